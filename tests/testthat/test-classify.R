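ev_base <- function(...) {
  ev <- list(lfc_MP_1 = NA_real_, lfc_MP_2 = NA_real_,
             lfc_dicer = NA_real_, padj_dicer = NA_real_,
             lfc_polIII = NA_real_, padj_polIII = NA_real_,
             short_hairpin = FALSE, polIII_architecture = FALSE,
             chip_overlap = FALSE, dominant_length = 22L, first_nt = "A")
  mods <- list(...)
  ev[names(mods)] <- mods
  as.data.frame(ev, stringsAsFactors = FALSE)
}

test_that("cleavage score follows the exact offset-log formula", {
  expect_equal(cleavage_score(0, 0)$score, 0)
  expect_equal(cleavage_score(7, 7)$score, 0)
  expect_equal(cleavage_score(10, 0)$score, log2(101))
  expect_equal(cleavage_score(0, 10)$score, -log2(101))
  expect_error(cleavage_score(-1, 0), "non-negative")
  # vectorised
  s <- cleavage_score(c(0, 10), c(0, 0))
  expect_equal(s$score, c(0, log2(101)))
})

test_that("chip overlap uses half-open 1-bp intersection semantics", {
  loci <- loci_frame(data.frame(
    locus_id = c("A", "B", "C"), contig_id = c("c1", "c1", "c2"),
    strand = "+", pre_start = 100L, pre_end = 160L,
    stringsAsFactors = FALSE))
  peaks <- data.frame(contig_id = "c1", start = c(159L), end = c(200L))
  ov <- chip_overlap(loci, peaks)
  expect_true(ov[["A"]])
  expect_true(ov[["B"]])
  expect_false(ov[["C"]])   # no peaks on its contig

  peaks2 <- data.frame(contig_id = "c1", start = 160L, end = 200L)
  expect_false(chip_overlap(loci, peaks2)[["A"]])

  expect_false(any(chip_overlap(loci, peaks[0, ])))
  expect_warning(
    chip_overlap(loci, data.frame(contig_id = "zz", start = 1L, end = 5L)),
    "contig")
})

test_that("classification rules reproduce the canonical evidence patterns", {
  # Pol III noncanonical: MP-insensitive in both datasets, Dicer- and
  # Pol III-dependent, short hairpin with promoter architecture
  pol <- classify_locus(ev_base(
    lfc_MP_1 = 0.3, lfc_MP_2 = 0.2, lfc_dicer = -2.5, padj_dicer = 1e-4,
    lfc_polIII = -3, padj_polIII = 1e-4, short_hairpin = TRUE,
    polIII_architecture = TRUE, chip_overlap = TRUE))
  expect_equal(pol$label, "polIII_noncanonical")
  expect_true(length(pol$rationale) > 0)

  # 21-nt 5'U Dicer-independent read: misannotated piRNA
  pi <- classify_locus(ev_base(dominant_length = 21L, first_nt = "U",
                               lfc_dicer = -0.1, padj_dicer = 0.9))
  expect_equal(pi$label, "misannotated_piRNA")

  # 26-nt 5'G read: misannotated 26G endo-siRNA
  g26 <- classify_locus(ev_base(dominant_length = 26L, first_nt = "G",
                                lfc_dicer = -2, padj_dicer = 1e-3))
  expect_equal(g26$label, "misannotated_26G")

  # MP- and Dicer-sensitive: canonical
  can <- classify_locus(ev_base(lfc_MP_1 = -3, padj_dicer = 1e-5,
                                lfc_dicer = -3))
  expect_equal(can$label, "canonical")

  # MP-insensitive + Dicer-dependent + short hairpin, no Pol III: mirtron
  mirt <- classify_locus(ev_base(lfc_MP_1 = 0.1, lfc_dicer = -2.2,
                                 padj_dicer = 1e-3, short_hairpin = TRUE))
  expect_equal(mirt$label, "mirtron_like")

  # neither MP nor Dicer needed, Pol III-dependent
  ind <- classify_locus(ev_base(lfc_MP_1 = 0.2, lfc_dicer = 0.1,
                                padj_dicer = 0.8, lfc_polIII = -2.5,
                                padj_polIII = 1e-3))
  expect_equal(ind$label, "mp_dicer_independent")

  # no evidence at all
  none <- classify_locus(ev_base())
  expect_equal(none$label, "unclassified")
  expect_equal(none$rationale, "no data")
})

test_that("MP insensitivity is a conjunction over available MP datasets", {
  # sensitive in one of two datasets: not MP-insensitive
  mixed <- classify_locus(ev_base(lfc_MP_1 = 0.3, lfc_MP_2 = -2.5,
                                  lfc_dicer = -2.5, padj_dicer = 1e-4,
                                  short_hairpin = TRUE))
  expect_equal(mixed$label, "canonical")
  # single dataset degrades gracefully and is noted
  single <- classify_locus(ev_base(lfc_MP_1 = 0.3, lfc_dicer = -2.5,
                                   padj_dicer = 1e-4, short_hairpin = TRUE))
  expect_equal(single$label, "mirtron_like")
  expect_true(any(grepl("single MP dataset", single$rationale)))
})

test_that("labels are deterministic and stable under row permutation", {
  set.seed(15)
  evs <- do.call(rbind, lapply(1:40, function(i) {
    ev_base(lfc_MP_1 = rnorm(1), lfc_dicer = rnorm(1, -1),
            padj_dicer = runif(1), lfc_polIII = rnorm(1, -1),
            padj_polIII = runif(1), short_hairpin = runif(1) < 0.5,
            polIII_architecture = runif(1) < 0.3,
            chip_overlap = runif(1) < 0.3)
  }))
  evs$locus_id <- paste0("L", 1:40)
  lab <- classify_loci(evs)
  perm <- sample(1:40)
  lab_perm <- classify_loci(evs[perm, ])
  expect_equal(lab_perm$label[order(perm)], lab$label)
})

test_that("stricter Dicer significance only moves loci out of
           Dicer-dependent classes", {
  set.seed(16)
  dd_classes <- c("canonical", "polIII_noncanonical", "mirtron_like")
  evs <- do.call(rbind, lapply(1:60, function(i) {
    ev_base(lfc_MP_1 = rnorm(1), lfc_dicer = rnorm(1, -1.5),
            padj_dicer = runif(1, 0, 0.2), lfc_polIII = rnorm(1, -1),
            padj_polIII = runif(1), short_hairpin = runif(1) < 0.5,
            polIII_architecture = runif(1) < 0.3)
  }))
  evs$locus_id <- paste0("L", 1:60)
  loose <- classify_loci(evs, classify_thresholds(padj = 0.05))
  strict <- classify_loci(evs, classify_thresholds(padj = 0.01))
  in_dd_strict <- strict$label %in% dd_classes
  in_dd_loose <- loose$label %in% dd_classes
  expect_true(all(!in_dd_strict | in_dd_loose))
})
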