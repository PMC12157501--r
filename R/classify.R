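#' Microprocessor cleavage-efficiency score
#'
#' `score = log2(n_product + 0.1) - log2(n_substrate + 0.1)`, where the
#' inputs are normalized counts of cleaved products and of uncleaved
#' primary-transcript substrates. The 0.1 offset keeps the score finite at
#' zero counts and makes `score = 0` for equal product and substrate
#' abundance (including the all-zero case). Low scores mark poor
#' Microprocessor substrates.
#'
#' @param n_product,n_substrate non-negative normalized counts (vectorised).
#' @return data.frame with `score`, `n_product`, `n_substrate`.
#' @export
cleavage_score <- function(n_product, n_substrate) {
  .check(all(n_product >= 0) && all(n_substrate >= 0),
         "cleavage_score inputs must be non-negative")
  data.frame(score = log2(n_product + 0.1) - log2(n_substrate + 0.1),
             n_product = n_product, n_substrate = n_substrate)
}

#' Overlap of precursor intervals with ChIP peaks
#'
#' A locus overlaps when its precursor shares at least 1 bp with any peak
#' (half-open interval intersection). Loci on contigs absent from the peak
#' set get `FALSE`; if the peak set shares no contig with the loci at all,
#' a warning is raised (likely a coordinate-system mismatch).
#'
#' @param loci locus table.
#' @param peaks BED-style data.frame from [read_bed()] (0-based half-open).
#' @return named logical vector per locus.
#' @export
chip_overlap <- function(loci, peaks) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(setNames(rep(FALSE, nrow(loci)), loci$locus_id))
  }
  if (!any(peaks$contig_id %in% loci$contig_id)) {
    warning("no peak contig matches any locus contig; check coordinates")
    return(setNames(rep(FALSE, nrow(loci)), loci$locus_id))
  }
  gr_loci <- GenomicRanges::GRanges(
    loci$contig_id, IRanges::IRanges(loci$pre_start + 1L, loci$pre_end))
  gr_peaks <- GenomicRanges::GRanges(
    peaks$contig_id, IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(gr_loci, gr_peaks, minoverlap = 1L))
  setNames(hits > 0, loci$locus_id)
}

#' Default classification thresholds
#'
#' @param mp_insensitive_lfc a locus counts as Microprocessor-insensitive
#'   in a dataset when its MP-depletion lfc is at or above this value
#'   (slightly below 0: MP-independent loci are often modestly
#'   up-regulated, but sampling noise motivates a tolerance band).
#' @param dep_lfc depletion-response cutoff: Dicer/Pol III dependence
#'   requires lfc at or below this value.
#' @param padj adjusted-p cutoff for significant depletion.
#' @param pi_len,pi_nt length/5' nucleotide of piRNA-type reads.
#' @param sirna_len,sirna_nt length/5' nucleotide of 26G-type reads.
#' @return list of thresholds.
#' @export
classify_thresholds <- function(mp_insensitive_lfc = -0.5, dep_lfc = -1,
                                padj = 0.05, pi_len = 21L, pi_nt = "U",
                                sirna_len = 26L, sirna_nt = "G") {
  list(mp_insensitive_lfc = mp_insensitive_lfc, dep_lfc = dep_lfc,
       padj = padj, pi_len = pi_len, pi_nt = pi_nt,
       sirna_len = sirna_len, sirna_nt = sirna_nt)
}

# dependence calls from lfc/p_adj pairs; NA-safe (absent evidence -> FALSE)
.dep_call <- function(lfc, padj, th) {
  !is.na(lfc) & !is.na(padj) & lfc <= th$dep_lfc & padj < th$padj
}

#' Classify one locus from its evidence vector
#'
#' Rules are evaluated in priority order on depletion responses, read
#' geometry, hairpin structure and Pol III promoter evidence:
#'
#' 1. `misannotated_piRNA`: dominant read length 21, 5' U, not
#'    Dicer-dependent.
#' 2. `misannotated_26G`: dominant read length 26, 5' G.
#' 3. `mp_dicer_independent`: MP-insensitive in every available MP
#'    dataset, not Dicer-dependent, with Pol III dependence or
#'    architecture.
#' 4. `polIII_noncanonical`: MP-insensitive in every available MP dataset,
#'    Dicer-dependent, and Pol III-dependent (or architecture corroborated
#'    by ChIP overlap when no depletion evidence is available).
#' 5. `mirtron_like`: MP-insensitive, Dicer-dependent, short hairpin, no
#'    Pol III evidence.
#' 6. `canonical`: MP-sensitive and Dicer-dependent.
#' 7. `unclassified` otherwise.
#'
#' MP insensitivity is the conjunction over the MP datasets present
#' (`lfc_MP_1`, `lfc_MP_2`); with a single dataset the rule degrades to
#' that dataset alone and the rationale notes it.
#'
#' @param ev one-row data.frame (or list) with fields `lfc_MP_1`,
#'   `lfc_MP_2`, `lfc_dicer`, `padj_dicer`, `lfc_polIII`, `padj_polIII`
#'   (any may be `NA`), `short_hairpin`, `polIII_architecture`,
#'   `chip_overlap`, `dominant_length`, `first_nt`.
#' @param thresholds see [classify_thresholds()].
#' @return list with `label` and `rationale` (character vector of fired /
#'   failed rules).
#' @export
classify_locus <- function(ev, thresholds = classify_thresholds()) {
  th <- thresholds
  rationale <- character(0)
  note <- function(...) rationale <<- c(rationale, sprintf(...))

  mp <- c(ev$lfc_MP_1, ev$lfc_MP_2)
  mp <- mp[!is.na(mp)]
  dicer_dep <- .dep_call(ev$lfc_dicer, ev$padj_dicer, th)
  polIII_dep <- .dep_call(ev$lfc_polIII, ev$padj_polIII, th)
  arch <- isTRUE(ev$polIII_architecture)
  chip <- isTRUE(ev$chip_overlap)
  short <- isTRUE(ev$short_hairpin)
  has_any <- length(mp) > 0 || !is.na(ev$lfc_dicer)
  if (!has_any) {
    return(list(label = "unclassified", rationale = "no data"))
  }
  mp_insensitive <- length(mp) > 0 && all(mp >= th$mp_insensitive_lfc)
  mp_sensitive <- length(mp) > 0 && !mp_insensitive
  if (length(mp) == 1L) note("single MP dataset available")
  note("MP %s (lfc: %s)", if (mp_insensitive) "insensitive" else
    if (mp_sensitive) "sensitive" else "no data",
    paste(sprintf("%.2f", mp), collapse = ","))
  if (is.na(ev$lfc_dicer)) {
    note("Dicer evidence absent")
  } else {
    note("Dicer %s", if (dicer_dep) "dependent" else "not dependent")
  }
  if (!is.na(ev$lfc_polIII)) {
    note("PolIII %s", if (polIII_dep) "dependent" else "not dependent")
  }
  if (arch) note("PolIII promoter architecture present")
  if (chip) note("PolIII ChIP overlap")

  label <- if (!is.na(ev$dominant_length) && !is.na(ev$first_nt) &&
               ev$dominant_length == th$pi_len && ev$first_nt == th$pi_nt &&
               !dicer_dep) {
    note("%d nt with 5' %s, Dicer-independent: piRNA-type", th$pi_len,
         th$pi_nt)
    "misannotated_piRNA"
  } else if (!is.na(ev$dominant_length) && !is.na(ev$first_nt) &&
             ev$dominant_length == th$sirna_len &&
             ev$first_nt == th$sirna_nt) {
    note("%d nt with 5' %s: 26G-type endo-siRNA", th$sirna_len, th$sirna_nt)
    "misannotated_26G"
  } else if (mp_insensitive && !dicer_dep && (polIII_dep || arch)) {
    note("requires neither MP nor Dicer, Pol III unit")
    "mp_dicer_independent"
  } else if (mp_insensitive && dicer_dep && (polIII_dep || (arch && chip))) {
    note("MP-independent, Dicer-dependent, Pol III-dependent")
    "polIII_noncanonical"
  } else if (mp_insensitive && dicer_dep && short && !polIII_dep && !arch) {
    note("MP-independent, Dicer-dependent short hairpin, no Pol III evidence")
    "mirtron_like"
  } else if (mp_sensitive && dicer_dep) {
    note("MP- and Dicer-dependent")
    "canonical"
  } else {
    note("no rule satisfied")
    "unclassified"
  }
  list(label = label, rationale = rationale)
}

#' Classify all loci in an evidence table
#'
#' @param evidence data.frame with one row per locus (columns as in
#'   [classify_locus()], plus `locus_id`).
#' @param thresholds see [classify_thresholds()].
#' @return data.frame: `locus_id`, `label`, `rationale` (rules joined with
#'   `; `).
#' @export
classify_loci <- function(evidence, thresholds = classify_thresholds()) {
  out <- lapply(seq_len(nrow(evidence)), function(i) {
    res <- classify_locus(evidence[i, ], thresholds)
    data.frame(locus_id = evidence$locus_id[i], label = res$label,
               rationale = paste(res$rationale, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble per-locus evidence from the pipeline stage outputs
#'
#' Per locus, depletion evidence is taken from its dominant arm (the arm
#' with the highest `baseMean` in the first available contrast table).
#' Dominant read length and 5' nucleotide come from assigned reads of that
#' arm when reads are available (weighted mode), else from the annotated
#' arm reference sequence. The 3p-biased A-tailing flag compares 3p and 5p
#' percent A-tailing within the locus when both arms are profiled.
#'
#' @param loci locus table.
#' @param genome named character vector of contig sequences.
#' @param diff_tables named list of [diff_table()] results; recognised
#'   names: `MP_1`, `MP_2`, `Dicer`, `PolIII`.
#' @param hairpins output of [hairpin_report_all()].
#' @param polIII output of [polIII_report_all()].
#' @param chip logical vector from [chip_overlap()], or `NULL`.
#' @param calls tail calls from [call_tails()], or `NULL`.
#' @param tail_bias_min percentage-point 3p-minus-5p A-tail difference
#'   flagged as 3p-biased.
#' @return evidence data.frame, one row per locus.
#' @export
build_evidence <- function(loci, genome, diff_tables, hairpins, polIII,
                           chip = NULL, calls = NULL, tail_bias_min = 5) {
  .check(length(diff_tables) > 0, "at least one contrast table required")
  first_dt <- diff_tables[[1]]
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    feats <- paste0(r$locus_id, "-", c("5p", "3p"))
    feats <- feats[c(!is.na(r$arm5p_start), !is.na(r$arm3p_start))]
    bm <- first_dt$baseMean[match(feats, first_dt$feature_id)]
    dom <- if (all(is.na(bm))) feats[1] else feats[which.max(bm)]

    get <- function(name, col) {
      dt <- diff_tables[[name]]
      if (is.null(dt)) return(NA_real_)
      dt[[col]][match(dom, dt$feature_id)]
    }
    # dominant read geometry
    dom_len <- NA_integer_
    first_nt <- NA_character_
    if (!is.null(calls) && nrow(calls) > 0) {
      cl <- calls[calls$feature_id == dom, , drop = FALSE]
      if (nrow(cl) > 0) {
        w <- cl$weight * cl$count
        lens <- tapply(w, nchar(cl$read), sum)
        dom_len <- as.integer(names(lens)[which.max(lens)])
        nts <- tapply(w, substr(cl$read, 1, 1), sum)
        first_nt <- chartr("T", "U", names(nts)[which.max(nts)])
      }
    }
    if (is.na(dom_len)) {
      arm <- sub("^.*-", "", dom)
      s <- r[[paste0("arm", arm, "_start")]]
      e <- r[[paste0("arm", arm, "_end")]]
      if (!is.na(s)) {
        dom_len <- e - s
        first_nt <- chartr("T", "U",
                           substr(sense_seq(genome, r$contig_id, s, e,
                                            r$strand), 1, 1))
      }
    }
    # 3p-vs-5p A-tail bias within the locus
    bias <- NA
    if (!is.null(calls) && nrow(calls) > 0 && length(feats) == 2) {
      pctA <- vapply(feats, function(f) {
        cl <- calls[calls$feature_id == f, , drop = FALSE]
        if (nrow(cl) == 0) return(NA_real_)
        w <- cl$weight * cl$count
        100 * sum(w[cl$tail_class == "A"]) / sum(w)
      }, numeric(1))
      if (!anyNA(pctA)) bias <- (pctA[2] - pctA[1]) >= tail_bias_min
    }
    hp <- match(r$locus_id, hairpins$locus_id)
    p3 <- match(r$locus_id, polIII$locus_id)
    rows[[i]] <- data.frame(
      locus_id = r$locus_id, dominant_arm = dom,
      lfc_MP_1 = get("MP_1", "lfc"), lfc_MP_2 = get("MP_2", "lfc"),
      lfc_dicer = get("Dicer", "lfc"), padj_dicer = get("Dicer", "p_adj"),
      lfc_polIII = get("PolIII", "lfc"), padj_polIII = get("PolIII", "p_adj"),
      short_hairpin = hairpins$short_hairpin[hp],
      stem_pairs = hairpins$stem_pairs[hp],
      polIII_architecture = polIII$polIII_architecture[p3],
      chip_overlap = if (!is.null(chip)) unname(chip[r$locus_id]) else NA,
      dominant_length = dom_len, first_nt = first_nt,
      a_tail_3p_bias = bias,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
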