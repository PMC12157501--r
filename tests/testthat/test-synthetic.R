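test_that("generator is fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 42)
  a <- build_genome_and_loci(cfg)
  b <- build_genome_and_loci(cfg)
  expect_identical(a, b)
  expect_identical(simulate_counts(cfg, a$manifest),
                   simulate_counts(cfg, b$manifest))
  expect_identical(simulate_reads(cfg, a$manifest),
                   simulate_reads(cfg, b$manifest))
  # a different seed changes sequences but not the schema
  c <- build_genome_and_loci(small_cfg(seed = 43))
  expect_false(identical(a$genome, c$genome))
  expect_identical(names(a$loci), names(c$loci))
})

test_that("planted loci have the requested structure and read geometry", {
  cfg <- small_cfg(seed = 8)
  sim <- build_genome_and_loci(cfg)
  tr <- sim$manifest$loci
  expect_equal(tr$stem_pairs[tr$class == "canonical"], rep(35L, 2))
  expect_equal(tr$stem_pairs[tr$class == "mirtron_like"], rep(22L, 2))
  # piRNA-type loci: 21-nt arm starting with T; 26G-type: 26 nt, G
  arms <- sim$manifest$arms
  pi_arms <- arms[arms$class == "piRNA_like", ]
  expect_true(all(nchar(pi_arms$arm_seq) == 21L))
  expect_true(all(substr(pi_arms$arm_seq, 1, 1) == "T"))
  g_arms <- arms[arms$class == "siRNA26G_like", ]
  expect_true(all(nchar(g_arms$arm_seq) == 26L))
  expect_true(all(substr(g_arms$arm_seq, 1, 1) == "G"))
  # arm reference sequences match the genome sense strand
  for (i in seq_len(nrow(arms))) {
    r <- sim$loci[match(arms$locus_id[i], sim$loci$locus_id), ]
    s <- r[[paste0("arm", arms$arm[i], "_start")]]
    e <- r[[paste0("arm", arms$arm[i], "_end")]]
    expect_equal(sense_seq(sim$genome, r$contig_id, s, e, r$strand),
                 arms$arm_seq[i])
  }
})

test_that("null fold changes give equal per-condition count means", {
  cfg <- sim_config(seed = 3, classes = "canonical", n_loci_per_class = 5,
                    n_replicates = 50, planted_lfc = null_lfc())
  sim <- build_genome_and_loci(cfg)
  cm <- simulate_counts(cfg, sim$manifest)
  means <- sapply(unique(cm$condition), function(cond) {
    mean(cm$counts[, cm$condition == cond])
  })
  expect_true(all(abs(log2(means / mean(means))) < 0.1))
})

test_that("planted lfc of -2 is reproduced by the count model", {
  lfc <- null_lfc()
  lfc["canonical", "Dicer_depleted"] <- -2
  cfg <- sim_config(seed = 4, classes = "canonical", n_loci_per_class = 5,
                    n_replicates = 20, depth_mean = 2000, planted_lfc = lfc)
  sim <- build_genome_and_loci(cfg)
  cm <- simulate_counts(cfg, sim$manifest)
  obs <- log2(mean(cm$counts[, cm$condition == "Dicer_depleted"]) /
                mean(cm$counts[, cm$condition == "control"]))
  expect_lt(abs(obs - (-2)), 0.3)
})

test_that("zero dispersion reaches the Poisson limit", {
  cfg <- sim_config(seed = 5, classes = "canonical", n_loci_per_class = 1,
                    n_replicates = 400, nb_dispersion = 0)
  sim <- build_genome_and_loci(cfg)
  cm <- simulate_counts(cfg, sim$manifest)
  x <- cm$counts[1, cm$condition == "control"]
  expect_lt(abs(var(x) / mean(x) - 1), 0.35)
})

test_that("degenerate read model emits exact arm references", {
  cfg <- sim_config(seed = 6, classes = "canonical", n_loci_per_class = 2,
                    trim_model = c(`0` = 1), reads_per_arm = 200)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  ref <- sim$manifest$arms$arm_seq[match(rd$feature_id,
                                         sim$manifest$arms$feature_id)]
  expect_true(all(rd$read == ref))
  expect_true(all(rd$trim == 0L))
  expect_true(all(rd$tail == ""))
})

test_that("planted A-tail rate and -1-isoform concentration are emitted", {
  cfg <- sim_config(seed = 7, classes = "polIII_noncanonical",
                    n_loci_per_class = 2, reads_per_arm = 10000,
                    n_replicates = 1)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  rd3 <- rd[grepl("-3p$", rd$feature_id), ]
  frac_a <- sum(rd3$count[rd3$tail != "" & grepl("^A+$", rd3$tail)]) /
    sum(rd3$count)
  expect_lt(abs(frac_a - 0.1), 0.01)
  # among tailed 3p reads the modal templated length is reference - 1
  tails <- rd3[rd3$tail != "", ]
  w <- tapply(tails$count, tails$trim, sum)
  expect_equal(names(w)[which.max(w)], "-1")
  # 5p arms are untailed under the default model
  rd5 <- rd[grepl("-5p$", rd$feature_id), ]
  expect_true(all(rd5$tail == ""))
})

test_that("read lengths stay within the collapsed-read bounds", {
  cfg <- small_cfg(seed = 9)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  expect_true(all(nchar(rd$read) >= 16 & nchar(rd$read) <= 35))
})
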