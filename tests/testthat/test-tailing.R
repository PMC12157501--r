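test_that("reads are assigned by anchored prefix with fractional weights", {
  fx <- manual_genome()
  idx <- arm_index(fx$loci, fx$genome)
  reads <- data.frame(
    read = c(fx$arm5,                         # shared by locA/locB 5p arms
             fx$arm3,                         # unique to locA 3p
             "GGGGGGGGGGGGGGGGGGGG"),         # matches nothing
    count = c(10L, 4L, 1L), sample_id = "s1", stringsAsFactors = FALSE)
  asn <- assign_reads(reads, idx)
  shared <- asn[asn$read == fx$arm5, ]
  expect_equal(nrow(shared), 2L)
  expect_setequal(shared$feature_id, c("locA-5p", "locB-5p"))
  expect_equal(shared$weight, c(0.5, 0.5))
  uniq <- asn[asn$read == fx$arm3, ]
  expect_equal(uniq$feature_id, "locA-3p")
  expect_equal(uniq$weight, 1)
  expect_equal(attr(asn, "n_unassigned"), 1L)
})

test_that("reads shifted within +/-2 nt of the arm start are still assigned", {
  fx <- manual_genome()
  idx <- arm_index(fx$loci, fx$genome)
  # read starting 2 nt into the arm
  reads2 <- data.frame(read = substr(fx$arm3, 3, 22), count = 1L,
                       sample_id = "s1", stringsAsFactors = FALSE)
  asn <- assign_reads(reads2, idx)
  expect_equal(asn$feature_id, "locA-3p")
  expect_equal(asn$shift, 2L)
})

test_that("tail calling splits reads at the maximal templated prefix", {
  fx <- manual_genome()
  idx <- arm_index(fx$loci, fx$genome)
  next_base <- substr(fx$genome[["ctgA"]], 171, 171)  # base after arm3p end
  expect_false(next_base == "A")                      # fixture guarantees
  reads <- data.frame(
    read = c(fx$arm3,                                  # exact reference
             paste0(substr(fx$arm3, 1, 21), "A"),      # 1 nt short + A tail
             paste0(fx$arm3, next_base),               # templated extension
             paste0(fx$arm3, "AG")),                   # mixed tail
    count = 1L, sample_id = "s1", stringsAsFactors = FALSE)
  calls <- call_tails(assign_reads(reads, idx), idx)
  expect_equal(calls$tail_class, c("none", "A", "none", "other"))
  expect_equal(calls$trim_offset, c(0L, -1L, 1L, 0L))
  expect_equal(calls$tail, c("", "A", "", "AG"))
  expect_equal(calls$templated_length[2], 21L)
})

test_that("tail calls match the brute-force split oracle on synthetic reads", {
  cfg <- sim_config(seed = 31, classes = c("polIII_noncanonical", "canonical"),
                    n_loci_per_class = 2, reads_per_arm = 600,
                    n_replicates = 1)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  idx <- arm_index(sim$loci, sim$genome)
  calls <- call_tails(assign_reads(rd[, c("read", "count", "sample_id")],
                                   idx), idx)
  arm_row <- match(calls$feature_id, idx$arms$feature_id)
  for (i in seq_len(nrow(calls))) {
    j <- arm_row[i]
    at <- idx$arms$lead[j] + calls$shift[i]
    ext <- substr(idx$arms$ext[j], at + 1L, nchar(idx$arms$ext[j]))
    oracle <- oracle_tail_split(calls$read[i], ext)
    expect_equal(calls$templated_length[i], oracle$templated)
    expect_equal(calls$tail[i], oracle$tail)
  }
  # and the calls recover the generator's planted per-read truth
  merged <- merge(calls, rd,
                  by = c("read", "sample_id", "feature_id", "count"))
  expect_true(all(merged$tail.x == merged$tail.y))
  expect_true(all(merged$trim_offset == merged$trim))
})

test_that("tailing profile percentages and RPM filtering", {
  calls <- data.frame(
    read = "x", count = c(90, 10, 1),
    sample_id = "s1", feature_id = c("L-3p", "L-3p", "M-5p"),
    shift = 0L, weight = 1,
    templated_length = 22L, trim_offset = 0L,
    tail = c("", "A", ""), tail_class = c("none", "A", "none"),
    low_conf = FALSE, stringsAsFactors = FALSE)
  prof <- tailing_profile(calls, min_rpm = 1)
  l <- prof$profile[prof$profile$feature_id == "L-3p", ]
  expect_equal(l$pct_A, 10)
  expect_equal(l$pct_untailed, 90)
  # percentages plus untailed fraction close at 100
  sums <- rowSums(prof$profile[, c("pct_A", "pct_U", "pct_C", "pct_G",
                                   "pct_other", "pct_untailed")])
  expect_true(all(abs(sums - 100) < 1e-9))
  # an arm at 0.5 RPM mean abundance is excluded
  calls2 <- rbind(calls,
                  data.frame(read = "y", count = 1e6, sample_id = "s1",
                             feature_id = "big-5p", shift = 0L, weight = 1,
                             templated_length = 22L, trim_offset = 0L,
                             tail = "", tail_class = "none",
                             low_conf = FALSE))
  prof2 <- tailing_profile(calls2, min_rpm = 1)
  expect_false("M-5p" %in% prof2$profile$feature_id)
})

test_that("isoform table conserves weighted counts and keeps top-k", {
  cfg <- sim_config(seed = 33, classes = "polIII_noncanonical",
                    n_loci_per_class = 1, reads_per_arm = 3000,
                    n_replicates = 1)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  idx <- arm_index(sim$loci, sim$genome)
  calls <- call_tails(assign_reads(rd[, c("read", "count", "sample_id")],
                                   idx), idx)
  full <- tailing_profile(calls, min_rpm = 0, top_k = 1000L)
  total_iso <- sum(full$isoforms$count)
  expect_equal(total_iso, sum(calls$weight * calls$count))
  top6 <- tailing_profile(calls, min_rpm = 0, top_k = 6L)
  expect_true(all(table(top6$isoforms$feature_id) <= 6))
})

test_that("asymmetry test is exchangeable under equal rates", {
  prof <- data.frame(feature_id = paste0("L", 1:6, c("-3p", "-5p")),
                     arm = rep(c("3p", "5p"), 3),
                     pct_A = rep(5, 6), stringsAsFactors = FALSE)
  res <- asymmetry_test(prof, "A", n_perm = 500, seed = 1)
  expect_equal(res$delta, 0)
  expect_equal(res$p, 1)
  expect_gte(res$p, 1 / 501)
  expect_error(asymmetry_test(prof[1:2, ], "A"), "2 arms")
})

test_that("planted 3p-biased A-tailing is detected as asymmetric", {
  cfg <- sim_config(seed = 35, classes = "polIII_noncanonical",
                    n_loci_per_class = 6, reads_per_arm = 2000,
                    n_replicates = 1)
  sim <- build_genome_and_loci(cfg)
  rd <- simulate_reads(cfg, sim$manifest)
  idx <- arm_index(sim$loci, sim$genome)
  calls <- call_tails(assign_reads(rd[, c("read", "count", "sample_id")],
                                   idx), idx)
  prof <- tailing_profile(calls, min_rpm = 0)
  res <- asymmetry_test(prof$profile, "A", n_perm = 2000, seed = 2)
  expect_gt(res$delta, 5)
  expect_lt(res$p, 0.05)
})
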