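mk_cm <- function(counts, spikes, cond) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  colnames(counts) <- paste0(cond, "_", ave(seq_along(cond), cond,
                                            FUN = seq_along))
  count_matrix(counts, spikes, cond)
}

test_that("spike size factors follow the stated formula and average to 1", {
  cm <- mk_cm(matrix(1, 2, 4), c(100, 100, 100, 100), rep(c("t", "c"), 2))
  expect_equal(unname(spike_size_factors(cm)), rep(1, 4))

  cm2 <- mk_cm(matrix(1, 2, 2), c(100, 300), c("t", "c"))
  expect_equal(unname(spike_size_factors(cm2)), c(0.5, 1.5))

  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    cm3 <- mk_cm(matrix(rpois(2 * n, 40), 2, n), rpois(n, 500) + 1,
                 rep(c("t", "c"), length.out = n))
    expect_equal(mean(spike_size_factors(cm3)), 1)
  }
})

test_that("scaling one sample's counts and spikes leaves normalization fixed", {
  set.seed(12)
  m <- matrix(rpois(20, 100), 5, 4)
  spikes <- c(200, 250, 300, 220)
  cond <- rep(c("t", "c"), each = 2)
  cm <- mk_cm(m, spikes, cond)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  spikes2 <- spikes; spikes2[2] <- spikes2[2] * 3
  cm2 <- mk_cm(m2, spikes2, cond)
  n1 <- sweep(cm$counts, 2, spike_size_factors(cm), "/")
  n2 <- sweep(cm2$counts, 2, spike_size_factors(cm2), "/")
  # all samples rescale by the same global factor (the spike-total mean),
  # so relative normalized abundances and fold changes are invariant
  expect_equal(n2[, 2] / n1[, 2], n2[, 1] / n1[, 1])
  expect_equal(log2_fold_change(cm, spike_size_factors(cm), c("t", "c"),
                                pseudocount = 0),
               log2_fold_change(cm2, spike_size_factors(cm2), c("t", "c"),
                                pseudocount = 0),
               tolerance = 1e-12)
})

test_that("log2 fold change formula, antisymmetry and zero limits", {
  m <- matrix(c(40, 40, 10, 10), 1)
  cm <- mk_cm(m, rep(100, 4), rep(c("t", "c"), each = 2))
  sf <- spike_size_factors(cm)
  expect_equal(unname(log2_fold_change(cm, sf, c("t", "c"))),
               log2(40.5 / 10.5))
  expect_equal(log2_fold_change(cm, sf, c("t", "c")),
               -log2_fold_change(cm, sf, c("c", "t")))
  m0 <- matrix(0, 1, 4)
  cm0 <- mk_cm(m0, rep(100, 4), rep(c("t", "c"), each = 2))
  expect_equal(unname(log2_fold_change(cm0, spike_size_factors(cm0),
                                       c("t", "c"))), 0)
  expect_error(log2_fold_change(cm, sf, c("t", "missing")), "absent")
})

test_that("nb_test truncates dispersion at the Poisson floor and needs n>=2", {
  # constant counts: s2 = 0 <= mean -> alpha truncated to 0, p well-defined
  m <- matrix(50, 3, 6)
  cm <- mk_cm(m, rep(100, 6), rep(c("t", "c"), each = 3))
  p <- nb_test(cm, spike_size_factors(cm), c("t", "c"))
  expect_true(all(p > 0 & p <= 1))
  expect_equal(unname(p), rep(1, 3))  # identical groups -> lfc 0 -> p 1

  cm1 <- mk_cm(matrix(50, 3, 2), rep(100, 2), c("t", "c"))
  expect_error(nb_test(cm1, spike_size_factors(cm1), c("t", "c")),
               "2 replicates")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(13)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  # monotone: sorted p gives sorted adjusted p
  p <- sort(runif(30))
  expect_false(is.unsorted(bh_adjust(p)))
})

test_that("diff_table wires normalization, test and flags together", {
  set.seed(14)
  n <- 3
  m <- rbind(strong = c(rpois(n, 2000), rpois(n, 250)),
             null = c(rpois(n, 500), rpois(n, 500)),
             low = c(rpois(n, 3), rpois(n, 3)))
  cm <- mk_cm(m, rpois(2 * n, 1000), rep(c("t", "c"), each = n))
  dt <- diff_table(cm, c("t", "c"), base_mean_min = 10)
  expect_equal(dt$feature_id, c("f1", "f2", "f3"))
  expect_true(all(dt$p_adj >= dt$p))
  expect_true(dt$flag_low[3])
  expect_false(any(dt$flag_low[1:2]))
  expect_gt(dt$lfc[1], 2)
})
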