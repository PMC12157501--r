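#' Spike-in size factors
#'
#' The per-sample size factor is the sample's spike-in total divided by the
#' mean spike-in total across samples, so normalized counts are on the
#' absolute scale set by the exogenous spikes and `mean(sf) == 1` by
#' construction. Normalized counts are raw counts divided by the size
#' factor.
#'
#' @param cm a `count_matrix`.
#' @return named numeric vector of size factors, one per sample.
#' @export
spike_size_factors <- function(cm) {
  .check(all(cm$spike_counts > 0), "zero spike-in total; cannot normalize")
  cm$spike_counts / mean(cm$spike_counts)
}

# normalized count matrix
.norm_counts <- function(cm, sf) {
  sweep(cm$counts, 2, sf, "/")
}

.contrast_cols <- function(cm, contrast) {
  treat <- which(cm$condition == contrast[1])
  ctrl <- which(cm$condition == contrast[2])
  .check(length(treat) > 0, "condition '%s' absent from count matrix",
         contrast[1])
  .check(length(ctrl) > 0, "condition '%s' absent from count matrix",
         contrast[2])
  list(treat = treat, ctrl = ctrl)
}

#' Log2 fold changes of spike-normalized mean counts
#'
#' `lfc = log2((mean normalized treat + pc) / (mean normalized ctrl + pc))`;
#' the pseudocount keeps fold changes finite for dropout features.
#'
#' @param cm a `count_matrix`.
#' @param sf size factors from [spike_size_factors()].
#' @param contrast length-2 character vector `(treat_label, ctrl_label)`.
#' @param pseudocount added to both group means.
#' @return named numeric vector of per-feature log2 fold changes.
#' @export
log2_fold_change <- function(cm, sf, contrast, pseudocount = 0.5) {
  cc <- .contrast_cols(cm, contrast)
  nc <- .norm_counts(cm, sf)
  m_t <- rowMeans(nc[, cc$treat, drop = FALSE])
  m_c <- rowMeans(nc[, cc$ctrl, drop = FALSE])
  log2((m_t + pseudocount) / (m_c + pseudocount))
}

#' Simplified negative-binomial Wald test per feature
#'
#' A deliberately transparent two-group test on spike-normalized counts:
#' the NB dispersion is estimated per feature by method of moments on the
#' pooled within-group variation (`alpha = max(0, (s2 - m)/m^2)`, truncated
#' at the Poisson floor), the Wald statistic is the log2 fold change over
#' its delta-method standard error under `NB(mu_g, alpha)` per group, and
#' the p-value is two-sided normal. Calibration of this test is part of
#' the package's acceptance checks; it is an approximation, not a
#' re-implementation of shrinkage-based tools.
#'
#' @inheritParams log2_fold_change
#' @return numeric vector of two-sided p-values in (0, 1].
#' @export
nb_test <- function(cm, sf, contrast, pseudocount = 0.5) {
  cc <- .contrast_cols(cm, contrast)
  .check(length(cc$treat) >= 2 && length(cc$ctrl) >= 2,
         "need >= 2 replicates per condition; report lfc only")
  nc <- .norm_counts(cm, sf)
  xt <- nc[, cc$treat, drop = FALSE]
  xc <- nc[, cc$ctrl, drop = FALSE]
  n_t <- ncol(xt)
  n_c <- ncol(xc)
  m_t <- rowMeans(xt)
  m_c <- rowMeans(xc)
  # MoM dispersion on the counts of both groups pooled into one sample;
  # between-group signal inflates alpha, making the test conservative for
  # large effects, which is the intended trade-off of this simple test
  pooled <- cbind(xt, xc)
  s2 <- apply(pooled, 1, var)
  m_all <- rowMeans(pooled)
  alpha <- pmax(0, (s2 - m_all) / m_all^2)
  alpha[!is.finite(alpha)] <- 0
  lfc <- log2((m_t + pseudocount) / (m_c + pseudocount))
  # delta method: Var(log2 mhat_g) ~ (mu_g + alpha mu_g^2) / n_g /
  #   ((mu_g + pc)^2 ln(2)^2)
  v_t <- (m_t + alpha * m_t^2) / n_t / ((m_t + pseudocount)^2 * log(2)^2)
  v_c <- (m_c + alpha * m_c^2) / n_c / ((m_c + pseudocount)^2 * log(2)^2)
  se <- sqrt(v_t + v_c)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; thin wrapper over the stock implementation so the
#' whole result table is produced through one package surface.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Differential abundance results table for one contrast
#'
#' Combines spike-in normalization, log2 fold changes, the NB Wald test and
#' BH adjustment into the standard per-feature results table. `baseMean` is
#' the mean of normalized counts over all samples (not only the contrasted
#' groups); features with `baseMean` below `base_mean_min` are flagged, not
#' removed.
#'
#' @inheritParams log2_fold_change
#' @param base_mean_min flagging threshold on `baseMean` (10 is typical for
#'   deep libraries, 1 for shallow ones).
#' @return data.frame: `feature_id`, `baseMean`, `lfc`, `p`, `p_adj`,
#'   `flag_low`.
#' @export
diff_table <- function(cm, contrast, pseudocount = 0.5, base_mean_min = 10) {
  sf <- spike_size_factors(cm)
  nc <- .norm_counts(cm, sf)
  base_mean <- rowMeans(nc)
  lfc <- log2_fold_change(cm, sf, contrast, pseudocount)
  p <- nb_test(cm, sf, contrast, pseudocount)
  data.frame(feature_id = rownames(cm$counts),
             baseMean = unname(base_mean),
             lfc = unname(lfc),
             p = unname(p),
             p_adj = unname(bh_adjust(p)),
             flag_low = unname(base_mean < base_mean_min),
             stringsAsFactors = FALSE)
}
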