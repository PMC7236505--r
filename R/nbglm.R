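# Shared negative-binomial GLM likelihood-ratio machinery.
#
# All two-group tests in the package (DIU, DCU, DFI, DPA, DGE) reduce to the
# same log-linear model on raw counts with effective library sizes as offsets:
#   log mu = log(offset) + unit + condition + unit:condition
# The interaction block is tested by likelihood ratio on (k-1)(c-1) degrees
# of freedom at fixed dispersion. Because the dispersion is a noisy
# method-of-moments estimate with few replicates, the scaled statistic
# LRT/df is referred to an F distribution whose denominator df is the
# residual df that fed the dispersion estimate (quasi-likelihood-style
# small-sample correction); with many replicates this converges to the
# chi-square reference.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Plain step-up implementation: sort p ascending, compute `p * n / rank`,
#' enforce monotonicity from the largest p downward, cap at 1. `NA` p-values
#' are left `NA` and do not count toward `n`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * n / seq(n, 1)))
  out[ok[o]] <- adj
  out
}

# pooled method-of-moments dispersion on offset-normalized counts.
# counts: units x samples; condition: factor-like per sample; offsets: per
# sample. For NB counts E[v] = m + phi m^2; the squared sample mean
# overestimates the true squared mean by var(mean) = E[v]/n, so the unbiased
# denominator is m^2 - v/n. phi-hat = sum_u,g (v - m) / sum_u,g (m^2 - v/n),
# floored.
estimate_dispersion <- function(counts, condition, offsets, floor = 0.01) {
  sf <- offsets / mean(offsets)
  y <- sweep(counts, 2, sf, "/")
  num <- 0; den <- 0
  for (cc in unique(condition)) {
    sub <- y[, condition == cc, drop = FALSE]
    n <- ncol(sub)
    if (n < 2L) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2 - v / n)
  }
  if (den <= 0) return(floor)
  max(floor, num / den)
}

# deviance of an NB GLM with fixed theta; returns NA on failure
nb_deviance <- function(y, X, offset_log, theta) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      x = X, y = y, offset = offset_log,
      family = MASS::negative.binomial(theta = theta),
      control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  fit$deviance
}

#' Negative-binomial interaction test for one gene
#'
#' Fits `log mu = log(offset) + unit + condition + unit:condition` to the raw
#' counts of the units (isoforms, CDS groups, include/exclude or
#' distal/proximal aggregates) of one gene and performs a likelihood-ratio
#' test of the interaction block against the additive model on
#' `df = (k-1)(c-1)` degrees of freedom. The dispersion is a pooled
#' per-condition method-of-moments estimate on offset-normalized counts,
#' floored at 0.01, shared by both fits; to account for its sampling noise
#' with few replicates, `LRT/df` is referred to an `F(df, resid_df)`
#' distribution with `resid_df = k * sum_groups (n_g - 1)`, the residual
#' degrees of freedom behind the dispersion estimate.
#'
#' @param counts integer-like matrix, units x samples (raw counts).
#' @param condition character/factor of per-sample conditions (2 levels, each
#'   with at least 2 replicates).
#' @param offsets per-sample effective library sizes.
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @return list with `k_units`, `statistic` (the LRT deviance difference),
#'   `df`, `resid_df`, `p`, `dispersion`, `status` (`"tested"` or
#'   `"not_testable"`).
#' @export
fit_interaction_test <- function(counts, condition, offsets, dispersion = NULL) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition), length(offsets) == length(condition))
  conds <- unique(condition)
  if (length(conds) != 2L || any(table(condition) < 2L))
    stop("contract error: two conditions with >=2 replicates each are required")
  if (any(counts != round(counts))) {
    counts <- round(counts)
    message("non-integer counts rounded for NB testing")
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  k <- nrow(counts)
  if (k < 2L)
    return(list(k_units = k, statistic = NA_real_, df = NA_integer_,
                resid_df = NA_integer_, p = NA_real_,
                dispersion = NA_real_, status = "not_testable"))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, condition, offsets)
  theta <- 1 / dispersion
  n_s <- length(condition)
  unit <- factor(rep(seq_len(k), times = n_s))
  cond <- factor(rep(condition, each = k))
  y <- as.vector(counts)              # column-major: units fastest
  off <- log(rep(offsets, each = k))
  Xf <- stats::model.matrix(~ unit * cond)
  Xr <- stats::model.matrix(~ unit + cond)
  dev_f <- nb_deviance(y, Xf, off, theta)
  dev_r <- nb_deviance(y, Xr, off, theta)
  if (is.na(dev_f) || is.na(dev_r))
    return(list(k_units = k, statistic = NA_real_, df = NA_integer_,
                resid_df = NA_integer_, p = NA_real_,
                dispersion = dispersion, status = "not_testable"))
  stat <- max(0, dev_r - dev_f)
  df <- (k - 1L) * (length(conds) - 1L)
  resid_df <- k * sum(table(condition) - 1L)
  list(k_units = k, statistic = stat, df = df, resid_df = resid_df,
       p = stats::pf(stat / df, df, resid_df, lower.tail = FALSE),
       dispersion = dispersion, status = "tested")
}
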