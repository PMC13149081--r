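# Segmentation and classification metrics plus patient-level statistical
# inference: stratified bootstrap CIs, exact paired Wilcoxon signed-rank
# tests, Holm-Bonferroni step-down correction, and fold-level dispersion.

check_masks <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  list(a = as.logical(a), b = as.logical(b))
}

#' Overlap and confusion metrics for binary masks
#'
#' `dice(A, B) = 2|A&B| / (|A| + |B|)` and friends. When both masks are
#' empty the overlap metrics return 1 by convention. All metrics lie in
#' `[0, 1]` and `iou <= dice` with equality only at 0 or 1.
#'
#' @param pred,truth Binary/logical masks of identical shape.
#' @return Scalar metric value.
#' @export
dice <- function(pred, truth) {
  m <- check_masks(pred, truth)
  s <- sum(m$a) + sum(m$b)
  if (s == 0) return(1)
  2 * sum(m$a & m$b) / s
}

#' @rdname dice
#' @export
iou <- function(pred, truth) {
  m <- check_masks(pred, truth)
  u <- sum(m$a | m$b)
  if (u == 0) return(1)
  sum(m$a & m$b) / u
}

#' @rdname dice
#' @export
pixel_accuracy <- function(pred, truth) {
  m <- check_masks(pred, truth)
  mean(m$a == m$b)
}

#' Classification metrics from binary predictions
#'
#' Sensitivity, specificity and F1 with class 1 as the positive class.
#'
#' @param pred,truth Binary vectors.
#' @return Named vector `c(acc, sen, spe, f1)`.
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(acc = mean(pred == truth), sen = sen, spe = spe, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Stratified nonparametric bootstrap confidence interval
#'
#' Resamples patients with replacement within each stratum, recomputes the
#' statistic `B` times, and returns the percentile interval.
#'
#' @param values Per-patient metric values.
#' @param strata Stratum labels (NULL = unstratified); every stratum needs
#'   at least 2 patients.
#' @param statistic Function of a numeric vector (default mean).
#' @param B Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(low, high, estimate)`.
#' @export
bootstrap_ci <- function(values, strata = NULL, statistic = mean, B = 2000L,
                         level = 0.95, seed = 1L) {
  stopifnot(B >= 1, level > 0, level < 1)
  n <- length(values)
  if (is.null(strata)) strata <- rep(1L, n)
  stopifnot(length(strata) == n)
  groups <- split(seq_len(n), strata)
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("every stratum needs at least 2 patients", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  stats <- vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                          replace = TRUE)]),
                  use.names = FALSE)
    statistic(values[idx])
  }, numeric(1))
  qs <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  c(low = qs[1], high = qs[2], estimate = statistic(values))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties. For up to 25 informative pairs the exact null
#' distribution of the signed-rank sum is computed by dynamic programming
#' over doubled midranks (exact under ties); larger samples use the normal
#' approximation with tie correction and continuity correction. The effect
#' size is the mean paired difference with a bootstrap percentile CI.
#'
#' @param a,b Paired numeric vectors.
#' @param exact_max Largest number of informative pairs for the exact test.
#' @param B Bootstrap replicates for the effect-size CI.
#' @param seed Seed for the effect-size bootstrap.
#' @return List: `p`, `statistic` (W+, rank sum of positive differences),
#'   `n_informative`, `delta` (mean of a-b), `delta_ci`, `degenerate`,
#'   `method`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25L, B = 2000L, seed = 1L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  delta <- mean(d)
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0L) {
    return(list(p = 1, statistic = 0, n_informative = 0L, delta = delta,
                delta_ci = c(low = delta, high = delta), degenerate = TRUE,
                method = "degenerate"))
  }
  r <- rank(abs(dn))
  W <- sum(r[dn > 0])
  if (n <= exact_max) {
    # exact distribution over 2^n sign assignments via DP on 2*rank sums
    r2 <- round(2 * r)
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[w+1] = number of assignments with 2W = w
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
        f[seq_len(total + 1L - ri)]
      f <- g
    }
    w2 <- round(2 * W)
    p_le <- sum(f[seq_len(w2 + 1L)]) / 2^n
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(dn))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  ci <- if (length(d) >= 2) {
    bootstrap_ci(d, B = B, seed = seed)[c("low", "high")]
  } else c(low = delta, high = delta)
  list(p = p, statistic = W, n_informative = n, delta = delta,
       delta_ci = ci, degenerate = FALSE, method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by `m - i + 1`,
#' enforces monotonicity by cumulative maximum, caps at 1 and restores the
#' input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Coefficient of variation across folds
#'
#' `100 * sd / mean` with the n-1 standard deviation; undefined at zero
#' mean.
#'
#' @param values Per-fold metric values.
#' @return CoV in percent.
#' @export
cov_percent <- function(values) {
  m <- mean(values)
  if (m == 0) stop("CoV undefined at zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Evaluate a pipeline result table
#'
#' Computes patient-level genotype metrics (accuracy/sen/spe/F1 from the
#' majority votes, AUC and P_mean from the stitched probabilities) and, when
#' segmentation Dice values are present, their summary, with stratified
#' bootstrap CIs.
#'
#' @param result data.frame from [run_pipeline()].
#' @param B Bootstrap replicates.
#' @param seed Seed for the CIs.
#' @return List of class `cohort_evaluation`.
#' @export
evaluate_cohort <- function(result, B = 2000L, seed = 1L) {
  ok <- result[result$status == "ok" & !is.na(result$p_mean), , drop = FALSE]
  excluded <- nrow(result) - nrow(ok)
  out <- list(n = nrow(ok), excluded = excluded)
  if (nrow(ok)) {
    cm <- classification_metrics(ok$vote, ok$truth)
    # P_mean of the *correct* class per patient, the patient-level
    # confidence that the model assigns to the truth
    p_true <- ifelse(ok$truth == 1, ok$p_mean, 1 - ok$p_mean)
    out$accuracy <- unname(cm["acc"])
    out$metrics <- cm
    out$p_mean <- mean(p_true)
    # stratify by class when every stratum is resamplable; tiny smoke
    # cohorts fall back to an unstratified (or absent) interval
    strata <- if (min(table(ok$truth)) >= 2) ok$truth else NULL
    out$p_mean_ci <- if (nrow(ok) >= 2) {
      bootstrap_ci(p_true, strata = strata, B = B, seed = seed)
    } else c(low = NA_real_, high = NA_real_, estimate = mean(p_true))
    out$auc <- if (length(unique(ok$truth)) == 2) auc(ok$p_mean, ok$truth)
               else NA_real_
  }
  if (any(!is.na(result$dice))) {
    dv <- result$dice[!is.na(result$dice)]
    out$dice <- mean(dv)
    out$dice_ci <- if (length(dv) >= 2) bootstrap_ci(dv, B = B, seed = seed)
                   else c(low = NA_real_, high = NA_real_, estimate = mean(dv))
  }
  structure(out, class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> %d patients (%d excluded)\n",
              x$n, x$excluded))
  if (!is.null(x$dice)) {
    cat(sprintf("  Dice: %.4f [%.4f, %.4f]\n", x$dice, x$dice_ci["low"],
                x$dice_ci["high"]))
  }
  if (!is.null(x$p_mean)) {
    cat(sprintf("  P_mean: %.4f [%.4f, %.4f]  accuracy: %.4f  AUC: %s\n",
                x$p_mean, x$p_mean_ci["low"], x$p_mean_ci["high"],
                x$accuracy,
                ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  }
  invisible(x)
}
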