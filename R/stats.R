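#' Mean and sample standard deviation of fold metrics
#'
#' @param values numeric vector (>= 2 values for the SD).
#' @return list with `mean` and `sd` (n-1 denominator).
#' @export
fold_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for the sample SD")
  list(mean = mean(values), sd = sd(values))
}

#' One-sample two-sided t-test against a baseline
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom
#' (delegated to [stats::t.test()]); the verdict is `"Significant"` when
#' `p < alpha`.
#'
#' @param values numeric vector (>= 2 values, non-constant).
#' @param mu0 hypothesized mean (e.g. the peer-model baseline accuracy).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `verdict`, `mu0`.
#' @export
one_sample_t_test <- function(values, mu0, alpha = 0.05) {
  if (length(values) < 2) stop("need at least 2 values")
  if (sd(values) == 0) stop("t statistic undefined: zero standard deviation")
  ht <- t.test(values, mu = mu0)
  list(t = unname(ht$statistic), p = ht$p.value,
       verdict = if (ht$p.value < alpha) "Significant" else "Not significant",
       mu0 = mu0)
}

#' Shapiro-Wilk normality test
#'
#' Royston's AS R94 algorithm as implemented by [stats::shapiro.test()];
#' valid for 3 to 5000 observations.
#'
#' @param values numeric vector.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires 3..5000 values")
  if (sd(values) == 0) stop("W undefined for constant input")
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Fold statistics report
#'
#' Summarizes per-fold cross-validation metrics the way the published
#' statistical table does: mean, sample SD, two-sided one-sample t-test
#' against `mu0`, and Shapiro-Wilk normality per metric column.
#'
#' @param folds data frame with one row per fold (e.g. a [cross_validate()]
#'   result or [tatha_reference_folds()]).
#' @param mu0 baseline mean; defaults to [peer_baseline_accuracy()].
#' @param metrics column names to summarize.
#' @return data frame with one row per metric: `mean`, `sd`, `t`, `p`,
#'   `verdict`, `shapiro_w`, `shapiro_p`, `mu0`.
#' @export
stat_report <- function(folds, mu0 = peer_baseline_accuracy(),
                        metrics = c("accuracy", "dice", "auc")) {
  rows <- lapply(metrics, function(m) {
    v <- folds[[m]]
    if (is.null(v)) stop("missing metric column: ", m)
    s <- fold_summary(v)
    tt <- one_sample_t_test(v, mu0)
    sw <- shapiro_wilk(v)
    data.frame(metric = m, mean = s$mean, sd = s$sd, t = tt$t, p = tt$p,
               verdict = tt$verdict, shapiro_w = sw$W, shapiro_p = sw$p,
               mu0 = mu0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published 15-fold cross-validation metrics for TATHA on DDTI
#'
#' The per-fold accuracy, Dice and AUC values reported for the method on
#' the DDTI dataset; shipped as a plain-text fixture so the statistics
#' harness can reproduce the published summary table without GPU training.
#'
#' @return data frame with columns `fold`, `accuracy`, `dice`, `auc`.
#' @export
tatha_reference_folds <- function() {
  read.csv(system.file("extdata", "tatha_crossval_15fold.csv",
                       package = "tatha"))
}

#' Published peer-model test metrics
#'
#' Test-set metrics reported for the four peer segmentation models
#' (U-Net, PSPNet, FPN, ViT) on DDTI.
#'
#' @return data frame with columns `metric`, `unet`, `pspnet`, `fpnnet`,
#'   `vit`.
#' @export
peer_test_metrics <- function() {
  read.csv(system.file("extdata", "peer_test_metrics.csv",
                       package = "tatha"))
}

#' Baseline accuracy: mean of the peer models' test accuracies
#'
#' The null-hypothesis value used by the fold t-tests (0.9124 at 4-decimal
#' rounding).
#'
#' @return scalar mean accuracy.
#' @export
peer_baseline_accuracy <- function() {
  pm <- peer_test_metrics()
  acc <- pm[pm$metric == "accuracy", c("unet", "pspnet", "fpnnet", "vit")]
  mean(as.numeric(acc))
}
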