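# Evaluation of predicted against true breeding values: accuracy, MSE,
# top-rank overlap, bias regression, between-method correlations, and the
# pi-sensitivity sweep for Bayes C.

#' Top-n rank accuracy
#'
#' Fraction of the `top_n` truly best animals (largest `true`) that are also
#' among the `top_n` predicted best. Ties are broken by position (animal
#' order), which is deterministic and documented. With
#' `method = "spearman"`, returns instead the Spearman correlation of the
#' two rankings restricted to the truly best `top_n` animals.
#'
#' @param pred,true numeric vectors of equal length, `length >= top_n`.
#' @param top_n size of the selected group (default 100).
#' @param method `"overlap"` (default) or `"spearman"`.
#' @return fraction in \[0,1\] (or a Spearman correlation).
#' @export
rank_accuracy <- function(pred, true, top_n = 100,
                          method = c("overlap", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(pred) == length(true))
  if (length(pred) < top_n)
    stop("need at least top_n = ", top_n, " animals")
  idx <- seq_along(true)
  top_true <- idx[order(-true, idx)][seq_len(top_n)]
  if (method == "spearman") {
    return(stats::cor(rank(pred[top_true]), rank(true[top_true])))
  }
  top_pred <- idx[order(-pred, idx)][seq_len(top_n)]
  length(intersect(top_pred, top_true)) / top_n
}

#' Bias regression coefficient
#'
#' OLS slope of true on predicted breeding values (the animal-breeding
#' convention for GEBV bias): a slope of 1 means unbiased dispersion,
#' below 1 over-dispersed predictions.
#'
#' @param pred,true numeric vectors of equal length.
#' @return the regression slope.
#' @export
bias_slope <- function(pred, true) {
  stopifnot(length(pred) == length(true))
  vp <- stats::var(pred)
  if (!is.finite(vp) || vp == 0) stop("zero variance in predictions")
  stats::cov(pred, true) / vp
}

#' Score predicted against true breeding values
#'
#' Returns the four statistics reported for method comparison: Pearson
#' correlation, mean squared error, top-`top_n` rank accuracy, and the bias
#' regression slope of true on predicted.
#'
#' @param pred,true numeric vectors of equal length (>= 3, nonzero
#'   variances for the correlation).
#' @param top_n group size for [rank_accuracy()] (default 100).
#' @param rank_method passed to [rank_accuracy()].
#' @param method optional method label carried into the result.
#' @return one-row data.frame: `method`, `correlation`, `mse`, `rank`,
#'   `regression`.
#' @export
gebv_accuracy <- function(pred, true, top_n = 100,
                          rank_method = "overlap", method = NA_character_) {
  stopifnot(length(pred) == length(true))
  if (length(pred) < 3) stop("need at least 3 animals")
  if (stats::var(pred) == 0 || stats::var(true) == 0)
    stop("zero variance: correlation undefined")
  data.frame(method = method,
             correlation = stats::cor(pred, true),
             mse = mean((pred - true)^2),
             rank = rank_accuracy(pred, true, top_n, rank_method),
             regression = bias_slope(pred, true))
}

#' Between-method GEBV correlation matrix
#'
#' Pairwise Pearson correlations between the GEBV produced by different
#' methods for the same animals.
#'
#' @param gebv_by_method named list of numeric vectors, one per method, each
#'   named by animal id (or all unnamed with equal lengths).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
method_correlation_matrix <- function(gebv_by_method) {
  stopifnot(is.list(gebv_by_method), length(gebv_by_method) >= 2)
  lens <- lengths(gebv_by_method)
  if (length(unique(lens)) != 1)
    stop("misaligned animal sets: GEBV vectors differ in length")
  nms <- lapply(gebv_by_method, names)
  has_names <- !vapply(nms, is.null, logical(1))
  if (any(has_names)) {
    if (!all(has_names))
      stop("misaligned animal sets: mix of named and unnamed GEBV vectors")
    ref <- nms[[1]]
    ok <- vapply(nms, function(x) identical(x, ref), logical(1))
    if (!all(ok))
      stop("misaligned animal sets: GEBV vectors name different animals")
  }
  M <- do.call(cbind, gebv_by_method)
  stats::cor(M)
}

#' Sensitivity of Bayes C accuracy to the mixture proportion pi
#'
#' Refits Bayes C over a grid of prior inclusion probabilities and evaluates
#' the validation-set accuracy at one time point. The default grid is
#' `c(0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 1)`; `pi = 1` puts every SNP in the
#' large-variance component (no selection).
#'
#' @param dataset a `gs_dataset`.
#' @param pi_values grid of mixture proportions.
#' @param chain a [chain_config()].
#' @param timepoint day at which to fit and evaluate; defaults to the last
#'   phenotyped time point. If equal to the dataset's extrapolation point,
#'   all phenotyped time points are fitted per pi and the extrapolated GEBV
#'   is evaluated instead.
#' @param prior base [prior_spec()]; its `pi` is replaced per grid point.
#' @param polygenic include the pedigree polygenic term (default `TRUE`).
#' @param top_n rank-accuracy group size, capped at the validation-set size.
#' @param seeds optional vector of chain seeds, one per pi value.
#' @return data.frame with one row per pi: `pi`, `correlation`, `mse`,
#'   `rank`, `regression`.
#' @export
pi_sweep <- function(dataset, pi_values = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 1),
                     chain = chain_config(), timepoint = NULL,
                     prior = prior_spec(), polygenic = TRUE, top_n = 100,
                     seeds = NULL) {
  tp <- dataset$config$time_points
  xp <- dataset$config$extrapolation_point
  if (is.null(timepoint)) timepoint <- tp[length(tp)]
  val <- !dataset$pedigree$phenotyped
  if (!any(val)) stop("dataset has no validation animals")
  top_n <- min(top_n, sum(val))
  ainv <- if (polygenic) pedigree_ainverse(dataset$pedigree) else NULL

  rows <- lapply(seq_along(pi_values), function(i) {
    pv <- pi_values[i]
    pr <- prior
    pr$pi <- pv
    ch <- chain
    if (!is.null(seeds)) ch$seed <- seeds[i]
    if (identical(timepoint, xp)) {
      fits <- lapply(tp, function(t) fit_timepoint(
        dataset, t, "bayesC", pr, ch, polygenic = polygenic, ainv = ainv))
      gt <- gebv_table(dataset, fits)
      pred <- gt[[paste0("gebv_t", xp)]][val]
      true <- dataset$truth$tbv[val, paste0("t", xp)]
    } else {
      fit <- fit_timepoint(dataset, timepoint, "bayesC", pr, ch,
                           polygenic = polygenic, ainv = ainv)
      pred <- compute_gebv(dataset$genotypes, fit)[val]
      true <- dataset$truth$tbv[val, paste0("t", timepoint)]
    }
    cbind(pi = pv, gebv_accuracy(pred, true, top_n = top_n)[-1])
  })
  do.call(rbind, rows)
}
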