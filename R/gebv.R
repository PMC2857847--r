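# Genomic estimated breeding values: marker-effect sums per time point and
# per-animal linear extrapolation of the time series to an unobserved day.

#' Compute GEBV from posterior marker effects
#'
#' `GEBV_i = sum_j x_ij * beta_hat_j` over raw 0/1/2 codes, using the
#' posterior-mean effects. The polygenic posterior mean can be added for
#' completeness, but is excluded by default (the validation truth of the
#' emulated dataset is marker-determined).
#'
#' @param genotypes animals x SNPs matrix of 0/1/2 codes (all animals,
#'   including unphenotyped ones).
#' @param fit a `gs_fit`, or a bare numeric vector of marker effects.
#' @param include_polygenic add the posterior-mean polygenic effect `u`
#'   (requires a `gs_fit` with a polygenic term; animals are matched by row
#'   position in the pedigree used to build A).
#' @return named numeric vector of GEBV (names = rownames of `genotypes`).
#' @export
compute_gebv <- function(genotypes, fit, include_polygenic = FALSE) {
  genotypes <- as.matrix(genotypes)
  if (anyNA(genotypes))
    stop("genotype matrix contains missing codes; imputation is out of scope")
  beta <- if (inherits(fit, "gs_fit")) fit$beta else as.numeric(fit)
  if (length(beta) != ncol(genotypes))
    stop("length of effects does not match number of SNPs")
  g <- as.numeric(genotypes %*% beta)
  if (include_polygenic) {
    if (!inherits(fit, "gs_fit") || length(fit$u) == 0)
      stop("include_polygenic requires a fit with a polygenic term")
    if (length(fit$u) != nrow(genotypes))
      stop("polygenic vector length does not match the animals supplied")
    g <- g + fit$u
  }
  names(g) <- rownames(genotypes)
  g
}

#' Extrapolate GEBV to an unobserved time point by per-animal OLS
#'
#' Fits an ordinary least-squares line through each animal's GEBV at the
#' observed time points and evaluates it at `target`. With the default
#' abscissae `(265, 397, 530)` and target 600 this reproduces the linear
#' extrapolation used to predict breeding values on the linear segment of a
#' growth curve. Exact (to floating point) for inputs lying on a line, and
#' affine-equivariant.
#'
#' @param gebv matrix (animals x time points) or data.frame of GEBV.
#' @param time_points abscissae (default `c(265, 397, 530)`), matching the
#'   columns of `gebv`.
#' @param target day to extrapolate to (default 600).
#' @return numeric vector of extrapolated GEBV; rows with any non-finite
#'   input give `NA` with a warning.
#' @export
extrapolate_gebv <- function(gebv, time_points = c(265, 397, 530),
                             target = 600) {
  g <- as.matrix(gebv)
  if (ncol(g) != length(time_points))
    stop("gebv must have one column per time point")
  if (length(time_points) < 2) stop("need at least two time points")
  bad <- !apply(is.finite(g), 1, all)
  if (any(bad)) {
    warning(sum(bad), " animal(s) with non-finite GEBV propagated as NA")
  }
  tbar <- mean(time_points)
  tc <- time_points - tbar
  sxx <- sum(tc^2)
  slope <- as.numeric(g %*% tc) / sxx
  out <- rowMeans(g) + slope * (target - tbar)
  out[bad] <- NA_real_
  names(out) <- rownames(g)
  out
}

#' GEBV table across time points for one method
#'
#' Computes per-animal GEBV at every phenotyped time point from a list of
#' per-time-point fits and appends the extrapolated value at the dataset's
#' extrapolation point.
#'
#' @param dataset a `gs_dataset`.
#' @param fits list of `gs_fit` objects, one per phenotyped time point, in
#'   time order (as returned by [fit_timepoint()]).
#' @param include_polygenic passed to [compute_gebv()]; polygenic effects are
#'   available for all pedigree animals.
#' @return data.frame: `id`, one `gebv_t<day>` column per time point, and
#'   `gebv_t<extrapolation day>`.
#' @export
gebv_table <- function(dataset, fits, include_polygenic = FALSE) {
  tp <- dataset$config$time_points
  if (length(fits) != length(tp))
    stop("need one fit per phenotyped time point")
  G <- sapply(fits, function(f)
    compute_gebv(dataset$genotypes, f, include_polygenic = include_polygenic))
  colnames(G) <- paste0("gebv_t", tp)
  g600 <- extrapolate_gebv(G, time_points = tp,
                           target = dataset$config$extrapolation_point)
  out <- data.frame(id = dataset$pedigree$id, G,
                    extra = g600, check.names = FALSE)
  names(out)[ncol(out)] <- paste0("gebv_t", dataset$config$extrapolation_point)
  out
}
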