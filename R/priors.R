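#' Scaled inverse-chi-squared draws
#'
#' Draws from the scaled inverse-chi-squared distribution in the
#' sum-of-squares parametrization used by all variance updates in this
#' package: a draw is `ss / rchisq(df)`, with mean `ss / (df - 2)` for
#' `df > 2`. Under a normal likelihood this family is conjugate with simple
#' additive updating: observing a squared deviation `d2` turns
#' ScInvChi2(df, ss) into ScInvChi2(df + 1, ss + d2), so the flat
#' chi^-2(-2, 0) prior on a variance composed with n residual terms yields
#' ScInvChi2(n - 2, SSE).
#'
#' @param n number of draws.
#' @param df degrees of freedom (> 0).
#' @param ss sum-of-squares scale (>= 0).
#' @return numeric vector of `n` positive draws.
#' @export
rscinvchisq <- function(n, df, ss) {
  stopifnot(df > 0, ss >= 0)
  ss / stats::rchisq(n, df)
}

#' Prior hyperparameters for the SNP-effect variance
#'
#' Computes the scale `S` of the per-SNP scaled inverse-chi-squared prior so
#' that its mean equals the per-SNP variance implied by an assumed total
#' additive genetic variance, following the construction of Meuwissen-style
#' whole-genome regression: the assumed genetic variance is spread over the
#' SNPs expected to carry an effect, discounted by the average marker
#' heterozygosity contribution `2*p*q`.
#'
#' The implied per-SNP effect variance is
#' `sigma_tilde2 = genetic_variance / (n_snp * nonzero_fraction * mean_2pq)`
#' and `S = sigma_tilde2 * (nu - 2)`, so that the prior mean
#' `S / (nu - 2)` equals `sigma_tilde2` exactly.
#'
#' @param genetic_variance assumed total additive genetic variance
#'   (trait units squared).
#' @param n_snp number of markers p.
#' @param nonzero_fraction expected fraction of markers with nonzero effect
#'   (1 for BLUP / Bayes A; the mixture proportion pi for the mixture models).
#' @param mean_2pq average `2*p*q` over the marker set; computed from a
#'   genotype matrix with [mean_het()].
#' @param nu prior degrees of freedom (> 2; default 4.012).
#' @return list with `sigma_tilde2` and `S`.
#' @export
compute_hyperparameters <- function(genetic_variance, n_snp,
                                    nonzero_fraction = 1, mean_2pq = 0.5,
                                    nu = 4.012) {
  if (nu <= 2) stop("nu must exceed 2: the prior mean is undefined otherwise")
  stopifnot(genetic_variance > 0, n_snp > 0,
            nonzero_fraction > 0, nonzero_fraction <= 1, mean_2pq > 0)
  sigma_tilde2 <- genetic_variance / (n_snp * nonzero_fraction * mean_2pq)
  list(sigma_tilde2 = sigma_tilde2, S = sigma_tilde2 * (nu - 2))
}

#' Average marker heterozygosity contribution
#'
#' Mean over markers of `2*p*q`, with allele frequency `p` estimated from
#' 0/1/2 genotype codes.
#'
#' @param genotypes n x p matrix of 0/1/2 codes.
#' @return scalar mean of `2*p*q`.
#' @export
mean_het <- function(genotypes) {
  p_hat <- colMeans(genotypes) / 2
  mean(2 * p_hat * (1 - p_hat))
}

#' Prior specification for a whole-genome regression fit
#'
#' @param nu degrees of freedom of the scaled inverse-chi-squared prior on
#'   SNP-effect variances (> 2; default 4.012).
#' @param S prior scale (sum-of-squares parametrization). `NULL` means
#'   compute it from the data at fit time via [compute_hyperparameters()],
#'   using `h2_guess`.
#' @param pi mixture proportion: prior probability that a SNP carries a
#'   nonzero (Bayes A/B) or large-component (Bayes C) effect. Default 0.05.
#' @param c Bayes C ratio of the "near zero" to the "large" effect variance
#'   (in (0,1]; default 0.01; `c = 1` makes the components identical, a
#'   degenerate case useful for validation).
#' @param k Bayes A/B: number of Bayes A iterations between reversible-jump
#'   sweeps (default 10).
#' @param m Bayes A/B: reversible-jump proposals per SNP per sweep
#'   (default 5).
#' @param h2_guess heritability guess used to set the assumed genetic
#'   variance (`var(y) * h2_guess`) when `S` is computed from data.
#' @return object of class `gs_prior`.
#' @export
prior_spec <- function(nu = 4.012, S = NULL, pi = 0.05, c = 0.01,
                       k = 10, m = 5, h2_guess = 0.5) {
  if (nu <= 2) stop("nu must exceed 2")
  if (!is.null(S) && S <= 0) stop("S must be positive")
  if (pi <= 0 || pi > 1) stop("pi must be in (0, 1]")
  if (c <= 0 || c > 1) stop("c must be in (0, 1]")
  if (k < 1 || m < 1) stop("k and m must be >= 1")
  if (h2_guess <= 0 || h2_guess >= 1) stop("h2_guess must be in (0, 1)")
  structure(list(nu = nu, S = S, pi = pi, c = c, k = as.integer(k),
                 m = as.integer(m), h2_guess = h2_guess),
            class = "gs_prior")
}

#' MCMC chain configuration
#'
#' @param n_iter total iterations (default 30000).
#' @param burn_in iterations discarded (default 10000; must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @param seed optional integer seed set before the chain runs.
#' @return object of class `gs_chain`.
#' @export
chain_config <- function(n_iter = 30000, burn_in = 10000, thin = 1,
                         seed = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "gs_chain")
}
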