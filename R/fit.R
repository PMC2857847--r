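# Front end to the MCMC engine: one call fits one method to one trait
# (one time point), with an optional pedigree polygenic term.

method_code <- function(method) {
  m <- match.arg(method, c("blup", "bayesA", "bayesAB", "bayesC"))
  c(blup = 0L, bayesA = 1L, bayesAB = 2L, bayesC = 3L)[[m]]
}

#' Fit a Bayesian whole-genome regression model by MCMC
#'
#' Runs the Gibbs (and, for `bayesAB`, reversible-jump) sampler for the model
#' `y = 1 mu + X beta + Z u + e` with `u ~ N(0, A sigma2_u)`,
#' `e ~ N(0, I sigma2_e)`, flat chi^-2(-2, 0) priors on `sigma2_u` and
#' `sigma2_e`, and the method-specific prior on `beta`:
#'
#' * `blup`: all effects share one normal variance, itself sampled once per
#'   iteration (infinitesimal-model analogue).
#' * `bayesA`: per-SNP scaled inverse-chi-squared variances (marginal t
#'   prior on effects).
#' * `bayesAB`: Bayes A, plus a reversible-jump sweep every `k` iterations
#'   with `m` in/out Metropolis-Hastings proposals per SNP and prior
#'   inclusion probability `pi`; excluded SNPs are held at exactly zero
#'   between sweeps.
#' * `bayesC`: stochastic search variable selection; an indicator sampled
#'   from its collapsed Bernoulli conditional assigns each effect to the
#'   large or the near-zero (`c` times smaller) variance component.
#'
#' @param y numeric response (one record per animal; no NAs).
#' @param X genotype design matrix, animals x SNPs, codes 0/1/2. Raw codes
#'   are used by default (the intercept absorbs the difference); set
#'   `center = TRUE` to column-center.
#' @param method one of `"blup"`, `"bayesA"`, `"bayesAB"`, `"bayesC"`.
#' @param prior a [prior_spec()]. If `prior$S` is `NULL` it is computed from
#'   the data via [compute_hyperparameters()] with assumed genetic variance
#'   `var(y) * h2_guess` and nonzero fraction 1 (`blup`, `bayesA`) or `pi`
#'   (mixture methods).
#' @param chain a [chain_config()].
#' @param ainv optional sparse A-inverse (a `dgCMatrix` from
#'   [pedigree_ainverse()]) enabling the polygenic term.
#' @param obs_ped integer vector mapping each element of `y` to its row in
#'   `ainv` (1-based); required with `ainv`.
#' @param center column-center `X` before sampling (default `FALSE`).
#' @param verbose print chain state every 1000 iterations.
#' @param options list of expert overrides for the sampler, merged over the
#'   defaults: `update_mu`, `mu_init`, `fix_sigma2_e`, `sigma2_e_init`,
#'   `fix_sigma2_beta`, `sigma2_beta_init`, `fix_sigma2_u`, `sigma2_u_init`,
#'   `var_floor` (default 1e-10). Mainly for oracle tests on toy models.
#' @return object of class `gs_fit`: posterior means (`mu`, `beta`, `u`,
#'   `sigma2_e`, `sigma2_u`, `sigma2_beta`), posterior variances (`beta_var`,
#'   `mu_var`), per-SNP `inclusion` probabilities, scalar `trace`, 20-batch
#'   `batch_means` for Monte-Carlo standard errors, and the residual-cache
#'   consistency diagnostic `max_resid_dev`.
#' @export
gs_fit <- function(y, X, method = c("blup", "bayesA", "bayesAB", "bayesC"),
                   prior = prior_spec(), chain = chain_config(),
                   ainv = NULL, obs_ped = NULL, center = FALSE,
                   verbose = FALSE, options = list()) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "gs_prior"), inherits(chain, "gs_chain"))
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must not contain NAs; subset to phenotyped animals")
  if (is.null(X)) X <- matrix(0, length(y), 0)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X)) stop("genotype matrix contains missing codes; ",
                     "imputation is out of scope")

  col_means <- NULL
  if (center && ncol(X) > 0) {
    col_means <- colMeans(X)
    X <- sweep(X, 2, col_means)
  }

  opts <- list(update_mu = TRUE, mu_init = 0,
               fix_sigma2_e = FALSE, sigma2_e_init = stats::var(y) / 2,
               fix_sigma2_beta = FALSE, sigma2_beta_init = NA_real_,
               fix_sigma2_u = FALSE, sigma2_u_init = -1,
               var_floor = 1e-10, verbose = verbose)
  opts[names(options)] <- options

  nonzero_frac <- if (method %in% c("bayesAB", "bayesC")) prior$pi else 1
  S <- prior$S
  if (is.null(S)) {
    vg <- stats::var(y) * prior$h2_guess
    m2pq <- if (ncol(X) > 0) {
      # heterozygosity from the (possibly centered) codes' variance proxy:
      # use raw codes when available
      if (is.null(col_means)) mean_het(X) else
        mean(2 * (col_means / 2) * (1 - col_means / 2))
    } else 0.5
    hp <- compute_hyperparameters(vg, max(ncol(X), 1), nonzero_frac,
                                  mean_2pq = max(m2pq, 1e-6), nu = prior$nu)
    S <- hp$S
  }
  if (is.na(opts$sigma2_beta_init)) opts$sigma2_beta_init <- S / (prior$nu - 2)

  if (!is.null(ainv)) {
    ainv <- as(ainv, "CsparseMatrix")
    if (is.null(obs_ped) || length(obs_ped) != length(y))
      stop("obs_ped must map every record to a row of ainv")
    n_ped <- nrow(ainv)
    ai_i <- ainv@i; ai_p <- ainv@p; ai_x <- ainv@x
    obs0 <- as.integer(obs_ped) - 1L
    if (opts$sigma2_u_init <= 0) opts$sigma2_u_init <- stats::var(y) / 4
  } else {
    n_ped <- 0L
    ai_i <- integer(0); ai_p <- integer(0); ai_x <- numeric(0)
    obs0 <- integer(0)
  }

  if (!is.null(chain$seed)) set.seed(chain$seed)
  res <- gs_mcmc_cpp(y, X, method_code(method),
                     prior$nu, S, prior$pi, prior$c, prior$k, prior$m,
                     ai_i, ai_p, ai_x, obs0, n_ped,
                     chain$n_iter, chain$burn_in, chain$thin, opts)

  structure(c(res, list(method = method, prior = prior, chain = chain,
                        S_used = S, center = center, col_means = col_means,
                        n_obs = length(y), n_snp = ncol(X))),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("gs_fit:", x$method, "|", x$n_obs, "records,", x$n_snp, "SNPs\n")
  cat(sprintf("  posterior means: mu=%.4f sigma2_e=%.4f sigma2_u=%s\n",
              x$mu, x$sigma2_e,
              if (is.na(x$sigma2_u)) "-" else sprintf("%.4f", x$sigma2_u)))
  cat(sprintf("  retained samples: %d | max residual-cache deviation: %.2e\n",
              x$n_samples, x$max_resid_dev))
  invisible(x)
}

#' Fit one method to one time point of a simulated dataset
#'
#' Convenience wrapper: extracts the phenotyped animals' records at one time
#' point, fits [gs_fit()] with the pedigree polygenic term, and records the
#' time point on the result. Each time point is modelled as a separate trait.
#'
#' @param dataset a `gs_dataset` from [sim_dataset()].
#' @param timepoint one of the dataset's phenotyped time points (a day).
#' @param method,prior,chain,center,verbose,options passed to [gs_fit()].
#' @param polygenic include the pedigree polygenic term (default `TRUE`).
#' @param ainv optional precomputed [pedigree_ainverse()] to reuse across
#'   fits.
#' @return a `gs_fit` with `timepoint` attached.
#' @export
fit_timepoint <- function(dataset, timepoint,
                          method = c("blup", "bayesA", "bayesAB", "bayesC"),
                          prior = prior_spec(), chain = chain_config(),
                          polygenic = TRUE, ainv = NULL, center = FALSE,
                          verbose = FALSE, options = list()) {
  method <- match.arg(method)
  col <- paste0("t", timepoint)
  if (!col %in% names(dataset$phenotypes))
    stop("no phenotypes at time point ", timepoint)
  y_all <- dataset$phenotypes[[col]]
  obs <- which(!is.na(y_all))
  y <- y_all[obs]
  X <- dataset$genotypes[obs, , drop = FALSE]
  if (polygenic) {
    if (is.null(ainv)) ainv <- pedigree_ainverse(dataset$pedigree)
    fit <- gs_fit(y, X, method, prior, chain, ainv = ainv, obs_ped = obs,
                  center = center, verbose = verbose, options = options)
  } else {
    fit <- gs_fit(y, X, method, prior, chain, center = center,
                  verbose = verbose, options = options)
  }
  fit$timepoint <- timepoint
  fit$obs_ids <- dataset$pedigree$id[obs]
  fit
}
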