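# Shared test helpers: independent oracles and small fixtures, all built in
# code at test time.

# Recursive (memoized, top-down) additive relationship oracle, an independent
# implementation against the bottom-up tabular build_A().
kinship_oracle <- function(pedigree) {
  id <- pedigree$id
  si <- match(pedigree$sire, id, nomatch = 0L)
  di <- match(pedigree$dam, id, nomatch = 0L)
  n <- length(id)
  memo <- matrix(NA_real_, n, n)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == j) {
      1 + 0.5 * (if (si[i] > 0L && di[i] > 0L) a(si[i], di[i]) else 0)
    } else {
      lo <- min(i, j); hi <- max(i, j)
      0.5 * (a(lo, si[hi]) + a(lo, di[hi]))
    }
    memo[i, j] <<- val
    memo[j, i] <<- val
    val
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) out[i, j] <- out[j, i] <- a(i, j)
  dimnames(out) <- list(id, id)
  out
}

# Random ordered pedigree of n animals: founders, one-parent and two-parent
# records all occur.
random_pedigree <- function(n) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= 2 || runif(1) < 0.3) next # founder
    prev <- seq_len(i - 1)
    pick <- sample(prev, min(2, length(prev)))
    if (length(pick) == 2 && runif(1) < 0.85) {
      sire[i] <- pick[1]; dam[i] <- pick[2]
    } else if (runif(1) < 0.5) {
      sire[i] <- pick[1]
    } else {
      dam[i] <- pick[1]
    }
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam)
}

# Multivariate normal log-density at zero mean.
ldmvnorm0 <- function(y, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Exact posterior inclusion probabilities for a spike/slab or SSVS toy model
# by enumeration over all indicator configurations, with SNP effects
# integrated out (Gaussian marginal likelihood). v_in / v_out are the effect
# variances of the two components (v_out = 0 for true in/out selection).
enumerate_inclusion <- function(y, X, se2, v_in, v_out, pi) {
  p <- ncol(X)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- apply(configs, 1, function(g) {
    V <- ifelse(g == 1, v_in, v_out)
    Sigma <- diag(se2, length(y))
    for (j in seq_len(p))
      if (V[j] > 0) Sigma <- Sigma + V[j] * tcrossprod(X[, j])
    ldmvnorm0(y, Sigma) + sum(g) * log(pi) + (p - sum(g)) * log(1 - pi)
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(colSums(configs * w))
}

# Monte-Carlo standard error of a posterior mean from 20 batch means.
bm_se <- function(batch_means) {
  sd(batch_means) / sqrt(length(batch_means))
}

# Small simulated dataset for pipeline-level tests.
tiny_config <- function(...) {
  sim_config(n_founders = 40, n_generations = 2, family_size = 8,
             n_validation_families = 10, n_snp = 50, n_qtl = 6, ...)
}
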