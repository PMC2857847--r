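# Gene-drop simulator of QTL-MAS-style genomic selection datasets:
# a pedigreed population genotyped at p unlinked SNPs, a finite set of QTL
# among them with effects that change linearly over a set of time points on
# the linear segment of a growth curve, phenotypes at those time points for
# the training generations, and a final generation of full-sib families that
# carries genotypes but no phenotypes (the validation set). True breeding
# values are known for all animals including an extrapolation time point
# (day 600), so prediction accuracy can be measured exactly.

#' Simulation configuration
#'
#' Defaults emulate the structure of the 13th QTL-MAS workshop dataset as far
#' as it is publicly described: 435 SNPs, 21 QTL, the largest QTL explaining
#' 10.5% of the genetic variance, phenotypes at days 265/397/530 on the
#' linear part of a growth curve, and a validation set of 50 full-sib
#' families without phenotypes. Population counts (founders, generations,
#' family size) are not publicly stated for the workshop data; the defaults
#' are free choices giving roughly 2,000 phenotyped training animals
#' (100 founders plus three bred generations of 50 families x 13), with a
#' final unphenotyped generation of 50 full-sib families as validation set.
#'
#' @param n_founders number of unrelated founders (half sires, half dams).
#' @param n_generations number of bred generations; the last one is the
#'   unphenotyped validation generation. `0` gives a founders-only pedigree.
#' @param family_size offspring per full-sib family.
#' @param n_validation_families full-sib families in every bred generation,
#'   including the final validation generation (default 50).
#' @param n_snp number of typed SNPs (default 435).
#' @param n_qtl number of QTL (default 21; must not exceed `n_snp`).
#' @param max_qtl_variance_share target share of genetic variance explained
#'   by the largest single QTL (default 0.105).
#' @param heritability narrow-sense heritability of each time point's trait
#'   (in (0,1); default 0.5).
#' @param time_points phenotyped days, strictly increasing, length >= 2
#'   (default `c(265, 397, 530)`).
#' @param extrapolation_point unphenotyped day at which true breeding values
#'   are also recorded (default 600).
#' @param mu_intercept,mu_slope population mean growth line
#'   `mu(t) = mu_intercept + mu_slope * t` (trait units).
#' @param qtl_typed if `TRUE` (default) QTL are typed SNP columns; if
#'   `FALSE`, QTL are hidden loci in LD with a typed SNP (the typed column is
#'   a noisy copy of the causal one).
#' @param ld_noise per-gamete allele flip rate linking a hidden QTL to its
#'   typed proxy when `qtl_typed = FALSE` (default 0.05).
#' @param seed optional root seed stored with the config.
#' @return object of class `gs_sim_config`.
#' @export
sim_config <- function(n_founders = 100, n_generations = 4, family_size = 13,
                       n_validation_families = 50, n_snp = 435, n_qtl = 21,
                       max_qtl_variance_share = 0.105, heritability = 0.5,
                       time_points = c(265, 397, 530),
                       extrapolation_point = 600,
                       mu_intercept = 1, mu_slope = 0.025,
                       qtl_typed = TRUE, ld_noise = 0.05, seed = NULL) {
  if (n_founders < 2) stop("impossible structure: need at least 2 founders")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (family_size < 1 || n_validation_families < 1)
    stop("family_size and n_validation_families must be >= 1")
  if (n_qtl > n_snp) stop("n_qtl must not exceed n_snp")
  if (n_qtl < 1) stop("n_qtl must be >= 1")
  if (max_qtl_variance_share <= 0 || max_qtl_variance_share >= 1)
    stop("max_qtl_variance_share must be in (0, 1)")
  if (n_qtl == 1 && max_qtl_variance_share < 1)
    stop("with a single QTL its variance share is necessarily 1; ",
         "a cap below 1 cannot be met")
  if (heritability <= 0 || heritability >= 1)
    stop("heritability must be in (0, 1)")
  if (length(time_points) < 2 || any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing with length >= 2")
  if (ld_noise < 0 || ld_noise >= 0.5) stop("ld_noise must be in [0, 0.5)")
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 family_size = as.integer(family_size),
                 n_validation_families = as.integer(n_validation_families),
                 n_snp = as.integer(n_snp), n_qtl = as.integer(n_qtl),
                 max_qtl_variance_share = max_qtl_variance_share,
                 heritability = heritability, time_points = time_points,
                 extrapolation_point = extrapolation_point,
                 mu_intercept = mu_intercept, mu_slope = mu_slope,
                 qtl_typed = qtl_typed, ld_noise = ld_noise, seed = seed),
            class = "gs_sim_config")
}

#' Simulate a multi-generation pedigree with full-sib families
#'
#' Founders are unrelated with unknown parents. Every bred generation
#' consists of `n_validation_families` full-sib families of `family_size`
#' offspring, with sires and dams drawn from the previous generation (dams
#' without replacement, so families are distinct). All animals are phenotyped
#' except the final bred generation, which is the validation set.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `gs_pedigree` with columns `id`, `sire`,
#'   `dam` (0 = unknown), `generation`, `sex` ("M"/"F"), `family`
#'   (NA for founders), `phenotyped` (logical). Parents always precede
#'   offspring.
#' @export
sim_pedigree <- function(config) {
  stopifnot(inherits(config, "gs_sim_config"))
  nf <- config$n_founders
  sex <- rep(c("M", "F"), length.out = nf)
  ped <- data.frame(id = seq_len(nf), sire = 0L, dam = 0L, generation = 0L,
                    sex = sex, family = NA_integer_, phenotyped = TRUE)
  if (config$n_generations == 0) {
    warning("n_generations = 0: founders only, no validation set")
    class(ped) <- c("gs_pedigree", "data.frame")
    return(ped)
  }
  fam_counter <- 0L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires_pool <- prev$id[prev$sex == "M"]
    dams_pool <- prev$id[prev$sex == "F"]
    n_fam <- config$n_validation_families
    if (length(sires_pool) < 1 || length(dams_pool) < n_fam)
      stop("impossible structure: generation ", g - 1L, " has too few ",
           "parents for ", n_fam, " distinct full-sib families")
    sires <- sample(sires_pool, n_fam, replace = TRUE)
    dams <- sample(dams_pool, n_fam, replace = FALSE)
    next_id <- max(ped$id)
    n_off <- n_fam * config$family_size
    fam_ids <- rep(fam_counter + seq_len(n_fam), each = config$family_size)
    offspring <- data.frame(
      id = next_id + seq_len(n_off),
      sire = rep(sires, each = config$family_size),
      dam = rep(dams, each = config$family_size),
      generation = g,
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      family = fam_ids,
      phenotyped = g < config$n_generations)
    fam_counter <- fam_counter + n_fam
    ped <- rbind(ped, offspring)
  }
  class(ped) <- c("gs_pedigree", "data.frame")
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn per locus from allele frequencies sampled
#' uniformly on (0.05, 0.95); each non-founder receives one allele from each
#' parent by Mendelian sampling, loci transmitted independently (unlinked).
#'
#' @param pedigree a [sim_pedigree()] result (parents before offspring).
#' @param config a [sim_config()].
#' @param founder_freq optional length-`n_snp` vector of founder allele
#'   frequencies overriding the uniform draw (useful for degenerate tests).
#' @return integer matrix (animals x SNPs) of 0/1/2 codes with animal ids as
#'   rownames; attribute `freq` holds the founder allele frequencies and
#'   attribute `haplotypes` the two gamete matrices.
#' @export
sim_genotypes <- function(pedigree, config, founder_freq = NULL) {
  stopifnot(inherits(pedigree, "gs_pedigree"))
  n <- nrow(pedigree)
  p <- config$n_snp
  freq <- if (is.null(founder_freq)) runif(p, 0.05, 0.95) else {
    stopifnot(length(founder_freq) == p)
    founder_freq
  }
  h1 <- matrix(0L, n, p)
  h2 <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]
    d <- pedigree$dam[i]
    if (s == 0L && d == 0L) {
      h1[i, ] <- rbinom(p, 1L, freq)
      h2[i, ] <- rbinom(p, 1L, freq)
    } else {
      if (s == 0L || d == 0L)
        stop("gene drop requires both parents known or both unknown")
      si <- match(s, pedigree$id)
      di <- match(d, pedigree$id)
      if (si >= i || di >= i)
        stop("pedigree is not sorted parents-first; topologically sort it")
      pick_s <- runif(p) < 0.5
      pick_d <- runif(p) < 0.5
      h1[i, ] <- ifelse(pick_s, h1[si, ], h2[si, ])
      h2[i, ] <- ifelse(pick_d, h1[di, ], h2[di, ])
    }
  }
  G <- h1 + h2
  rownames(G) <- pedigree$id
  attr(G, "freq") <- freq
  attr(G, "haplotypes") <- list(h1 = h1, h2 = h2)
  G
}

#' Assign time-varying QTL effects with a capped largest-QTL share
#'
#' Chooses `n_qtl` polymorphic SNP columns without replacement and assigns
#' each an additive effect that changes linearly across time points:
#' `beta_j(t) = b_j * (1 + s_j * (t - t_mid) / range(t))`. Effects are then
#' iteratively rescaled so that at the middle time point the realized share
#' of genetic variance explained by the largest single QTL equals
#' `max_qtl_variance_share` within +/- 0.01 (shares are computed from the
#' realized genotype counts, so linkage between family members is accounted
#' for in the total).
#'
#' @param genotypes matrix from [sim_genotypes()] (or the hidden causal
#'   genotypes when QTL are untyped).
#' @param config a [sim_config()].
#' @return list of class `gs_truth` with `qtl_idx`, `qtl_base`, `qtl_slope`,
#'   `effects_at()` is available via [qtl_effects_at()]; `qtl_effects` is the
#'   n_qtl x n_timepoints matrix at the phenotyped time points.
#' @export
sim_qtl_effects <- function(genotypes, config) {
  v <- apply(genotypes, 2, stats::var)
  candidates <- which(v > 0)
  if (length(candidates) < config$n_qtl)
    stop("not enough polymorphic SNPs to place ", config$n_qtl, " QTL")
  qtl_idx <- sort(sample(candidates, config$n_qtl))
  b <- rnorm(config$n_qtl)
  while (all(b == 0)) b <- rnorm(config$n_qtl) # at least one nonzero effect
  s <- rnorm(config$n_qtl, 0, 0.15)
  tp <- config$time_points
  t_mid <- tp[ceiling(length(tp) / 2)]
  t_range <- diff(range(tp))

  Xq <- genotypes[, qtl_idx, drop = FALSE]
  target <- config$max_qtl_variance_share
  if (config$n_qtl > 1) {
    for (it in 1:50) {
      tbv_mid <- as.numeric(Xq %*% b) # effects at t_mid equal b
      vg <- stats::var(tbv_mid)
      vj <- b^2 * apply(Xq, 2, stats::var)
      shares <- vj / vg
      jmax <- which.max(shares)
      if (abs(shares[jmax] - target) <= 0.005) break
      lam2 <- target * (vg - vj[jmax]) / (vj[jmax] * (1 - target))
      lam2 <- max(lam2, 1e-6)
      b[jmax] <- b[jmax] * sqrt(lam2)
    }
  }
  effects_mat <- outer(b, rep(1, length(tp))) *
    (1 + outer(s, (tp - t_mid) / t_range))
  structure(list(qtl_idx = qtl_idx, qtl_base = b, qtl_slope = s,
                 t_mid = t_mid, t_range = t_range,
                 time_points = tp, qtl_effects = effects_mat),
            class = "gs_truth")
}

#' Evaluate QTL effects at arbitrary time points
#'
#' @param truth a `gs_truth` from [sim_qtl_effects()].
#' @param t vector of days.
#' @return n_qtl x length(t) matrix of additive effects.
#' @export
qtl_effects_at <- function(truth, t) {
  outer(truth$qtl_base, rep(1, length(t))) *
    (1 + outer(truth$qtl_slope, (t - truth$t_mid) / truth$t_range))
}

#' Simulate phenotypes and complete the truth set
#'
#' True breeding values are `TBV_i(t) = sum_j x_ij * beta_j(t)`; because each
#' QTL effect is linear in `t`, every animal's TBV is exactly linear over the
#' phenotyped time points and the extrapolation-point truth lies on the same
#' line. Phenotypes are `y_i(t) = mu(t) + TBV_i(t) + e_i(t)` with residual
#' variance set from the heritability and the realized TBV variance of the
#' phenotyped animals. No polygenic effect is simulated. Validation animals
#' keep genotypes but get `NA` phenotypes.
#'
#' @param genotypes causal genotype matrix (animals x SNPs).
#' @param truth a `gs_truth`.
#' @param pedigree the pedigree (for the `phenotyped` flag).
#' @param config a [sim_config()].
#' @param residual_var optional fixed residual variance per time point
#'   (recycled), overriding the heritability-derived value; `0` gives exact
#'   noiseless phenotypes.
#' @return list with `phenotypes` (data.frame `id`, one `t<day>` column per
#'   phenotyped time point, NA for validation animals), `tbv` (matrix with
#'   one column per time point plus the extrapolation point), and
#'   `residual_var` actually used.
#' @export
sim_phenotypes <- function(genotypes, truth, pedigree, config,
                           residual_var = NULL) {
  tp <- config$time_points
  t_all <- c(tp, config$extrapolation_point)
  eff <- qtl_effects_at(truth, t_all)
  Xq <- genotypes[, truth$qtl_idx, drop = FALSE]
  tbv <- Xq %*% eff
  colnames(tbv) <- paste0("t", t_all)
  rownames(tbv) <- pedigree$id

  obs <- pedigree$phenotyped
  h2 <- config$heritability
  ve <- sapply(seq_along(tp), function(j) {
    vg <- stats::var(tbv[obs, j])
    vg * (1 - h2) / h2
  })
  if (!is.null(residual_var)) ve <- rep(residual_var, length.out = length(tp))

  n <- nrow(pedigree)
  pheno <- data.frame(id = pedigree$id)
  for (j in seq_along(tp)) {
    mu_t <- config$mu_intercept + config$mu_slope * tp[j]
    y <- mu_t + tbv[, j] + rnorm(n, 0, sqrt(ve[j]))
    y[!obs] <- NA_real_
    pheno[[paste0("t", tp[j])]] <- y
  }
  list(phenotypes = pheno, tbv = tbv, residual_var = ve)
}

#' Simulate a complete genomic selection dataset
#'
#' Orchestrates [sim_pedigree()], [sim_genotypes()], [sim_qtl_effects()] and
#' [sim_phenotypes()] under one root seed. Each stage runs on its own RNG
#' stream derived from the root seed (four sub-seeds drawn up front), so a
#' dataset is bit-reproducible from `(config, seed)` and changing a later
#' stage's internals does not perturb earlier stages.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (defaults to `config$seed`).
#' @param residual_var optional residual-variance override passed to
#'   [sim_phenotypes()].
#' @return list of class `gs_dataset` with elements `pedigree`, `genotypes`
#'   (typed markers), `phenotypes`, `truth` (with `tbv`, `qtl_idx`,
#'   `qtl_effects`, `residual_var`, and `causal_genotypes` when QTL are
#'   untyped), and `config`.
#' @export
sim_dataset <- function(config = sim_config(), seed = config$seed,
                        residual_var = NULL) {
  if (is.null(seed)) stop("a seed is required for a reproducible dataset")
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4)

  set.seed(stage_seed[1])
  pedigree <- sim_pedigree(config)

  set.seed(stage_seed[2])
  genotypes <- sim_genotypes(pedigree, config)

  causal <- genotypes
  if (!config$qtl_typed) {
    # hidden causal loci: the typed column is a noisy copy of the causal one
    hap <- attr(genotypes, "haplotypes")
    flip1 <- matrix(runif(length(hap$h1)) < config$ld_noise, nrow(hap$h1))
    flip2 <- matrix(runif(length(hap$h2)) < config$ld_noise, nrow(hap$h2))
    typed <- (hap$h1 + flip1) %% 2 + (hap$h2 + flip2) %% 2
    rownames(typed) <- rownames(genotypes)
    attr(typed, "freq") <- attr(genotypes, "freq")
    genotypes <- typed
  }

  set.seed(stage_seed[3])
  truth <- sim_qtl_effects(causal, config)

  set.seed(stage_seed[4])
  ph <- sim_phenotypes(causal, truth, pedigree, config,
                       residual_var = residual_var)

  truth$tbv <- ph$tbv
  truth$residual_var <- ph$residual_var
  if (!config$qtl_typed) truth$causal_genotypes <- causal
  attr(genotypes, "haplotypes") <- NULL

  structure(list(pedigree = pedigree, genotypes = genotypes,
                 phenotypes = ph$phenotypes, truth = truth, config = config),
            class = "gs_dataset")
}

#' @export
print.gs_dataset <- function(x, ...) {
  ped <- x$pedigree
  cat("gs_dataset:", nrow(ped), "animals,", ncol(x$genotypes), "SNPs,",
      length(x$truth$qtl_idx), "QTL\n")
  cat("  phenotyped:", sum(ped$phenotyped),
      " validation:", sum(!ped$phenotyped), "\n")
  cat("  time points:", paste(x$config$time_points, collapse = ", "),
      " extrapolation:", x$config$extrapolation_point, "\n")
  invisible(x)
}

#' Write a dataset to plain-text files
#'
#' Writes `pedigree.tsv` (id, sire, dam, generation, phenotyped),
#' `genotypes.tsv` (id then 0/1/2 codes), `phenotypes.tsv` (id, one column
#' per time point, NA for missing), `truth_tbv.tsv` and `truth_qtl.tsv`.
#'
#' @param dataset a `gs_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(dataset$pedigree, "pedigree.tsv")
  g <- data.frame(id = rownames(dataset$genotypes))
  g <- cbind(g, as.data.frame(unclass(dataset$genotypes[, ,drop = FALSE])))
  names(g) <- c("id", paste0("snp", seq_len(ncol(dataset$genotypes))))
  w(g, "genotypes.tsv")
  w(dataset$phenotypes, "phenotypes.tsv")
  tbv <- data.frame(id = rownames(dataset$truth$tbv), dataset$truth$tbv,
                    check.names = FALSE)
  w(tbv, "truth_tbv.tsv")
  qtl <- data.frame(qtl_idx = dataset$truth$qtl_idx,
                    dataset$truth$qtl_effects, check.names = FALSE)
  names(qtl) <- c("qtl_idx",
                  paste0("eff_t", dataset$config$time_points))
  w(qtl, "truth_qtl.tsv")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth_tbv`,
#'   `truth_qtl` data objects.
#' @export
read_dataset <- function(dir) {
  r <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                     sep = "\t", check.names = FALSE)
  ped <- r("pedigree.tsv")
  class(ped) <- c("gs_pedigree", "data.frame")
  g <- r("genotypes.tsv")
  geno <- as.matrix(g[, -1, drop = FALSE])
  rownames(geno) <- g$id
  tbv <- r("truth_tbv.tsv")
  tbv_m <- as.matrix(tbv[, -1, drop = FALSE])
  rownames(tbv_m) <- tbv$id
  list(pedigree = ped, genotypes = geno, phenotypes = r("phenotypes.tsv"),
       truth_tbv = tbv_m, truth_qtl = r("truth_qtl.tsv"))
}
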