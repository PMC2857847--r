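test_that("pedigree structure matches the design", {
  set.seed(1)
  cfg <- sim_config(n_founders = 150, n_generations = 3, family_size = 20,
                    n_validation_families = 50, n_snp = 20, n_qtl = 3)
  ped <- sim_pedigree(cfg)
  last <- ped[ped$generation == 3, ]
  expect_equal(nrow(last), 50 * 20)
  expect_false(any(last$phenotyped))
  expect_equal(length(unique(last$family)), 50)
  expect_true(all(table(last$family) == 20))
  # all earlier generations are phenotyped
  expect_true(all(ped$phenotyped[ped$generation < 3]))
  # topological order: parent indices precede offspring
  idx <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  expect_true(all(si < idx) && all(di < idx))
})

test_that("a zero-generation config yields founders only", {
  cfg <- sim_config(n_generations = 0, n_founders = 12, n_snp = 10, n_qtl = 2)
  expect_warning(ped <- sim_pedigree(cfg), "founders only")
  expect_equal(nrow(ped), 12)
  expect_true(all(ped$sire == 0 & ped$dam == 0))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_qtl = 50, n_snp = 40), "n_qtl")
  expect_error(sim_config(heritability = 1), "heritability")
  expect_error(sim_config(time_points = c(300, 200)), "increasing")
  expect_error(sim_config(n_founders = 0), "founders")
  expect_error(sim_config(n_qtl = 1, max_qtl_variance_share = 0.5),
               "single QTL")
})

test_that("gene drop is Mendelian-consistent with codes in 0..2", {
  set.seed(2)
  cfg <- sim_config(n_founders = 30, n_generations = 2, family_size = 6,
                    n_validation_families = 8, n_snp = 40, n_qtl = 5)
  ped <- sim_pedigree(cfg)
  G <- sim_genotypes(ped, cfg)
  expect_true(all(G %in% 0:2))
  # a parent with code 0 transmits allele 0; code 2 transmits allele 1:
  # every offspring code must lie within the reachable range
  off <- which(ped$sire > 0)
  lo <- function(code) ifelse(code == 2, 1, 0)
  hi <- function(code) ifelse(code == 0, 0, 1)
  gs <- G[match(ped$sire[off], ped$id), , drop = FALSE]
  gd <- G[match(ped$dam[off], ped$id), , drop = FALSE]
  go <- G[off, , drop = FALSE]
  expect_true(all(go >= lo(gs) + lo(gd)))
  expect_true(all(go <= hi(gs) + hi(gd)))
})

test_that("fixed founder frequency 1 forces genotype code 2 everywhere", {
  set.seed(3)
  cfg <- sim_config(n_founders = 6, n_generations = 1,
                    n_validation_families = 2, family_size = 4,
                    n_snp = 15, n_qtl = 2)
  ped <- sim_pedigree(cfg)
  G <- sim_genotypes(ped, cfg, founder_freq = rep(1, 15))
  expect_true(all(G == 2))
})

test_that("het x het matings segregate 1:2:1", {
  set.seed(4)
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    n_validation_families = 1, family_size = 800,
                    n_snp = 100, n_qtl = 2)
  ped <- sim_pedigree(cfg)
  G <- sim_genotypes(ped, cfg)
  founders <- G[1:2, ]
  hh <- which(founders[1, ] == 1 & founders[2, ] == 1)
  expect_gt(length(hh), 10)
  kids <- G[-(1:2), hh, drop = FALSE]
  n <- length(kids)
  props <- tabulate(as.integer(kids) + 1L, 3) / n
  # multinomial law: 1:2:1; 4-sigma binomial bands
  tol <- 4 * sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / n)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < tol))
})

test_that("largest realized QTL share hits the target within tolerance", {
  for (s in c(5, 6)) {
    ds <- sim_dataset(sim_config(n_founders = 60, n_generations = 2,
                                 family_size = 10, n_validation_families = 15,
                                 n_snp = 200, n_qtl = 21), seed = s)
    Xq <- ds$genotypes[, ds$truth$qtl_idx, drop = FALSE]
    b <- ds$truth$qtl_base
    # independent recomputation from genotype counts at the middle time point
    share <- b^2 * apply(Xq, 2, var) / var(as.numeric(Xq %*% b))
    expect_lt(abs(max(share) - 0.105), 0.01)
  }
})

test_that("phenotypes realize the target heritability and variance budget", {
  ds <- sim_dataset(sim_config(n_founders = 80, n_generations = 3,
                               family_size = 10, n_validation_families = 40,
                               n_snp = 120, n_qtl = 10, heritability = 0.5),
                    seed = 7)
  obs <- ds$pedigree$phenotyped
  expect_gt(sum(obs), 800)
  for (tp in c("t265", "t397", "t530")) {
    y <- ds$phenotypes[[tp]][obs]
    g <- ds$truth$tbv[obs, tp]
    h2_real <- var(g) / var(y)
    expect_lt(abs(h2_real - 0.5), 0.05)
  }
  # variance accounting: var(y) ~ var(TBV) + residual variance
  y <- ds$phenotypes$t397[obs]
  expect_lt(abs(var(y) - var(ds$truth$tbv[obs, "t397"]) -
                  ds$truth$residual_var[2]) / var(y), 0.1)
  # validation animals have genotypes but no phenotypes
  expect_true(all(is.na(ds$phenotypes$t397[!obs])))
  expect_false(anyNA(ds$genotypes))
})

test_that("zero residual variance gives exact phenotypes and TBV lies on a line", {
  cfg <- tiny_config()
  ds <- sim_dataset(cfg, seed = 8, residual_var = 0)
  obs <- ds$pedigree$phenotyped
  mu397 <- cfg$mu_intercept + cfg$mu_slope * 397
  expect_equal(ds$phenotypes$t397[obs],
               unname(mu397 + ds$truth$tbv[obs, "t397"]), tolerance = 1e-12)
  # per-animal line through the three phenotyped time points, evaluated at
  # the extrapolation day, reproduces the stored truth exactly
  tp <- cfg$time_points
  ex <- extrapolate_gebv(ds$truth$tbv[, paste0("t", tp)], tp, 600)
  expect_lt(max(abs(ex - ds$truth$tbv[, "t600"])), 1e-10)
})

test_that("identical seed and config reproduce the dataset bit for bit", {
  cfg <- tiny_config()
  d1 <- sim_dataset(cfg, seed = 99)
  d2 <- sim_dataset(cfg, seed = 99)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth$tbv, d2$truth$tbv)
  d3 <- sim_dataset(cfg, seed = 100)
  expect_false(identical(d1$genotypes, d3$genotypes))
})

test_that("hidden-QTL (LD) mode keeps truth on causal loci", {
  cfg <- tiny_config(qtl_typed = FALSE, ld_noise = 0.1)
  ds <- sim_dataset(cfg, seed = 12)
  expect_false(is.null(ds$truth$causal_genotypes))
  # typed markers differ from causal ones but are correlated with them
  j <- ds$truth$qtl_idx[1]
  r <- cor(ds$genotypes[, j], ds$truth$causal_genotypes[, j])
  expect_gt(r, 0.5)
  expect_lt(r, 1)
})

test_that("dataset round-trips through plain-text files", {
  ds <- sim_dataset(tiny_config(), seed = 13)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(unname(back$genotypes), unname(ds$genotypes),
               ignore_attr = TRUE)
  expect_equal(back$phenotypes$t397, ds$phenotypes$t397)
  expect_equal(unname(back$truth_tbv), unname(ds$truth$tbv))
  expect_equal(back$truth_qtl$qtl_idx, ds$truth$qtl_idx)
})
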