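cfg <- analysis_config()

test_that("paired NB engine sees no effect in identical allelic patterns", {
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  m <- matrix(c(80L, 60L, 80L, 60L), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), sheet$sample_id))
  m[2, ] <- c(40L, 30L, 40L, 30L)
  p <- m %/% 4L  # same maternal:paternal ratio in every sample
  res <- fit_paired_nb(m, p, sheet, cfg, dispersion = 0.05)
  expect_true(all(res$p > 0.5))
  expect_equal(res$df, c(1L, 1L))
})

test_that("in the Poisson limit the paired NB test reduces to the binomial LRT", {
  # sample pairing factors make totals ancillary, so with dispersion -> 0 the
  # allele x genotype LRT must agree with a logistic regression on proportions
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  m <- matrix(c(90L, 70L, 55L, 60L), 1, 4,
              dimnames = list("g", sheet$sample_id))
  p <- matrix(c(10L, 12L, 45L, 35L), 1, 4,
              dimnames = list("g", sheet$sample_id))
  res <- fit_paired_nb(m, p, sheet, cfg, dispersion = 0)
  oracle <- oracle_binom_lrt(m[1, ], p[1, ], sheet$genotype)
  expect_equal(res$p, oracle$p, tolerance = 1e-6)
  expect_equal(res$lrt_statistic, oracle$stat, tolerance = 1e-6)
})

test_that("paired NB maximized likelihood matches an independent NB fit", {
  # one gene, four samples: edgeR's Levenberg fit vs stats::glm IRLS with a
  # negative-binomial family at the same fixed dispersion
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  m <- matrix(c(90L, 70L, 55L, 60L), 1, 4,
              dimnames = list("g", sheet$sample_id))
  p <- matrix(c(10L, 12L, 45L, 35L), 1, 4,
              dimnames = list("g", sheet$sample_id))
  disp <- 0.1
  y <- c(m[1, ], p[1, ])
  dd <- imprintcall:::paired_design(sheet, cre_in_model = TRUE)
  gfit <- suppressWarnings(stats::glm(
    y ~ 0 + dd$design + offset(rep(log(1e6), 8)),
    family = MASS::negative.binomial(theta = 1 / disp)))
  ll_oracle <- nb_loglik(y, fitted(gfit), disp)
  d <- edgeR::DGEList(counts = matrix(y, 1), lib.size = rep(1e6, 8))
  efit <- edgeR::glmFit(d, dd$design, dispersion = disp)
  ll_edger <- nb_loglik(y, efit$fitted.values[1, ], disp)
  expect_equal(ll_edger, ll_oracle, tolerance = 1e-4)
})

test_that("dispersion estimation recovers the simulating value", {
  set.seed(41)
  n_genes <- 200; n_samp <- 8
  mu <- rlnorm(n_genes, log(200), 0.5)
  y <- matrix(rnbinom(n_genes * n_samp, mu = rep(mu, n_samp), size = 1 / 0.1),
              n_genes, n_samp)
  design <- matrix(1, n_samp, 1)
  disp <- estimate_dispersions(y, design, mode = "common")
  expect_true(disp[1] > 0.07 && disp[1] < 0.13)
  expect_equal(length(unique(disp)), 1L)  # common mode is constant
  # Poisson data drives the common dispersion to the boundary
  y0 <- matrix(rpois(n_genes * n_samp, rep(mu, n_samp)), n_genes, n_samp)
  disp0 <- estimate_dispersions(y0, design, mode = "common")
  expect_lte(disp0[1], 0.01)
  tw <- estimate_dispersions(y, design, mode = "tagwise")
  expect_equal(length(tw), n_genes)
})

test_that("beta-binomial LRT is null on symmetric data and matches a grid", {
  g <- c("wt", "wt", "wt", "matD", "matD", "matD")
  m <- c(20L, 35L, 28L, 20L, 35L, 28L)
  r0 <- betabin_lrt(m, m, g, phi = 0.01)  # m = p in every sample
  expect_equal(r0$lrt_statistic, 0, tolerance = 1e-6)
  expect_equal(r0$p, 1, tolerance = 1e-6)

  m1 <- c(5L, 9L, 3L, 25L, 31L, 28L)
  p1 <- c(60L, 70L, 41L, 35L, 30L, 33L)
  r1 <- betabin_lrt(m1, p1, g, phi = 0.01)
  oracle <- oracle_betabin_grid(m1, m1 + p1, g, phi = 0.01, step = 0.002)
  expect_equal(r1$lrt_statistic, oracle$stat, tolerance = 1e-3)
  # maximized likelihoods agree with the dense grid
  expect_equal(r1$df, 1L)

  # a genotype with no informative sample cannot be tested
  r2 <- betabin_lrt(c(5L, NA, NA), c(50L, NA, NA), c("wt", "matD", "matD"),
                    phi = 0.01)
  expect_true(is.na(r2$p))
  expect_match(r2$reason, "matD")
})

test_that("the dual calling rule needs both significance and effect size", {
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  mk <- function(p, delta) {
    res <- data.frame(gene_id = "g", engine = "betabin",
                      lrt_statistic = 1, df = 1L, p = p,
                      reason = NA_character_, stringsAsFactors = FALSE)
    st <- matrix(c(0.02, 0.02, 0.02 + delta, 0.02 + delta), 1, 4,
                 dimnames = list("g", sheet$sample_id))
    call_differential(res, st, sheet, cfg)
  }
  expect_true(mk(0.01, 0.07)$called)     # significant and > 5 points
  expect_false(mk(0.01, 0.03)$called)    # significant but effect too small
  expect_false(mk(0.20, 0.10)$called)    # large effect but not significant
})

test_that("with two Cre lines the effect criterion may be met by either", {
  sheet <- toy_sheet(rep(c("wt", "matD"), each = 4),
                     cre = c("MMTV", "MMTV", "Zp3", "Zp3"))
  res <- data.frame(gene_id = "g", engine = "paired_nb", lrt_statistic = 9,
                    df = 1L, p = 0.001, reason = NA_character_,
                    stringsAsFactors = FALSE)
  # MMTV stratum shifts by 0.15, Zp3 stratum not at all
  st <- matrix(c(0.02, 0.02, 0.02, 0.02, 0.17, 0.17, 0.02, 0.02), 1, 8,
               dimnames = list("g", sheet$sample_id))
  out <- call_differential(res, st, sheet, cfg)
  expect_true(out$called)
  expect_equal(out$delta.matD.MMTV, 0.15, tolerance = 1e-12)
  expect_equal(out$delta.matD.Zp3, 0, tolerance = 1e-12)
})

test_that("the two engines rank genes concordantly on complete data", {
  sc <- simulation_scenario(
    n_genes = 300, samples_per_genotype = c(wt = 6, matD = 6),
    frac_maternal_expressed = 0.25, frac_paternal_expressed = 0.25,
    frac_biallelic_flagged = 0, p0_silent = 0.05, loi_frac = 0.5,
    loi_delta = c(matD = 0.15), mu_gene = 200, seed = 51)
  sim <- simulate_expression(sc)
  calls <- call_imprinted(sim$counts, sim$sheet, cfg)
  r_nb <- test_differential_imprinting(sim$counts, sim$sheet, calls, cfg,
                                       engine = "paired_nb")
  r_bb <- test_differential_imprinting(sim$counts, sim$sheet, calls, cfg,
                                       engine = "betabin")
  ok <- !is.na(r_nb$p) & !is.na(r_bb$p)
  expect_gt(sum(ok), 50)
  expect_gte(cor(r_nb$p[ok], r_bb$p[ok], method = "spearman"), 0.9)
})
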