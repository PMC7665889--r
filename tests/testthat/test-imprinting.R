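cfg <- analysis_config()

test_that("pooled log-ratio equals the iteratively maximized logistic MLE", {
  # closed form ln(sum m / sum p) vs glm's IRLS fit, 100 random fixtures
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    m <- rpois(n, sample(5:200, 1))
    p <- rpois(n, sample(5:200, 1))
    if (sum(m) == 0 || sum(p) == 0) next
    fit <- glm(cbind(m, p) ~ 1, family = binomial())
    expect_equal(allelic_log_ratio(m, p), unname(coef(fit)), tolerance = 1e-8)
  }
  expect_equal(allelic_log_ratio(c(30, 30), c(10, 10)), log(3))
  expect_equal(allelic_log_ratio(10, 10), 0)
  expect_equal(allelic_log_ratio(15, 10), log(1.5))
})

test_that("log-ratio is antisymmetric and guards zero sums", {
  set.seed(12)
  for (i in 1:20) {
    m <- rpois(4, 40); p <- rpois(4, 20)
    expect_identical(allelic_log_ratio(m, p), -allelic_log_ratio(p, m))
  }
  expect_true(is.na(allelic_log_ratio(c(0, 0), c(0, 0))))
  # Haldane-Anscombe pseudocount when one pooled sum is zero
  expect_equal(allelic_log_ratio(c(0, 0), c(5, 5)), log(0.5 / 10.5))
})

test_that("imprinting calls apply the screen, coverage filter and exclusions", {
  genes <- toy_genes(6)
  genes$gene_id <- c("strong", "boundary", "low_cov", "Gatm", "onX", "biallelic")
  genes$chrom[5] <- "chrX"
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  m <- rbind(strong = c(95, 95, 60, 60),
             boundary = c(15, 15, 15, 15),
             low_cov = c(90, 90, 6, 6),    # matD mean 9.5 counts/sample
             Gatm = c(95, 95, 95, 95),
             onX = c(95, 95, 95, 95),
             biallelic = c(50, 50, 50, 50))
  p <- rbind(strong = c(5, 5, 40, 40),
             boundary = c(10, 10, 10, 10),
             low_cov = c(5, 5, 4, 3),
             Gatm = c(5, 5, 5, 5),
             onX = c(5, 5, 5, 5),
             biallelic = c(50, 50, 50, 50))
  storage.mode(m) <- "integer"; p <- round(p); storage.mode(p) <- "integer"
  x <- toy_counts(m, p, m + p + 10L, genes)
  calls <- call_imprinted(x, sheet, cfg, expressed = genes$gene_id)
  expect_false("Gatm" %in% calls$gene_id)   # always excluded
  expect_false("onX" %in% calls$gene_id)    # autosomal only
  expect_true(calls$imprinted[calls$gene_id == "strong"])
  expect_equal(calls$silent_allele[calls$gene_id == "strong"], "paternal")
  # |log ratio| exactly log(1.5) is retained as imprinted
  expect_equal(calls$log_ratio[calls$gene_id == "boundary"], log(1.5))
  expect_true(calls$imprinted[calls$gene_id == "boundary"])
  # mean haplotyped counts 9.9 in one genotype: imprinted but not testable
  expect_true(calls$imprinted[calls$gene_id == "low_cov"])
  expect_lt(calls$mean_counts.matD[calls$gene_id == "low_cov"], 10)
  expect_false(calls$testable[calls$gene_id == "low_cov"])
  expect_false(calls$imprinted[calls$gene_id == "biallelic"])
})

test_that("silent-allele proportions follow their definition", {
  genes <- toy_genes(3)
  x <- toy_counts(matrix(c(90L, 25L, 0L), 3, 1), matrix(c(10L, 75L, 0L), 3, 1),
                  matrix(c(100L, 100L, 0L), 3, 1), genes)
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      silent_allele = c("paternal", "maternal", "paternal"))
  st <- silent_allele_proportions(x, calls)
  expect_equal(unname(st[, 1]), c(0.10, 0.25, NA))
})

test_that("the screen recovers simulated imprinting with high sensitivity", {
  sc <- simulation_scenario(
    n_genes = 600, samples_per_genotype = c(wt = 8, matD = 8),
    frac_maternal_expressed = 0.1, frac_paternal_expressed = 0.1,
    frac_biallelic_flagged = 0.15, p0_silent = 0.02, loi_frac = 0,
    mu_gene = 150, seed = 31)  # haplotyped depth ~ 120 per sample
  sim <- simulate_expression(sc)
  calls <- call_imprinted(sim$counts, sim$sheet, cfg)
  tru <- sim$truth[match(calls$gene_id, sim$truth$gene_id), ]
  imp <- tru$archetype != "biallelic"
  expect_gte(mean(calls$imprinted[imp]), 0.95)          # sensitivity
  expect_lte(mean(calls$imprinted[!imp]), 0.05)         # false positives
  # silent-allele direction recovered from wild type
  ok <- calls$imprinted & imp
  expect_true(all(calls$silent_allele[ok] == tru$silent_allele[ok]))
})

test_that("a fully lost imprint averages a silent proportion of one half", {
  sc <- simulation_scenario(
    n_genes = 60, samples_per_genotype = c(wt = 8, matD = 8),
    frac_maternal_expressed = 0.5, frac_paternal_expressed = 0.5,
    frac_biallelic_flagged = 0, p0_silent = 0.0, loi_frac = 1,
    loi_delta = c(matD = 0.5), mu_gene = 300, seed = 32)
  sim <- simulate_expression(sc)
  calls <- data.frame(gene_id = sim$truth$gene_id,
                      silent_allele = sim$truth$silent_allele)
  st <- silent_allele_proportions(sim$counts, calls)
  matd <- sim$sheet$sample_id[sim$sheet$genotype == "matD"]
  expect_equal(mean(rowMeans(st[, matd])), 0.5, tolerance = 0.02)
})
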