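cfg <- analysis_config()

test_that("CpG calls aggregate over half-open regions", {
  regions <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600),
                        name = c("r1", "r2"), class = "germline_DMR")
  cpg <- data.frame(chrom = "chr1",
                    pos = c(120, 150, 200, 550),
                    sample_id = "s1", allele = "maternal",
                    meth = c(3L, 2L, 9L, 1L), unmeth = c(1L, 2L, 9L, 0L))
  agg <- aggregate_region_counts(cpg, regions)
  r1 <- agg[agg$name == "r1", ]
  expect_equal(r1$meth, 5)            # 3 + 2; pos 200 == end is excluded
  expect_equal(r1$unmeth, 3)
  expect_equal(r1$percent_mC, 0.625)
  # a region with no CpG appears with zero counts and NA percent
  empty <- data.frame(chrom = "chr1", start = 900, end = 950,
                      name = "r3", class = "cpg_island")
  agg3 <- aggregate_region_counts(cpg, rbind(regions, empty))
  expect_equal(agg3$meth[agg3$name == "r3"], 0)
  expect_true(is.na(agg3$percent_mC[agg3$name == "r3"]))
})

test_that("aggregation conserves counts when regions tile the CpGs", {
  set.seed(61)
  cpg <- data.frame(chrom = "chr1", pos = sample(0:999, 200),
                    sample_id = rep(c("s1", "s2"), each = 100),
                    allele = "unsplit",
                    meth = rpois(200, 3), unmeth = rpois(200, 3))
  tiles <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100),
                      name = paste0("t", 1:10), class = "bin10kb")
  agg <- aggregate_region_counts(cpg, tiles)
  expect_equal(sum(agg$meth), sum(cpg$meth))
  expect_equal(sum(agg$unmeth), sum(cpg$unmeth))
  # a subset of the tiles captures no more than the input
  agg5 <- aggregate_region_counts(cpg, tiles[1:5, ])
  expect_lte(sum(agg5$meth), sum(cpg$meth))
})

test_that("DMR filters drop low coverage and weak wild-type contrast", {
  sheet <- toy_sheet(c("wt", "wt", "matD", "matD"))
  mk_region <- function(name, meth_m, unmeth_m, meth_p, unmeth_p) {
    do.call(rbind, lapply(seq_len(4), function(s) {
      data.frame(chrom = "chr1", start = 0, end = 100, name = name,
                 class = "germline_DMR", sample_id = paste0("s", s),
                 allele = c("maternal", "paternal"),
                 meth = c(meth_m, meth_p), unmeth = c(unmeth_m, unmeth_p))
    }))
  }
  counts <- rbind(
    mk_region("good", 45, 5, 2, 48),      # 90% vs 4%, coverage 100
    mk_region("low_cov", 4, 1, 1, 3),     # coverage 9 < 10
    mk_region("weak", 27, 23, 23, 27))    # 54% vs 46%: 8% difference
  sel <- select_testable_dmrs(counts, sheet, cfg, "matD")
  expect_true(sel$testable[sel$name == "good"])
  expect_equal(sel$hyper_allele[sel$name == "good"], "maternal")
  expect_false(sel$testable[sel$name == "low_cov"])
  expect_false(sel$testable[sel$name == "weak"])
})

test_that("DMR selection separates germline DMRs from unmethylated islands", {
  sc <- simulation_scenario(n_genes = 10, samples_per_genotype = c(wt = 4, matD = 4),
                            meth_coverage = 30, seed = 62)
  regions <- simulation_regions(sc, c(germline_DMR = 40L, cpg_island = 40L))
  ms <- simulate_methylation(sc, regions)
  sel <- select_testable_dmrs(ms$counts, imprintcall:::scenario_samples(sc),
                              cfg, "matD")
  expect_gte(mean(sel$testable[sel$class == "germline_DMR"]), 0.95)
  expect_lte(mean(sel$testable[sel$class == "cpg_island"]), 0.05)
})

test_that("the paired DMR test reacts to methylation loss, not to noise", {
  sheet <- toy_sheet(c("wt", "wt", "wt", "wt", "matD", "matD", "matD", "matD"))
  set.seed(63)
  mk <- function(name, p_wt, p_mut) {
    do.call(rbind, lapply(seq_len(8), function(s) {
      pr <- if (s <= 4) p_wt else p_mut
      meth <- rbinom(1, 100, pr)
      data.frame(chrom = "chr1", start = 0, end = 100, name = name,
                 class = "germline_DMR", sample_id = paste0("s", s),
                 allele = "maternal", meth = meth, unmeth = 100L - meth)
    }))
  }
  counts <- rbind(mk("stable", 0.9, 0.9), mk("drop", 0.9, 0.6))
  testable <- data.frame(name = c("stable", "drop"), class = "germline_DMR",
                         hyper_allele = "maternal", testable = TRUE)
  res <- test_dmr_differential(counts, testable, sheet, cfg, "matD")
  expect_false(res$called[res$name == "stable"])
  expect_gt(res$p[res$name == "stable"], 0.3)
  expect_true(res$called[res$name == "drop"])   # 30-point drop at coverage 100
  # with a single tested region, BH leaves the p-value unchanged
  res1 <- test_dmr_differential(counts[counts$name == "drop", ],
                                testable[2, ], sheet, cfg, "matD")
  expect_equal(res1$p_adj, res1$p)
})

test_that("genome-wide calls require coverage, significance and a 10% shift", {
  sheet <- toy_sheet(c("wt", "wt", "wt", "matD", "matD", "matD"))
  mk <- function(name, meth, unmeth) {
    data.frame(chrom = "chr1", start = 0, end = 100, name = name,
               class = "cpg_island", sample_id = paste0("s", 1:6),
               allele = "unsplit", meth = meth, unmeth = unmeth)
  }
  counts <- rbind(
    # significant but only a 5-point shift
    mk("small_shift", c(200, 200, 200, 230, 230, 230),
       c(200, 200, 200, 170, 170, 170)),
    # 20-point shift but noisy/weak evidence
    mk("weak_sig", c(4, 6, 5, 7, 8, 7), c(6, 4, 5, 3, 2, 3)),
    # fewer than 10 total counts: excluded before testing
    mk("low", c(1, 0, 0, 1, 0, 0), c(0, 1, 0, 0, 1, 0)),
    # strong shift with strong evidence
    mk("real", c(100, 100, 100, 300, 300, 300),
       c(300, 300, 300, 100, 100, 100)))
  res <- test_genomewide_methylation(counts, sheet, cfg, "matD")
  expect_false("low" %in% res$name)
  expect_false(res$called[res$name == "small_shift"])
  expect_lt(res$p_adj[res$name == "small_shift"], 0.05)  # significant, yet not called
  expect_false(res$called[res$name == "weak_sig"])
  expect_true(res$called[res$name == "real"])
})

test_that("regions annotate to their closest gene within 2 kb", {
  genes <- data.frame(gene_id = c("near", "far", "tie_a", "tie_b"),
                      chrom = "chr1",
                      start = c(10000, 50000, 70000, 76000),
                      end = c(12000, 52000, 72000, 78000))
  regions <- data.frame(chrom = "chr1",
                        start = c(8000, 44000, 73000, 11000),
                        end = c(8200, 47000, 75000, 11500),
                        name = c("up1800", "gap3000", "between", "inside"))
  ann <- annotate_regions_to_genes(regions, genes, cfg)
  expect_equal(ann$gene_id[ann$name == "up1800"], "near")     # 1.8 kb upstream
  expect_true(is.na(ann$gene_id[ann$name == "gap3000"]))     # 3 kb away
  # equidistant (1 kb to both): tie broken by smaller start coordinate
  expect_equal(ann$gene_id[ann$name == "between"], "tie_a")
  expect_equal(ann$distance[ann$name == "inside"], 0)        # overlap
})

test_that("embryos are sexed and screened for maternal contamination", {
  qc <- data.frame(sample_id = c("e1", "e2", "e3", "e4"),
                   x_paternal = c(450, 0, 40, 0),
                   x_total = c(1000, 800, 100, 0),
                   maternal_fraction = c(0.5, 0.52, 0.80, 0.5))
  res <- sex_and_qc_embryos(qc, cfg)
  expect_equal(res$sex, c("F", "M", "F", NA))
  expect_equal(res$contamination_flag, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$keep, c(TRUE, TRUE, FALSE, FALSE))
})
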