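#' Aggregate per-CpG methylation calls over regions
#'
#' Sums methylated and unmethylated counts per region, sample and allele.
#' Positions are 0-based and regions half-open, so a CpG at `pos ==
#' region$end` is excluded; a CpG inside several overlapping regions is
#' counted in each of them; CpGs outside all regions are ignored. Regions
#' with no covered CpG appear with zero counts (percent methylation NA).
#'
#' @param cpg data.frame with columns `chrom`, `pos`, `sample_id`, `allele`,
#'   `meth`, `unmeth`.
#' @param regions BED-like data.frame with `chrom`, `start`, `end`, `name`,
#'   `class`.
#' @return long data.frame (`meth_region_counts`): region fields, sample_id,
#'   allele, meth, unmeth, percent_mC (on [0,1], NA at zero coverage).
#' @export
aggregate_region_counts <- function(cpg, regions) {
  stopifnot(all(c("chrom", "pos", "sample_id", "allele", "meth", "unmeth")
                %in% names(cpg)),
            all(c("chrom", "start", "end", "name") %in% names(regions)))
  if (!"class" %in% names(regions)) regions$class <- NA_character_
  samples <- unique(cpg$sample_id)
  alleles <- unique(cpg$allele)
  grid <- expand.grid(region_i = seq_len(nrow(regions)),
                      sample_id = samples, allele = alleles,
                      stringsAsFactors = FALSE)
  grid$meth <- 0; grid$unmeth <- 0
  key <- function(ri, s, a) paste(ri, s, a, sep = "\r")
  rownames(grid) <- key(grid$region_i, grid$sample_id, grid$allele)
  for (ch in intersect(unique(regions$chrom), unique(cpg$chrom))) {
    ri <- which(regions$chrom == ch)
    ci <- which(cpg$chrom == ch)
    # 0-based half-open [start, end) -> 1-based closed [start+1, end]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cpg$pos[ci] + 1L, cpg$pos[ci] + 1L),
      IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri]))
    if (!length(hits)) next
    qi <- ci[S4Vectors_from(hits)]
    si <- ri[S4Vectors_to(hits)]
    k <- key(si, cpg$sample_id[qi], cpg$allele[qi])
    add_m <- tapply(cpg$meth[qi], k, sum)
    add_u <- tapply(cpg$unmeth[qi], k, sum)
    grid[names(add_m), "meth"] <- grid[names(add_m), "meth"] + add_m
    grid[names(add_u), "unmeth"] <- grid[names(add_u), "unmeth"] + add_u
  }
  out <- cbind(regions[grid$region_i, c("chrom", "start", "end", "name", "class")],
               grid[, c("sample_id", "allele", "meth", "unmeth")])
  rownames(out) <- NULL
  out$percent_mC <- ifelse(out$meth + out$unmeth > 0,
                           out$meth / (out$meth + out$unmeth), NA_real_)
  out
}

# IRanges accessors without importing the generics wholesale
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Select testable imprinted DMRs and assign the hypermethylated allele
#'
#' A region is testable when (i) its mean total allelic counts
#' (maternal + paternal, methylated + unmethylated) per sample reach
#' `dmr_min_counts` in both the wild-type and the tested genotype, and
#' (ii) the mean wild-type difference in percent methylation between the
#' parental alleles is at least `dmr_wt_allelic_diff_min`. The
#' hypermethylated allele is the wild-type-higher one.
#'
#' @param counts output of [aggregate_region_counts()] (or
#'   [simulate_methylation()]).
#' @param sheet sample sheet.
#' @param config an [analysis_config()].
#' @param test_genotype genotype compared against wild type.
#' @return data.frame: name, class, mean coverage per genotype,
#'   wt_allelic_diff, hyper_allele, testable.
#' @export
select_testable_dmrs <- function(counts, sheet, config = analysis_config(),
                                 test_genotype = "matD") {
  sheet <- validate_sample_sheet(sheet)
  wt <- sheet$sample_id[sheet$genotype == "wt"]
  ts <- sheet$sample_id[sheet$genotype == test_genotype]
  if (!length(wt)) stop("no wild-type samples")
  al <- counts[counts$allele %in% c("maternal", "paternal"), , drop = FALSE]
  names_u <- unique(al$name)
  cov_mean <- function(region, samples) {
    v <- al[al$name == region & al$sample_id %in% samples, ]
    sum(v$meth + v$unmeth) / length(samples)
  }
  res <- data.frame(name = names_u, stringsAsFactors = FALSE)
  res$class <- counts$class[match(names_u, counts$name)]
  res$mean_counts_wt <- vapply(names_u, cov_mean, 0, samples = wt)
  res$mean_counts_test <- vapply(names_u, cov_mean, 0, samples = ts)
  wt_diff <- vapply(names_u, function(region) {
    v <- al[al$name == region & al$sample_id %in% wt, ]
    pm <- v$meth / (v$meth + v$unmeth)
    d <- pm[v$allele == "maternal"][match(wt, v$sample_id[v$allele == "maternal"])] -
      pm[v$allele == "paternal"][match(wt, v$sample_id[v$allele == "paternal"])]
    mean(d, na.rm = TRUE)
  }, 0)
  res$wt_allelic_diff <- wt_diff
  res$hyper_allele <- ifelse(is.na(wt_diff), NA_character_,
                             ifelse(wt_diff >= 0, "maternal", "paternal"))
  res$testable <- res$mean_counts_wt >= config$dmr_min_counts &
    res$mean_counts_test >= config$dmr_min_counts &
    !is.na(wt_diff) & abs(wt_diff) >= config$dmr_wt_allelic_diff_min
  res
}

#' Test DMRs for differential allelic methylation between genotypes
#'
#' For each testable region, the methylated and unmethylated counts of the
#' hypermethylated allele form two paired observations per sample, analysed
#' with the same paired negative-binomial design as the expression engine
#' (sample pairing factor, methylation-state effect, state-by-genotype
#' interaction) at the common dispersion across regions; the interaction is
#' assessed by likelihood-ratio test, p-values are Benjamini-Hochberg
#' adjusted across tested regions, and a region is called when the adjusted
#' value is below `fdr_alpha`.
#'
#' @param counts output of [aggregate_region_counts()].
#' @param testable output of [select_testable_dmrs()].
#' @param sheet sample sheet.
#' @param config an [analysis_config()].
#' @param test_genotype genotype compared against wild type.
#' @param allele `"hyper"` to test the hypermethylated allele (bulk) or
#'   `"unsplit"` to test total methylation (sparse single-embryo data).
#' @return data.frame: name, class, hyper_allele, lrt_statistic, df, p,
#'   p_adj, mean percent methylation per genotype, called.
#' @export
test_dmr_differential <- function(counts, testable, sheet,
                                  config = analysis_config(),
                                  test_genotype = "matD",
                                  allele = c("hyper", "unsplit")) {
  allele <- match.arg(allele)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$genotype %in% c("wt", test_genotype), , drop = FALSE]
  regions <- testable$name[testable$testable]
  empty <- data.frame(name = character(), class = character(),
                      hyper_allele = character(), lrt_statistic = numeric(),
                      df = integer(), p = numeric(), p_adj = numeric(),
                      pct_wt = numeric(), pct_test = numeric(),
                      called = logical(), stringsAsFactors = FALSE)
  if (!length(regions)) return(empty)
  n <- nrow(sheet)
  meth <- matrix(NA_real_, length(regions), n,
                 dimnames = list(regions, sheet$sample_id))
  unmeth <- meth
  for (i in seq_along(regions)) {
    hyp <- testable$hyper_allele[testable$name == regions[i]]
    want <- if (allele == "hyper") hyp else "unsplit"
    v <- counts[counts$name == regions[i] & counts$allele == want, ]
    meth[i, ] <- v$meth[match(sheet$sample_id, v$sample_id)]
    unmeth[i, ] <- v$unmeth[match(sheet$sample_id, v$sample_id)]
  }
  # meth/unmeth play the roles of the paired per-sample observations
  fit <- fit_paired_nb(meth, unmeth, sheet, config,
                       dispersion_mode = "common")
  pct <- meth / (meth + unmeth)
  wt <- sheet$sample_id[sheet$genotype == "wt"]
  ts <- sheet$sample_id[sheet$genotype == test_genotype]
  out <- data.frame(
    name = regions,
    class = testable$class[match(regions, testable$name)],
    hyper_allele = testable$hyper_allele[match(regions, testable$name)],
    lrt_statistic = fit$lrt_statistic, df = fit$df, p = fit$p,
    p_adj = bh_adjust(fit$p),
    pct_wt = rowMeans(pct[, wt, drop = FALSE], na.rm = TRUE),
    pct_test = rowMeans(pct[, ts, drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$called <- !is.na(out$p_adj) & out$p_adj < config$fdr_alpha
  out
}

#' Genome-wide methylation testing
#'
#' For CpG islands, promoters or 10 kb bins, tests the total (non-split by
#' allele) methylated/unmethylated counts with a per-region binomial
#' logistic regression of methylation on genotype (likelihood-ratio test
#' against the intercept-only null). Regions with fewer than
#' `dmr_min_counts` total counts across the analysed samples are excluded
#' before testing. A region is called when the BH-adjusted p-value is below
#' `fdr_alpha` and the absolute difference in mean methylation proportion
#' between the genotypes is at least `meth_diff_min`.
#'
#' @param counts output of [aggregate_region_counts()]; rows with
#'   `allele == "unsplit"` are used.
#' @param sheet sample sheet.
#' @param config an [analysis_config()].
#' @param test_genotype genotype compared against wild type.
#' @param classes region classes to test.
#' @return data.frame: name, class, p, p_adj, pct_wt, pct_test, diff, called.
#' @export
test_genomewide_methylation <- function(counts, sheet,
                                        config = analysis_config(),
                                        test_genotype = "matD",
                                        classes = c("cpg_island", "promoter",
                                                    "bin10kb")) {
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[sheet$genotype %in% c("wt", test_genotype), , drop = FALSE]
  un <- counts[counts$allele == "unsplit" & counts$class %in% classes &
                 counts$sample_id %in% sheet$sample_id, , drop = FALSE]
  split_r <- split(un, un$name)
  rows <- lapply(split_r, function(v) {
    tot <- sum(v$meth + v$unmeth)
    if (tot < config$dmr_min_counts) return(NULL)
    g <- factor(sheet$genotype[match(v$sample_id, sheet$sample_id)],
                levels = c("wt", test_genotype))
    full <- stats::glm(cbind(meth, unmeth) ~ g, data = v, family = stats::binomial())
    null <- stats::glm(cbind(meth, unmeth) ~ 1, data = v, family = stats::binomial())
    stat <- max(0, null$deviance - full$deviance)
    df <- null$df.residual - full$df.residual
    pm <- v$meth / (v$meth + v$unmeth)
    data.frame(name = v$name[1], class = v$class[1],
               lrt_statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE),
               pct_wt = mean(pm[g == "wt"], na.rm = TRUE),
               pct_test = mean(pm[g == test_genotype], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(name = character(), class = character(),
                      lrt_statistic = numeric(), df = integer(), p = numeric(),
                      pct_wt = numeric(), pct_test = numeric(),
                      p_adj = numeric(), diff = numeric(), called = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out$diff <- out$pct_test - out$pct_wt
  out$called <- !is.na(out$p_adj) & out$p_adj < config$fdr_alpha &
    abs(out$diff) >= config$meth_diff_min
  out
}

#' Annotate regions with their closest gene
#'
#' Nearest gene by interval distance on the same chromosome (0 when the
#' region overlaps the gene); NA when the closest gene is farther than
#' `gene_assoc_dist` (default 2 kb). Ties are broken by smaller distance,
#' then smaller gene start coordinate.
#'
#' @param regions BED-like data.frame (`chrom`, `start`, `end`, `name`).
#' @param genes gene annotation data.frame.
#' @param config an [analysis_config()].
#' @return data.frame: name, gene_id (NA when no gene within range), distance.
#' @export
annotate_regions_to_genes <- function(regions, genes,
                                      config = analysis_config()) {
  out <- data.frame(name = regions$name, gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    # distance between half-open intervals; 0 when overlapping or book-ended
    d <- pmax(0, pmax(g$start - regions$end[i], regions$start[i] - g$end))
    ord <- order(d, g$start)
    best <- ord[1]
    if (d[best] <= config$gene_assoc_dist) {
      out$gene_id[i] <- g$gene_id[best]
      out$distance[i] <- d[best]
    }
  }
  out
}

#' Sex and quality-control single embryos
#'
#' Embryos are sexed from the paternal-strain (Cast) haplotyped bisulfite
#' reads on the X chromosome: females carry a paternal X, so a paternal-X
#' fraction of the X-linked allelic reads at or above `sex_threshold` calls
#' a female, below it a male; zero X coverage gives NA and excludes the
#' embryo. Embryos whose genome-wide maternal-allele read fraction reaches
#' `contamination_threshold` are flagged as maternally contaminated and
#' excluded.
#'
#' @param qc data.frame with columns `sample_id`, `x_paternal` (paternal-X
#'   allelic reads), `x_total` (all X-linked allelic reads),
#'   `maternal_fraction` (genome-wide maternal-allele proportion).
#' @param config an [analysis_config()].
#' @return data.frame: sample_id, sex, contamination_flag, keep.
#' @export
sex_and_qc_embryos <- function(qc, config = analysis_config()) {
  stopifnot(all(c("sample_id", "x_paternal", "x_total", "maternal_fraction")
                %in% names(qc)))
  frac <- ifelse(qc$x_total > 0, qc$x_paternal / qc$x_total, NA_real_)
  sex <- ifelse(is.na(frac), NA_character_,
                ifelse(frac >= config$sex_threshold, "F", "M"))
  contaminated <- !is.na(qc$maternal_fraction) &
    qc$maternal_fraction >= config$contamination_threshold
  data.frame(sample_id = qc$sample_id, sex = sex,
             contamination_flag = contaminated,
             keep = !is.na(sex) & !contaminated,
             stringsAsFactors = FALSE)
}
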