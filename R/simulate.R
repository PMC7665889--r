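#' Simulation scenario
#'
#' Describes a truth-tagged synthetic dataset with the statistical structure
#' the analysis assumes: negative-binomial total expression, beta-binomially
#' overdispersed allelic splits with parent-of-origin bias, genotype-dependent
#' loss-of-imprinting shifts of the silent-allele proportion, mosaic
#' heterozygous/homozygous chromosome segments for N1 backcross samples, and
#' beta-binomial allelic methylation with germline-imprint structure.
#'
#' Gene archetypes are `biallelic` (maternal proportion 0.5),
#' `maternal_expressed` (paternal allele silent) and `paternal_expressed`
#' (maternal allele silent). Imprinted archetypes express the silent allele
#' at a base proportion `p0_silent`; in non-wild-type genotypes a fraction
#' `loi_frac` of them shift that proportion up by `loi_delta[genotype]`
#' (loss of imprinting). A share of biallelic genes is also flagged as
#' known-imprinted so the wild-type imprinting screen has true negatives to
#' reject.
#'
#' @param n_genes number of genes.
#' @param samples_per_genotype named integer vector, e.g. `c(wt = 8, matD = 8)`.
#' @param cre Cre line label(s) recycled over samples within each genotype.
#' @param tissue,cross sample sheet fields.
#' @param frac_maternal_expressed,frac_paternal_expressed fraction of genes
#'   per imprinted archetype.
#' @param frac_biallelic_flagged fraction of biallelic genes flagged as
#'   known-imprinted (true negatives for the screen).
#' @param p0_silent base silent-allele proportion of imprinted genes.
#' @param loi_frac fraction of imprinted genes that lose imprinting in
#'   non-wild-type genotypes.
#' @param loi_delta named numeric vector of silent-allele shifts per
#'   non-wild-type genotype.
#' @param mu_log_mean,mu_log_sd log-normal parameters of the per-gene mean
#'   total count.
#' @param mu_gene optional vector of per-gene mean total counts overriding
#'   the log-normal draw (recycled to `n_genes`; a zero gives an all-zero
#'   row).
#' @param nb_dispersion negative-binomial dispersion of total counts.
#' @param rho beta-binomial intraclass correlation of the allelic split.
#' @param haplotyping_efficiency fraction of total reads that are
#'   allele-assignable.
#' @param informative_fraction probability a gene/sample cell is informative
#'   (set below 1 to emulate N1 mosaic missingness).
#' @param n_chroms,chrom_length autosome count and length (bp) of the toy
#'   genome; a small fraction of genes is placed on chrX to exercise the
#'   autosomal filter.
#' @param n1_het_fraction long-run heterozygous fraction of N1 genomes.
#' @param n1_min_segment_bins,n1_mean_segment_bins segment-length law
#'   (minimum plus geometric excess) in bins.
#' @param n1_samples number of backcross bin tracks to simulate.
#' @param bin_depth_mean mean allelic reads per 100 kb bin.
#' @param n1_eps Cast read proportion in homozygous-B6 segments (residual
#'   mismapping).
#' @param n1_rho beta-binomial intraclass correlation of bin counts.
#' @param meth_coverage mean bisulfite coverage per region, sample and allele.
#' @param meth_rho beta-binomial intraclass correlation of methylation counts.
#' @param meth_levels named list of per-class (hypermethylated, hypomethylated)
#'   allele methylation levels.
#' @param meth_loi_frac fraction of DMRs whose hypermethylated allele loses
#'   methylation in non-wild-type genotypes.
#' @param meth_loi_shift methylation shift (on [0,1], negative = loss) applied
#'   to affected regions in non-wild-type genotypes.
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return An object of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_genes = 2000L,
                                samples_per_genotype = c(wt = 8L, matD = 8L),
                                cre = "none",
                                tissue = "placenta_E14.5",
                                cross = "F1",
                                frac_maternal_expressed = 0.05,
                                frac_paternal_expressed = 0.05,
                                frac_biallelic_flagged = 0.05,
                                p0_silent = 0.02,
                                loi_frac = 0.2,
                                loi_delta = c(matD = 0.3),
                                mu_log_mean = log(100),
                                mu_log_sd = 1,
                                mu_gene = NULL,
                                nb_dispersion = 0.1,
                                rho = 0.01,
                                haplotyping_efficiency = 0.8,
                                informative_fraction = 1,
                                n_chroms = 19L,
                                chrom_length = 5e7,
                                n1_het_fraction = 0.5,
                                n1_min_segment_bins = 20L,
                                n1_mean_segment_bins = 150L,
                                n1_samples = 4L,
                                bin_depth_mean = 50,
                                n1_eps = 0.01,
                                n1_rho = 0.02,
                                meth_coverage = 50,
                                meth_rho = 0.05,
                                meth_levels = list(
                                  germline_DMR = c(0.95, 0.05),
                                  secondary_DMR = c(0.75, 0.25),
                                  cpg_island = c(0.05, 0.05),
                                  promoter = c(0.25, 0.25),
                                  bin10kb = c(0.70, 0.70)),
                                meth_loi_frac = 0,
                                meth_loi_shift = -0.4,
                                seed = 1L) {
  sc <- as.list(environment())
  genos <- names(sc$samples_per_genotype)
  if (is.null(genos) || !"wt" %in% genos)
    stop("samples_per_genotype must be named and include 'wt'")
  non_wt <- setdiff(genos, "wt")
  missing_delta <- setdiff(non_wt, names(sc$loi_delta))
  if (length(missing_delta))
    sc$loi_delta[missing_delta] <- 0
  probs <- c(sc$frac_maternal_expressed, sc$frac_paternal_expressed,
             sc$frac_biallelic_flagged, sc$p0_silent, sc$loi_frac, sc$rho,
             sc$haplotyping_efficiency, sc$informative_fraction,
             sc$n1_het_fraction, sc$n1_eps, sc$n1_rho, sc$meth_rho,
             sc$meth_loi_frac)
  if (any(probs < 0 | probs > 1))
    stop("all scenario proportions must lie in [0,1]")
  if (sc$haplotyping_efficiency <= 0)
    stop("haplotyping_efficiency must be in (0,1]")
  if (any(sc$p0_silent + sc$loi_delta > 1))
    stop("loi_delta pushes the silent-allele proportion above 1")
  structure(sc, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d genes, samples per genotype: %s, cross %s\n",
              x$n_genes,
              paste(names(x$samples_per_genotype), x$samples_per_genotype,
                    sep = "=", collapse = ", "),
              x$cross))
  cat(sprintf("  p0 = %.3f, loi: frac %.2f, delta %s; rho = %.3f, h = %.2f\n",
              x$p0_silent, x$loi_frac,
              paste(names(x$loi_delta), x$loi_delta, sep = "=", collapse = ", "),
              x$rho, x$haplotyping_efficiency))
  invisible(x)
}

# beta-binomial draws parametrized by (mean prob, intraclass correlation rho);
# rho = 0 degenerates to the binomial
rbetabinom <- function(n, size, prob, rho) {
  prob <- rep_len(prob, n); size <- rep_len(size, n)
  if (length(rho) == 1L) rho <- rep_len(rho, n)
  out <- integer(n)
  plain <- rho <= 0 | prob <= 0 | prob >= 1
  if (any(plain))
    out[plain] <- stats::rbinom(sum(plain), size[plain], prob[plain])
  if (any(!plain)) {
    i <- which(!plain)
    a <- prob[i] * (1 - rho[i]) / rho[i]
    b <- (1 - prob[i]) * (1 - rho[i]) / rho[i]
    out[i] <- stats::rbinom(length(i), size[i], stats::rbeta(length(i), a, b))
  }
  out
}

scenario_samples <- function(scenario) {
  genos <- rep(names(scenario$samples_per_genotype),
               scenario$samples_per_genotype)
  ids <- unlist(lapply(names(scenario$samples_per_genotype), function(g) {
    paste0(g, "_", seq_len(scenario$samples_per_genotype[[g]]))
  }))
  cre <- unlist(lapply(scenario$samples_per_genotype, function(n) {
    rep_len(scenario$cre, n)
  }))
  data.frame(sample_id = ids, genotype = genos, cre = cre,
             tissue = scenario$tissue, cross = scenario$cross,
             maternal_strain = if (scenario$cross == "N1") "C57BL/6" else "C57BL/6",
             paternal_strain = if (scenario$cross == "N1") "CastB6F1" else "CAST/EiJ",
             sex = NA_character_, stringsAsFactors = FALSE)
}

scenario_genes <- function(scenario) {
  n <- scenario$n_genes
  n_mat <- round(scenario$frac_maternal_expressed * n)
  n_pat <- round(scenario$frac_paternal_expressed * n)
  archetype <- rep("biallelic", n)
  archetype[seq_len(n_mat)] <- "maternal_expressed"
  archetype[n_mat + seq_len(n_pat)] <- "paternal_expressed"
  n_flag <- round(scenario$frac_biallelic_flagged * n)
  flagged_biallelic <- n_mat + n_pat + seq_len(min(n_flag, n - n_mat - n_pat))
  known <- archetype != "biallelic"
  known[flagged_biallelic] <- TRUE
  # ~1% of genes on chrX to exercise the autosomal filter
  chroms <- c(sample(paste0("chr", seq_len(scenario$n_chroms)), n, replace = TRUE))
  chroms[sample.int(n, max(1L, round(0.01 * n)))] <- "chrX"
  start <- floor(stats::runif(n, 0, scenario$chrom_length - 1e4))
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = chroms, start = start, end = start + 1e4,
    strand = sample(c("+", "-"), n, replace = TRUE),
    is_known_imprinted = known,
    cluster = ifelse(known, paste0("cluster", (seq_len(n) %% 5) + 1), NA_character_),
    stringsAsFactors = FALSE)
  list(genes = genes, archetype = archetype)
}

#' Simulate allele-specific expression
#'
#' Total counts per gene and sample are negative-binomial; an
#' allele-assignable depth is binomially thinned at the haplotyping
#' efficiency; maternal reads are beta-binomial around the archetype- and
#' genotype-determined maternal proportion. The returned truth table records
#' the archetype, silent allele and the silent-allele proportion per
#' genotype for every gene.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `counts` (an `allele_counts`), `sheet` (sample sheet
#'   data.frame) and `truth` (per-gene truth data.frame with one
#'   `p_silent.<genotype>` and `delta.<genotype>` column per genotype).
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  sheet <- scenario_samples(scenario)
  ga <- scenario_genes(scenario)
  genes <- ga$genes; archetype <- ga$archetype
  n <- scenario$n_genes; ns <- nrow(sheet)
  genos <- names(scenario$samples_per_genotype)

  imprinted <- archetype != "biallelic"
  responsive <- imprinted &
    (stats::runif(n) < scenario$loi_frac)
  silent <- ifelse(archetype == "maternal_expressed", "paternal",
                   ifelse(archetype == "paternal_expressed", "maternal",
                          NA_character_))

  # per-gene, per-genotype silent-allele proportion
  p_silent <- matrix(NA_real_, n, length(genos), dimnames = list(NULL, genos))
  delta <- matrix(0, n, length(genos), dimnames = list(NULL, genos))
  for (g in genos) {
    d <- if (g == "wt") 0 else unname(scenario$loi_delta[g])
    delta[responsive, g] <- d
    p_silent[, g] <- ifelse(imprinted, scenario$p0_silent + delta[, g], NA_real_)
  }
  if (any(p_silent > 1, na.rm = TRUE))
    stop("scenario error: p_silent outside [0,1]")

  mu <- if (is.null(scenario$mu_gene)) {
    stats::rlnorm(n, scenario$mu_log_mean, scenario$mu_log_sd)
  } else rep_len(scenario$mu_gene, n)
  total <- matrix(0L, n, ns)
  maternal <- matrix(NA_integer_, n, ns)
  paternal <- matrix(NA_integer_, n, ns)
  informative <- matrix(stats::runif(n * ns) < scenario$informative_fraction,
                        n, ns)
  size <- 1 / scenario$nb_dispersion
  for (s in seq_len(ns)) {
    g <- sheet$genotype[s]
    tot <- stats::rnbinom(n, mu = mu, size = size)
    depth <- stats::rbinom(n, tot, scenario$haplotyping_efficiency)
    pi_m <- rep(0.5, n)
    pi_m[silent %in% "paternal"] <- 1 - p_silent[silent %in% "paternal", g]
    pi_m[silent %in% "maternal"] <- p_silent[silent %in% "maternal", g]
    m <- rbetabinom(n, depth, pi_m, scenario$rho)
    total[, s] <- tot
    maternal[, s] <- ifelse(informative[, s], m, NA_integer_)
    paternal[, s] <- ifelse(informative[, s], depth - m, NA_integer_)
  }
  colnames(total) <- colnames(maternal) <- colnames(paternal) <-
    colnames(informative) <- sheet$sample_id

  truth <- data.frame(gene_id = genes$gene_id, archetype = archetype,
                      silent_allele = silent, p0 = ifelse(imprinted, scenario$p0_silent, NA),
                      responsive = responsive, stringsAsFactors = FALSE)
  for (g in genos) {
    truth[[paste0("delta.", g)]] <- delta[, g]
    truth[[paste0("p_silent.", g)]] <- p_silent[, g]
  }
  list(counts = allele_count_matrix(genes, maternal, paternal, total,
                                    informative = informative),
       sheet = sheet, truth = truth)
}

#' Simulate N1 backcross bin tracks
#'
#' Each chromosome is partitioned into alternating heterozygous and
#' homozygous-B6 segments (length = minimum plus geometric excess); per-bin
#' Cast read proportions are beta-binomial around 0.5 in heterozygous
#' segments and around a small residual in homozygous segments.
#'
#' @param scenario a [simulation_scenario()].
#' @param chrom_lengths named vector of chromosome lengths in bp; defaults to
#'   the scenario's toy genome.
#' @param bin_width bin width in bp.
#' @return list with `track` (data.frame sample_id, chrom, bin_start, cast,
#'   total) and `truth` (data.frame sample_id, chrom, first_bin, last_bin,
#'   zygosity), bins indexed from 0.
#' @export
simulate_backcross_bins <- function(scenario, chrom_lengths = NULL,
                                    bin_width = 100000L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 1L)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(
      rep(scenario$chrom_length, scenario$n_chroms),
      paste0("chr", seq_len(scenario$n_chroms)))
  }
  ids <- paste0("n1_", seq_len(scenario$n1_samples))
  seg_len <- function() {
    scenario$n1_min_segment_bins +
      stats::rgeom(1, 1 / max(1, scenario$n1_mean_segment_bins -
                                   scenario$n1_min_segment_bins + 1))
  }
  tracks <- list(); truths <- list()
  for (id in ids) {
    for (ch in names(chrom_lengths)) {
      n_bins <- as.integer(floor(chrom_lengths[[ch]] / bin_width))
      if (scenario$n1_het_fraction >= 1) {
        zyg <- rep("het", 1L); lens <- n_bins
      } else if (scenario$n1_het_fraction <= 0) {
        zyg <- rep("hom", 1L); lens <- n_bins
      } else {
        zyg <- character(); lens <- integer(); tot <- 0L
        state <- if (stats::runif(1) < scenario$n1_het_fraction) "het" else "hom"
        while (tot < n_bins) {
          l <- min(seg_len(), n_bins - tot)
          zyg <- c(zyg, state); lens <- c(lens, l); tot <- tot + l
          state <- if (state == "het") "hom" else "het"
        }
      }
      last <- cumsum(lens) - 1L
      first <- c(0L, utils::head(cumsum(lens), -1L))
      truths[[length(truths) + 1L]] <- data.frame(
        sample_id = id, chrom = ch, first_bin = first, last_bin = last,
        zygosity = zyg, stringsAsFactors = FALSE)
      p <- rep(ifelse(zyg == "het", 0.5, scenario$n1_eps), lens)
      tot_reads <- stats::rpois(n_bins, scenario$bin_depth_mean)
      cast <- rbetabinom(n_bins, tot_reads, p, scenario$n1_rho)
      tracks[[length(tracks) + 1L]] <- data.frame(
        sample_id = id, chrom = ch,
        bin_start = (seq_len(n_bins) - 1L) * as.numeric(bin_width),
        cast = cast, total = tot_reads, stringsAsFactors = FALSE)
    }
  }
  list(track = do.call(rbind, tracks), truth = do.call(rbind, truths))
}

#' Default simulated region set
#'
#' Germline and secondary DMRs, CpG islands, promoters and 10 kb bins placed
#' uniformly on the scenario's toy genome.
#'
#' @param scenario a [simulation_scenario()].
#' @param n_per_class named integer vector of region counts per class.
#' @return BED-like data.frame (chrom, start, end, name, class).
#' @export
simulation_regions <- function(scenario,
                               n_per_class = c(germline_DMR = 45L,
                                               secondary_DMR = 10L,
                                               cpg_island = 100L,
                                               promoter = 50L,
                                               bin10kb = 100L)) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 2L)
  widths <- c(germline_DMR = 2000, secondary_DMR = 2000, cpg_island = 1000,
              promoter = 5000, bin10kb = 10000)
  out <- lapply(names(n_per_class), function(cl) {
    k <- n_per_class[[cl]]
    ch <- sample(paste0("chr", seq_len(scenario$n_chroms)), k, replace = TRUE)
    st <- floor(stats::runif(k, 0, scenario$chrom_length - widths[[cl]]))
    data.frame(chrom = ch, start = st, end = st + widths[[cl]],
               name = sprintf("%s_%03d", cl, seq_len(k)), class = cl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate allelic methylation counts
#'
#' Germline DMRs get one hypermethylated (~95\% mC) and one hypomethylated
#' (~5\% mC) parental allele; secondary DMRs a weaker contrast; CpG islands
#' are unmethylated on both alleles. In non-wild-type genotypes a fraction
#' `meth_loi_frac` of DMRs shifts the hypermethylated allele by
#' `meth_loi_shift` (and non-DMR classes shift both alleles, emulating a
#' genome-wide methylation change). Counts are beta-binomial at Poisson
#' coverage; the `unsplit` allele is the sum of the two parental tracks.
#'
#' @param scenario a [simulation_scenario()].
#' @param regions BED-like region data.frame with a `class` column; defaults
#'   to [simulation_regions()].
#' @param sheet sample sheet; defaults to the scenario's samples.
#' @return list with `counts` (long data.frame: region fields, sample_id,
#'   allele, meth, unmeth) and `truth` (per-region hyper allele, levels and
#'   affected flag).
#' @export
simulate_methylation <- function(scenario, regions = simulation_regions(scenario),
                                 sheet = scenario_samples(scenario)) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed + 3L)
  nr <- nrow(regions)
  hyper <- sample(c("maternal", "paternal"), nr, replace = TRUE)
  lev <- t(vapply(regions$class, function(cl) scenario$meth_levels[[cl]],
                  numeric(2)))
  is_dmr <- grepl("DMR", regions$class)
  affected <- stats::runif(nr) < scenario$meth_loi_frac
  rows <- list()
  for (s in seq_len(nrow(sheet))) {
    g <- sheet$genotype[s]
    shift <- if (g == "wt") 0 else scenario$meth_loi_shift
    m_hyper <- pmin(1, pmax(0, lev[, 1] + ifelse(affected, shift, 0)))
    m_hypo <- pmin(1, pmax(0, lev[, 2] +
                             ifelse(affected & !is_dmr, shift, 0)))
    m_mat <- ifelse(hyper == "maternal", m_hyper, m_hypo)
    m_pat <- ifelse(hyper == "maternal", m_hypo, m_hyper)
    cov_m <- stats::rpois(nr, scenario$meth_coverage)
    cov_p <- stats::rpois(nr, scenario$meth_coverage)
    meth_m <- rbetabinom(nr, cov_m, m_mat, scenario$meth_rho)
    meth_p <- rbetabinom(nr, cov_p, m_pat, scenario$meth_rho)
    base <- regions[, c("chrom", "start", "end", "name", "class")]
    rows[[length(rows) + 1L]] <- rbind(
      cbind(base, sample_id = sheet$sample_id[s], allele = "maternal",
            meth = meth_m, unmeth = cov_m - meth_m),
      cbind(base, sample_id = sheet$sample_id[s], allele = "paternal",
            meth = meth_p, unmeth = cov_p - meth_p),
      cbind(base, sample_id = sheet$sample_id[s], allele = "unsplit",
            meth = meth_m + meth_p, unmeth = (cov_m - meth_m) + (cov_p - meth_p)))
  }
  truth <- data.frame(regions[, c("name", "class")],
                      hyper_allele = hyper,
                      level_hyper = lev[, 1], level_hypo = lev[, 2],
                      affected = affected,
                      shift = ifelse(affected, scenario$meth_loi_shift, 0),
                      stringsAsFactors = FALSE)
  list(counts = do.call(rbind, rows), truth = truth)
}
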