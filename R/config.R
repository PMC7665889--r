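#' Analysis configuration
#'
#' Bundles every fixed constant of the imprinting analysis into a single
#' validated object. The defaults reproduce the published workflow:
#' expression filter at 1 cpm in at least a third of libraries, imprinting
#' screen at |log-ratio| >= log(1.5), coverage filter at 10 haplotyped counts
#' per sample, dual differential-imprinting rule (FDR < 0.05 and > 5 percentage
#' points change in silent-allele proportion), beta-binomial dispersion fixed
#' at 0.01, 100 kb segmentation bins with rpart options minsplit = 4 and
#' cp = 0.05, DMR filters (10 counts/sample, 10\% wild-type allelic
#' difference), 10\% genome-wide methylation difference, and 2 kb gene
#' association distance.
#'
#' @param cpm_min minimum counts-per-million for a library to count as
#'   expressing a gene.
#' @param cpm_frac_libs fraction of libraries that must reach `cpm_min`.
#' @param imprint_log_ratio_min minimum absolute natural-log maternal:paternal
#'   ratio for a gene to be called imprinted in wild type.
#' @param min_haplotyped_counts_per_sample minimum mean haplotyped
#'   (maternal + paternal) counts per sample required in every genotype.
#' @param fdr_alpha Benjamini-Hochberg adjusted p-value cutoff.
#' @param delta_silent_min minimum absolute change in mean silent-allele
#'   proportion (on [0,1]) required to call differential imprinting.
#' @param betabin_phi fixed beta-binomial intraclass correlation.
#' @param bin_width width in bp of the genomic bins used for segmentation.
#' @param tree_minsplit minimum node size for a segmentation split.
#' @param tree_cp complexity parameter: a split must reduce the chromosome's
#'   root sum of squares by at least this fraction.
#' @param zygosity_threshold fitted Cast proportion at or above which a
#'   segment is called heterozygous.
#' @param min_bin_depth bins with fewer allelic reads than this are set to NA
#'   before segmentation.
#' @param dmr_min_counts minimum mean counts per sample for a DMR to be tested.
#' @param dmr_wt_allelic_diff_min minimum wild-type maternal-paternal
#'   methylation difference (on [0,1]) for a DMR to be tested.
#' @param meth_diff_min minimum absolute methylation-proportion difference for
#'   a genome-wide call.
#' @param gene_assoc_dist maximum distance in bp for region-to-gene annotation.
#' @param excluded_genes genes removed from imprinting analysis regardless of
#'   counts (the default removes Gatm, whose maternal bias reflects maternal
#'   decidua contamination rather than imprinting).
#' @param sex_threshold minimum paternal-X fraction of X-linked allelic reads
#'   for a female call.
#' @param contamination_threshold genome-wide maternal-allele fraction at or
#'   above which an embryo is flagged as maternally contaminated.
#' @param cre_in_model whether the Cre line enters the paired design as an
#'   allele-by-Cre term when both Cre lines are present.
#' @param rng_seed seed used by pipeline stages that draw random numbers.
#' @return An object of class `imprint_config` (a validated named list).
#' @export
analysis_config <- function(cpm_min = 1,
                            cpm_frac_libs = 1 / 3,
                            imprint_log_ratio_min = log(1.5),
                            min_haplotyped_counts_per_sample = 10,
                            fdr_alpha = 0.05,
                            delta_silent_min = 0.05,
                            betabin_phi = 0.01,
                            bin_width = 100000L,
                            tree_minsplit = 4L,
                            tree_cp = 0.05,
                            zygosity_threshold = 0.25,
                            min_bin_depth = 5L,
                            dmr_min_counts = 10,
                            dmr_wt_allelic_diff_min = 0.10,
                            meth_diff_min = 0.10,
                            gene_assoc_dist = 2000L,
                            excluded_genes = "Gatm",
                            sex_threshold = 0.25,
                            contamination_threshold = 0.65,
                            cre_in_model = TRUE,
                            rng_seed = 1L) {
  cfg <- list(
    cpm_min = as.numeric(cpm_min),
    cpm_frac_libs = as.numeric(cpm_frac_libs),
    imprint_log_ratio_min = as.numeric(imprint_log_ratio_min),
    min_haplotyped_counts_per_sample = as.numeric(min_haplotyped_counts_per_sample),
    fdr_alpha = as.numeric(fdr_alpha),
    delta_silent_min = as.numeric(delta_silent_min),
    betabin_phi = as.numeric(betabin_phi),
    bin_width = as.integer(bin_width),
    tree_minsplit = as.integer(tree_minsplit),
    tree_cp = as.numeric(tree_cp),
    zygosity_threshold = as.numeric(zygosity_threshold),
    min_bin_depth = as.integer(min_bin_depth),
    dmr_min_counts = as.numeric(dmr_min_counts),
    dmr_wt_allelic_diff_min = as.numeric(dmr_wt_allelic_diff_min),
    meth_diff_min = as.numeric(meth_diff_min),
    gene_assoc_dist = as.integer(gene_assoc_dist),
    excluded_genes = as.character(excluded_genes),
    sex_threshold = as.numeric(sex_threshold),
    contamination_threshold = as.numeric(contamination_threshold),
    cre_in_model = isTRUE(cre_in_model),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "imprint_config")
}

validate_config <- function(cfg) {
  probs <- c("cpm_frac_libs", "fdr_alpha", "delta_silent_min", "betabin_phi",
             "zygosity_threshold", "dmr_wt_allelic_diff_min", "meth_diff_min",
             "sex_threshold", "contamination_threshold", "tree_cp")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a probability in [0,1]", p))
  }
  pos <- c("cpm_min", "imprint_log_ratio_min",
           "min_haplotyped_counts_per_sample", "bin_width", "tree_minsplit",
           "dmr_min_counts", "gene_assoc_dist")
  for (p in pos) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config field '%s' must be strictly positive", p))
  }
  if (cfg$betabin_phi >= 1) stop("betabin_phi must lie in [0,1)")
  invisible(cfg)
}

#' @export
print.imprint_config <- function(x, ...) {
  cat("Imprinting analysis configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-34s %s\n", nm, paste(format(val, digits = 6), collapse = ", ")))
  }
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' Only fields of [analysis_config()] are accepted; unknown keys error so
#' typos in a config file cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return `read_config` returns an `imprint_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config an `imprint_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "imprint_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
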