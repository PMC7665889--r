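#' Segment binned allelic proportions into zygosity blocks
#'
#' For an N1 backcross sample, fits a recursive-partitioning regression tree
#' (rpart, anova method) per chromosome to the Cast read proportion of each
#' 100 kb bin as a function of bin position, with `minsplit` and `cp` from
#' the configuration. Tree leaves are intervals of bins and become
#' piecewise-constant segments; a segment is called heterozygous when its
#' fitted proportion is at or above `zygosity_threshold` (default 0.25, the
#' midpoint between the expected 0.5 of a heterozygous region and ~0 of a
#' homozygous-B6 region). Bins with fewer than `min_bin_depth` allelic reads
#' are set to NA and skipped; their positions are preserved so segment
#' coordinates stay on the bin grid.
#'
#' @param track data.frame for one sample with columns `chrom`, `bin_start`,
#'   `cast`, `total` (and optionally `sample_id`).
#' @param config an [analysis_config()].
#' @param sample_id sample label stored in the model; defaults to the
#'   track's `sample_id` column.
#' @return An object of class `segment_model`: list with `sample_id` and
#'   `segments` (data.frame chrom, first_bin, last_bin, n_bins,
#'   fitted_proportion, zygosity), bins indexed from 0 per chromosome.
#' @export
segment_allelic_proportions <- function(track, config = analysis_config(),
                                        sample_id = NULL) {
  stopifnot(all(c("chrom", "bin_start", "cast", "total") %in% names(track)))
  if (is.null(sample_id))
    sample_id <- if ("sample_id" %in% names(track)) track$sample_id[1] else NA_character_
  bw <- config$bin_width
  segs <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$bin_start), , drop = FALSE]
    bin <- as.integer(round(tr$bin_start / bw))
    prop <- ifelse(tr$total >= config$min_bin_depth & tr$total > 0,
                   tr$cast / tr$total, NA_real_)
    keep <- !is.na(prop)
    if (!any(keep)) {
      warning(sprintf("chromosome %s has no usable bins for sample %s",
                      ch, sample_id))
      next
    }
    x <- bin[keep]; y <- prop[keep]
    if (length(y) < 2L || stats::var(y) == 0) {
      leaf <- rep(1L, length(y))
    } else {
      fit <- rpart::rpart(y ~ x, data = data.frame(x = x, y = y),
                          method = "anova",
                          control = rpart::rpart.control(
                            minsplit = config$tree_minsplit,
                            cp = config$tree_cp,
                            xval = 0, maxcompete = 0, maxsurrogate = 0))
      leaf <- fit$where
    }
    # leaves of a tree on bin position are contiguous runs along the bin order
    run <- cumsum(c(1L, diff(leaf) != 0L))
    for (r in unique(run)) {
      i <- which(run == r)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, first_bin = x[i[1]], last_bin = x[i[length(i)]],
        n_bins = length(i), fitted_proportion = mean(y[i]),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), first_bin = integer(),
               last_bin = integer(), n_bins = integer(),
               fitted_proportion = numeric(), stringsAsFactors = FALSE)
  segments$zygosity <- ifelse(
    segments$fitted_proportion >= config$zygosity_threshold, "het", "hom")
  structure(list(sample_id = sample_id, segments = segments,
                 bin_width = bw), class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  s <- x$segments
  cat(sprintf("segment_model for sample %s: %d segments on %d chromosomes\n",
              x$sample_id, nrow(s), length(unique(s$chrom))))
  if (nrow(s))
    cat(sprintf("  het fraction of bins: %.2f\n",
                sum(s$n_bins[s$zygosity == "het"]) / sum(s$n_bins)))
  invisible(x)
}

#' Project segment zygosity onto genes
#'
#' A gene is informative in a sample when the segment containing its
#' midpoint is heterozygous. Genes on chromosomes absent from the segment
#' model, or whose midpoint falls in no segment (e.g. a zero-coverage
#' stretch), are non-informative.
#'
#' @param model a `segment_model` (or list of them, one per sample).
#' @param genes gene annotation data.frame with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @return logical vector named by gene (single model) or gene x sample
#'   logical matrix (list of models).
#' @export
project_informativeness <- function(model, genes) {
  if (inherits(model, "segment_model")) {
    return(project_one(model, genes))
  }
  stopifnot(is.list(model), all(vapply(model, inherits, TRUE, "segment_model")))
  m <- vapply(model, project_one, logical(nrow(genes)), genes = genes)
  dimnames(m) <- list(genes$gene_id,
                      vapply(model, `[[`, "", "sample_id"))
  m
}

project_one <- function(model, genes) {
  segs <- model$segments
  mid_bin <- floor(((genes$start + genes$end) / 2) / model$bin_width)
  out <- logical(nrow(genes))
  missing_chrom <- setdiff(unique(genes$chrom), unique(segs$chrom))
  if (length(missing_chrom))
    warning("no segments for chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  for (i in seq_len(nrow(genes))) {
    hit <- segs$chrom == genes$chrom[i] &
      segs$first_bin <= mid_bin[i] & segs$last_bin >= mid_bin[i]
    out[i] <- any(hit) && segs$zygosity[which(hit)[1]] == "het"
  }
  names(out) <- genes$gene_id
  out
}

#' Apply informativeness to an allele count matrix
#'
#' Marks gene/sample cells non-informative (allelic counts treated as
#' missing) where the sample's segment model places the gene outside a
#' heterozygous segment. F1 samples, which are heterozygous genome-wide,
#' bypass segmentation: their informativeness is the matrix's own flags.
#'
#' @param counts an `allele_counts` object.
#' @param models named list of `segment_model`s (names = sample ids; samples
#'   without a model are left unchanged).
#' @return the updated `allele_counts` object.
#' @export
apply_informativeness <- function(counts, models) {
  stopifnot(inherits(counts, "allele_counts"))
  for (s in intersect(names(models), counts$samples)) {
    keep <- project_one(models[[s]], counts$genes)
    drop <- counts$informative[, s] & !keep
    counts$informative[, s] <- counts$informative[, s] & keep
    counts$maternal[drop, s] <- NA_integer_
    counts$paternal[drop, s] <- NA_integer_
  }
  counts
}
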