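#' Pooled allelic log-ratio
#'
#' Maximum-likelihood log-odds of the intercept-only binomial (logistic)
#' model on per-sample maternal/paternal counts, which has the closed form
#' ln(sum maternal / sum paternal). When exactly one pooled sum is zero a
#' Haldane-Anscombe pseudocount of 0.5 is added to both sums; when both are
#' zero the ratio is undefined and NA is returned. The function is exactly
#' antisymmetric in its arguments.
#'
#' @param maternal,paternal per-sample count vectors (NA cells ignored).
#' @return natural-log maternal:paternal ratio, positive for maternal bias.
#' @export
allelic_log_ratio <- function(maternal, paternal) {
  sm <- sum(maternal, na.rm = TRUE)
  sp <- sum(paternal, na.rm = TRUE)
  if (sm == 0 && sp == 0) return(NA_real_)
  if (sm == 0 || sp == 0) {
    sm <- sm + 0.5
    sp <- sp + 0.5
  }
  log(sm) - log(sp)  # exactly antisymmetric, unlike log(sm/sp)
}

#' Call imprinted genes in wild-type samples
#'
#' The candidate set is the known-imprinted genes that are autosomal,
#' expressed (see [filter_expressed()]) and not excluded by configuration
#' (by default Gatm, whose maternal bias reflects maternal tissue
#' contamination). A candidate is called imprinted when the absolute pooled
#' wild-type log-ratio is at least `imprint_log_ratio_min` (log 1.5); the
#' boundary value itself is retained. The silent allele is paternal when the
#' ratio is positive (maternal-expressed gene) and maternal when negative.
#' Genes are then flagged untestable when any genotype lacks an average of
#' `min_haplotyped_counts_per_sample` haplotyped (maternal + paternal)
#' counts over its informative samples.
#'
#' @param counts an `allele_counts` object.
#' @param sheet sample sheet data.frame.
#' @param config an [analysis_config()].
#' @param expressed character vector of expressed gene ids; computed with
#'   [filter_expressed()] when NULL.
#' @return data.frame of class `imprinting_calls`: gene_id, chrom, cluster,
#'   log_ratio, imprinted, silent_allele, testable, and one
#'   `mean_counts.<genotype>` column per genotype.
#' @export
call_imprinted <- function(counts, sheet, config = analysis_config(),
                           expressed = NULL) {
  stopifnot(inherits(counts, "allele_counts"))
  sheet <- validate_sample_sheet(sheet)
  wt <- sheet$sample_id[sheet$genotype == "wt"]
  if (!length(wt)) stop("no wild-type samples in the sample sheet")
  if (is.null(expressed)) expressed <- filter_expressed(counts, config)

  genes <- counts$genes
  autosomal <- !genes$chrom %in% c("chrX", "chrY", "chrM", "X", "Y", "MT")
  cand <- genes$is_known_imprinted & autosomal &
    genes$gene_id %in% expressed & !genes$gene_id %in% config$excluded_genes
  idx <- which(cand)

  genos <- unique(sheet$genotype)
  res <- data.frame(gene_id = genes$gene_id[idx],
                    chrom = genes$chrom[idx],
                    cluster = genes$cluster[idx],
                    log_ratio = NA_real_, imprinted = FALSE,
                    silent_allele = NA_character_, testable = FALSE,
                    stringsAsFactors = FALSE)
  for (g in genos) res[[paste0("mean_counts.", g)]] <- NA_real_

  hap <- counts$maternal + counts$paternal   # NA where non-informative
  for (k in seq_along(idx)) {
    i <- idx[k]
    res$log_ratio[k] <- allelic_log_ratio(counts$maternal[i, wt],
                                          counts$paternal[i, wt])
    for (g in genos) {
      ss <- sheet$sample_id[sheet$genotype == g]
      v <- hap[i, ss]
      res[[paste0("mean_counts.", g)]][k] <-
        if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }
  }
  res$imprinted <- !is.na(res$log_ratio) &
    abs(res$log_ratio) >= config$imprint_log_ratio_min
  res$silent_allele <- ifelse(res$imprinted,
                              ifelse(res$log_ratio > 0, "paternal", "maternal"),
                              NA_character_)
  covered <- rowSums(
    as.matrix(res[, paste0("mean_counts.", genos), drop = FALSE]) <
      config$min_haplotyped_counts_per_sample) == 0
  res$testable <- res$imprinted & covered
  class(res) <- c("imprinting_calls", "data.frame")
  res
}

#' @export
print.imprinting_calls <- function(x, ...) {
  cat(sprintf("imprinting_calls: %d candidates, %d imprinted, %d testable\n",
              nrow(x), sum(x$imprinted), sum(x$testable)))
  NextMethod()
}

#' Silent-allele proportion per gene and sample
#'
#' The expression of the normally silent allele as a proportion of total
#' allelic expression: silent / (maternal + paternal). NA where the gene is
#' non-informative in a sample, has zero haplotyped depth, or has no
#' assigned silent allele.
#'
#' @param counts an `allele_counts` object.
#' @param calls output of [call_imprinted()] (or any data.frame with
#'   `gene_id` and `silent_allele`).
#' @return numeric matrix (genes in `calls` x samples).
#' @export
silent_allele_proportions <- function(counts, calls) {
  stopifnot(inherits(counts, "allele_counts"))
  idx <- match(calls$gene_id, counts$genes$gene_id)
  if (any(is.na(idx))) stop("calls contain genes absent from the count matrix")
  m <- counts$maternal[idx, , drop = FALSE]
  p <- counts$paternal[idx, , drop = FALSE]
  depth <- m + p
  silent <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  i_m <- which(calls$silent_allele %in% "maternal")
  i_p <- which(calls$silent_allele %in% "paternal")
  silent[i_m, ] <- m[i_m, ]
  silent[i_p, ] <- p[i_p, ]
  out <- silent / depth
  out[!is.finite(out)] <- NA_real_
  rownames(out) <- calls$gene_id
  out
}
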