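#' Haplotype-resolved allele count matrix
#'
#' Container for gene-level maternal, paternal and total (non-haplotyped)
#' read counts across samples, together with gene annotation and per-sample
#' library sizes. Cells where the gene is not informative in a sample (no
#' strain-distinguishing SNP, or a homozygous region in a backcross sample)
#' carry `informative = FALSE`; every allelic computation in the package
#' treats those maternal/paternal counts as missing, while the total counts
#' are always retained.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open bp), `strand` (+/-/NA), `is_known_imprinted`
#'   (logical), `cluster` (character or NA).
#' @param maternal,paternal,total integer matrices, genes x samples, with
#'   column names giving the sample ids.
#' @param informative logical matrix of the same shape; defaults to cells
#'   with non-missing maternal and paternal counts.
#' @return An object of class `allele_counts`.
#' @export
allele_count_matrix <- function(genes, maternal, paternal, total,
                                informative = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique")
  if (any(genes$start >= genes$end))
    stop("gene annotation must satisfy start < end")
  if (!"strand" %in% names(genes)) genes$strand <- NA_character_
  if (!"is_known_imprinted" %in% names(genes)) genes$is_known_imprinted <- FALSE
  if (!"cluster" %in% names(genes)) genes$cluster <- NA_character_

  maternal <- as.matrix(maternal); paternal <- as.matrix(paternal)
  total <- as.matrix(total)
  samples <- colnames(total)
  if (is.null(samples)) stop("count matrices must have sample column names")
  if (!all(dim(maternal) == dim(total)) || !all(dim(paternal) == dim(total)))
    stop("maternal, paternal and total matrices must have identical shape")
  if (nrow(total) != nrow(genes))
    stop("count matrices must have one row per annotated gene")
  rownames(maternal) <- rownames(paternal) <- rownames(total) <- genes$gene_id

  if (is.null(informative)) {
    informative <- !(is.na(maternal) | is.na(paternal))
  }
  informative <- as.matrix(informative)
  dimnames(informative) <- dimnames(total)

  for (nm in c("maternal", "paternal", "total")) {
    m <- get(nm)
    if (any(m[!is.na(m)] < 0))
      stop(sprintf("negative %s count: counts must be non-negative integers", nm))
  }
  if (any(is.na(total))) stop("total counts must not be missing")
  m <- ifelse(informative, maternal, 0L)
  p <- ifelse(informative, paternal, 0L)
  m[is.na(m)] <- 0L; p[is.na(p)] <- 0L
  bad <- which(m + p > total, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "maternal + paternal exceeds total at gene '%s', sample '%s'",
      genes$gene_id[bad[1, 1]], samples[bad[1, 2]]))
  }
  maternal[!informative] <- NA_integer_
  paternal[!informative] <- NA_integer_

  structure(list(
    genes = genes,
    samples = samples,
    maternal = maternal,
    paternal = paternal,
    total = total,
    informative = informative,
    library_size = colSums(total)
  ), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d genes x %d samples\n",
              nrow(x$total), length(x$samples)))
  cat(sprintf("  informative cells: %.1f%%\n", 100 * mean(x$informative)))
  cat(sprintf("  known imprinted genes: %d\n", sum(x$genes$is_known_imprinted)))
  cat(sprintf("  median library size: %s\n",
              format(stats::median(x$library_size), big.mark = ",")))
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) dim(x$total)

#' Read and write allele count tables
#'
#' The on-disk layout is a tab-separated file with a `gene_id` column
#' followed by three columns per sample, `<sample>.maternal`,
#' `<sample>.paternal` and `<sample>.total`. Allelic cells left empty or
#' written as `.` mark non-informative gene/sample combinations; totals are
#' always required. Malformed files fail loudly: negative counts are a
#' format error, and a cell where maternal + paternal exceeds the total is
#' an integrity error naming the cell.
#'
#' @param path TSV file path.
#' @param annotation gene annotation data.frame (see
#'   [allele_count_matrix()]); rows are matched to the file by `gene_id`.
#' @return `read_allele_counts` returns an `allele_counts` object;
#'   `write_allele_counts` returns `path` invisibly.
#' @export
read_allele_counts <- function(path, annotation) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, na.strings = c(".", ""),
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be 'gene_id'")
  cols <- names(tab)[-1]
  parts <- regmatches(cols, regexec("^(.*)\\.(maternal|paternal|total)$", cols))
  if (any(lengths(parts) != 3))
    stop("sample columns must be named <sample>.maternal/.paternal/.total")
  samp <- vapply(parts, `[`, "", 2)
  kind <- vapply(parts, `[`, "", 3)
  samples <- unique(samp)
  grab <- function(k) {
    m <- as.matrix(tab[, -1, drop = FALSE][, kind == k, drop = FALSE])
    colnames(m) <- samp[kind == k]
    storage.mode(m) <- "integer"
    m[, samples, drop = FALSE]
  }
  ann <- annotation[match(tab$gene_id, annotation$gene_id), , drop = FALSE]
  if (any(is.na(ann$gene_id)))
    stop("genes in count file missing from annotation: ",
         paste(utils::head(setdiff(tab$gene_id, annotation$gene_id)), collapse = ", "))
  allele_count_matrix(ann, grab("maternal"), grab("paternal"), grab("total"))
}

#' @rdname read_allele_counts
#' @param x an `allele_counts` object.
#' @export
write_allele_counts <- function(x, path) {
  stopifnot(inherits(x, "allele_counts"))
  out <- data.frame(gene_id = x$genes$gene_id, stringsAsFactors = FALSE)
  fmt <- function(m) ifelse(is.na(m), ".", as.character(m))
  for (s in x$samples) {
    out[[paste0(s, ".maternal")]] <- fmt(x$maternal[, s])
    out[[paste0(s, ".paternal")]] <- fmt(x$paternal[, s])
    out[[paste0(s, ".total")]] <- as.character(x$total[, s])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `genotype` (wt/het/matD/zygD/
#'   matzygD), `cre` (MMTV/Zp3/none), `tissue`, `cross` (F1/N1),
#'   `maternal_strain`, `paternal_strain`, `sex` (M/F/NA).
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "genotype", "cre", "tissue", "cross")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("sample_id values must be unique")
  geno_ok <- c("wt", "het", "matD", "zygD", "matzygD")
  if (!all(sheet$genotype %in% geno_ok))
    stop("genotype must be one of: ", paste(geno_ok, collapse = ", "))
  if (!all(sheet$cross %in% c("F1", "N1")))
    stop("cross must be F1 or N1")
  sheet
}

#' Counts per million
#'
#' @param total counts matrix (genes x samples).
#' @param library_size per-sample library sizes; defaults to column sums.
#' @return matrix of cpm values.
#' @export
cpm <- function(total, library_size = colSums(total)) {
  total <- as.matrix(total)
  if (any(library_size <= 0)) stop("library sizes must be positive")
  sweep(total, 2, library_size, "/") * 1e6
}

#' Expression filter
#'
#' A gene is retained when at least `cpm_frac_libs` of the libraries show at
#' least `cpm_min` counts per million, computed on the total (non-haplotyped)
#' counts. The fractional threshold is compared as a real number, so with 6
#' libraries a gene expressed in exactly 2 passes (2 >= 6/3).
#'
#' @param counts an `allele_counts` object.
#' @param config an [analysis_config()].
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, config = analysis_config()) {
  stopifnot(inherits(counts, "allele_counts"))
  cp <- cpm(counts$total, counts$library_size)
  n_pass <- rowSums(cp >= config$cpm_min)
  counts$genes$gene_id[n_pass >= config$cpm_frac_libs * length(counts$samples)]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; NA values are passed through and do not count
#' toward the number of tests. Input order is preserved.
#'
#' @param pvalues numeric vector of p-values in [0,1] (NA allowed).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}
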