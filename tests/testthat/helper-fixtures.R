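# small hand-built fixtures shared across test files

toy_genes <- function(n = 3, chrom = "chr1", known = TRUE) {
  data.frame(gene_id = paste0("g", seq_len(n)), chrom = chrom,
             start = (seq_len(n) - 1) * 1e5, end = (seq_len(n) - 1) * 1e5 + 1e4,
             strand = "+", is_known_imprinted = known, cluster = NA_character_,
             stringsAsFactors = FALSE)
}

toy_counts <- function(maternal, paternal, total = maternal + paternal,
                       genes = NULL, samples = NULL) {
  maternal <- as.matrix(maternal); paternal <- as.matrix(paternal)
  total <- as.matrix(total)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(maternal)))
  colnames(maternal) <- colnames(paternal) <- colnames(total) <- samples
  if (is.null(genes)) genes <- toy_genes(nrow(maternal))
  allele_count_matrix(genes, maternal, paternal, total)
}

toy_sheet <- function(genotype, cre = "none", tissue = "placenta_E14.5",
                      cross = "F1", samples = NULL) {
  n <- length(genotype)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  data.frame(sample_id = samples, genotype = genotype,
             cre = rep_len(cre, n), tissue = tissue, cross = cross,
             maternal_strain = "C57BL/6", paternal_strain = "CAST/EiJ",
             sex = NA_character_, stringsAsFactors = FALSE)
}

# single-chromosome bin track with bins 0..(length(prop_counts)-1)
toy_track <- function(cast, total, chrom = "chr1", bin_width = 1e5) {
  data.frame(sample_id = "s1", chrom = chrom,
             bin_start = (seq_along(cast) - 1) * bin_width,
             cast = cast, total = total, stringsAsFactors = FALSE)
}
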