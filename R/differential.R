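#' Paired negative-binomial likelihood-ratio test of allelic balance
#'
#' Models the maternal and paternal counts of each gene as two
#' negative-binomial observations per sample with a log link. The full
#' design has one indicator per sample (the pairing factor, which absorbs
#' total expression and library depth), an allele main effect, and
#' allele-by-genotype interaction terms (plus allele-by-Cre terms when more
#' than one Cre line is present and `cre_in_model` is set); the null drops
#' the allele-by-genotype terms. Fitting and the likelihood-ratio test are
#' performed with edgeR's GLM machinery; all 2n allelic libraries are given
#' equal effective library sizes so that depth is carried entirely by the
#' pairing factor. Genes with any non-informative cell among the analysed
#' samples get an NA result with a reason (the beta-binomial engine exists
#' for that regime).
#'
#' @param maternal,paternal integer matrices (genes x samples) with NA in
#'   non-informative cells; column names are sample ids.
#' @param sheet sample sheet restricted to the samples under test (wild type
#'   plus the tested genotype(s)).
#' @param config an [analysis_config()].
#' @param dispersion optional per-gene NB dispersion (scalar or vector);
#'   estimated with [estimate_dispersions()] when NULL.
#' @param dispersion_mode `"tagwise"` (bulk) or `"common"` (single embryos).
#' @return data.frame: gene_id, engine, lrt_statistic, df, p, reason.
#' @export
fit_paired_nb <- function(maternal, paternal, sheet,
                          config = analysis_config(),
                          dispersion = NULL,
                          dispersion_mode = c("tagwise", "common")) {
  dispersion_mode <- match.arg(dispersion_mode)
  sheet <- validate_sample_sheet(sheet)
  maternal <- as.matrix(maternal); paternal <- as.matrix(paternal)
  stopifnot(identical(colnames(maternal), colnames(paternal)))
  maternal <- maternal[, sheet$sample_id, drop = FALSE]
  paternal <- paternal[, sheet$sample_id, drop = FALSE]
  gene_ids <- rownames(maternal)

  out <- data.frame(gene_id = gene_ids, engine = "paired_nb",
                    lrt_statistic = NA_real_, df = NA_integer_,
                    p = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  tab <- table(sheet$genotype)
  if (any(tab < 2) || length(tab) < 2) {
    out$reason <- "non-identifiable design: fewer than 2 samples in a genotype"
    return(out)
  }

  complete <- rowSums(is.na(maternal) | is.na(paternal)) == 0
  out$reason[!complete] <- "non-informative cells; use the beta-binomial engine"
  if (!any(complete)) return(out)

  y <- cbind(maternal[complete, , drop = FALSE],
             paternal[complete, , drop = FALSE])
  if (sum(complete) == 1L) y <- matrix(y, nrow = 1L,
                                       dimnames = list(gene_ids[complete], NULL))
  colnames(y) <- c(paste0(sheet$sample_id, ".m"), paste0(sheet$sample_id, ".p"))

  dd <- paired_design(sheet, config$cre_in_model)
  design <- dd$design; drop_cols <- dd$drop

  d <- edgeR::DGEList(counts = y, lib.size = rep(1e6, ncol(y)))
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersions(y, design, mode = dispersion_mode)
  }
  fit <- edgeR::glmFit(d, design, dispersion = dispersion)
  lrt <- edgeR::glmLRT(fit, coef = drop_cols)
  tt <- lrt$table
  out$lrt_statistic[complete] <- tt$LR
  out$df[complete] <- length(drop_cols)
  out$p[complete] <- tt$PValue
  out
}

# design for 2-observations-per-sample allelic counts: sample pairing factor,
# allele main effect, allele x genotype interactions (tested), allele x cre
paired_design <- function(sheet, cre_in_model = TRUE) {
  n <- nrow(sheet)
  samp <- factor(rep(sheet$sample_id, 2), levels = sheet$sample_id)
  allele <- rep(c(1, 0), each = n)  # 1 = maternal
  geno <- factor(rep(sheet$genotype, 2),
                 levels = c("wt", setdiff(unique(sheet$genotype), "wt")))
  design <- stats::model.matrix(~samp)
  design <- cbind(design, allele = allele)
  drop <- integer()
  for (g in levels(geno)[-1]) {
    design <- cbind(design, as.numeric(allele * (geno == g)))
    colnames(design)[ncol(design)] <- paste0("allele.", g)
    drop <- c(drop, ncol(design))
  }
  cre <- factor(rep(sheet$cre, 2))
  if (cre_in_model && nlevels(cre) > 1) {
    for (l in levels(cre)[-1]) {
      cand <- cbind(design, as.numeric(allele * (cre == l)))
      if (qr(cand)$rank == ncol(cand)) {
        design <- cand
        colnames(design)[ncol(design)] <- paste0("allele.cre", l)
      }
    }
  }
  list(design = design, drop = drop)
}

#' Estimate negative-binomial dispersions
#'
#' Common mode returns the single dispersion maximizing the pooled adjusted
#' profile likelihood across genes; tagwise mode returns per-gene estimates
#' shrunk toward the common trend by edgeR's weighted-likelihood scheme.
#'
#' @param counts count matrix (genes x libraries).
#' @param design model matrix for the mean structure.
#' @param mode `"common"` or `"tagwise"`.
#' @return per-gene dispersion vector (constant when `mode = "common"`).
#' @export
estimate_dispersions <- function(counts, design, mode = c("tagwise", "common")) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (all(counts == 0)) stop("all counts are zero; cannot estimate dispersion")
  d <- edgeR::DGEList(counts = counts, lib.size = rep(1e6, ncol(counts)))
  if (mode == "common") {
    d <- edgeR::estimateGLMCommonDisp(d, design)
    rep(d$common.dispersion, nrow(counts))
  } else {
    d <- edgeR::estimateDisp(d, design)
    d$tagwise.dispersion
  }
}

# beta-binomial log-likelihood, (mean pi, intraclass correlation rho)
bb_loglik <- function(y, n, pi, rho) {
  if (pi <= 0) return(if (all(y == 0)) 0 else -Inf)
  if (pi >= 1) return(if (all(y == n)) 0 else -Inf)
  if (rho <= 0) return(sum(stats::dbinom(y, n, pi, log = TRUE)))
  a <- pi * (1 - rho) / rho
  b <- (1 - pi) * (1 - rho) / rho
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

bb_fit_group <- function(y, n, rho) {
  # intercept-only beta-binomial MLE on the logit scale (1-D, deterministic)
  opt <- stats::optimize(function(eta) -bb_loglik(y, n, stats::plogis(eta), rho),
                         interval = c(-12, 12), tol = 1e-9)
  -opt$objective
}

#' Fixed-dispersion beta-binomial likelihood-ratio test
#'
#' Tests whether the maternal-allele proportion differs between genotypes
#' under a beta-binomial model with logit-linear mean (intercept plus
#' genotype) and the intraclass correlation fixed at `phi` (default 0.01).
#' Because the genotype groups are disjoint, the full-model maximum
#' likelihood separates into independent one-dimensional group fits, which
#' are solved deterministically on the logit scale. Samples with zero
#' informative depth are dropped; a genotype left with no informative
#' samples yields an NA result with a reason.
#'
#' @param maternal,paternal per-sample counts (NA = non-informative).
#' @param genotype character/factor of genotype labels per sample.
#' @param phi beta-binomial intraclass correlation in [0,1).
#' @return list with `lrt_statistic`, `df`, `p`, `reason`.
#' @export
betabin_lrt <- function(maternal, paternal, genotype, phi = 0.01) {
  if (phi < 0 || phi >= 1) stop("phi must lie in [0,1)")
  n <- maternal + paternal
  keep <- !is.na(n) & n > 0
  lev <- unique(as.character(genotype))
  empty <- setdiff(lev, unique(as.character(genotype)[keep]))
  if (length(empty)) {
    return(list(lrt_statistic = NA_real_, df = NA_integer_, p = NA_real_,
                reason = paste("genotype entirely non-informative:",
                               paste(empty, collapse = ", "))))
  }
  y <- maternal[keep]; nn <- n[keep]; g <- as.character(genotype)[keep]
  if (length(unique(g)) < 2) {
    return(list(lrt_statistic = NA_real_, df = NA_integer_, p = NA_real_,
                reason = "fewer than two genotypes with informative samples"))
  }
  ll_null <- bb_fit_group(y, nn, phi)
  ll_full <- sum(vapply(split(seq_along(y), g), function(i) {
    bb_fit_group(y[i], nn[i], phi)
  }, numeric(1)))
  stat <- max(0, 2 * (ll_full - ll_null))
  df <- length(unique(g)) - 1L
  list(lrt_statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), reason = NA_character_)
}

#' Differential-imprinting test over a gene set
#'
#' Runs one of the two engines over the testable genes of an imprinting
#' call set: `paired_nb` (complete informativeness, e.g. F1 crosses) or
#' `betabin` (mosaic informativeness, e.g. N1 backcrosses).
#'
#' @param counts an `allele_counts` object.
#' @param sheet sample sheet restricted to wild type plus tested genotype(s).
#' @param calls output of [call_imprinted()]; only `testable` genes are run.
#' @param config an [analysis_config()].
#' @param engine `"paired_nb"` or `"betabin"`.
#' @param dispersion_mode for the paired engine: `"tagwise"` or `"common"`.
#' @return data.frame gene_id, engine, lrt_statistic, df, p, reason.
#' @export
test_differential_imprinting <- function(counts, sheet, calls,
                                         config = analysis_config(),
                                         engine = c("paired_nb", "betabin"),
                                         dispersion_mode = c("tagwise", "common")) {
  engine <- match.arg(engine)
  dispersion_mode <- match.arg(dispersion_mode)
  sheet <- validate_sample_sheet(sheet)
  gene_ids <- calls$gene_id[calls$testable]
  idx <- match(gene_ids, counts$genes$gene_id)
  m <- counts$maternal[idx, sheet$sample_id, drop = FALSE]
  p <- counts$paternal[idx, sheet$sample_id, drop = FALSE]
  rownames(m) <- rownames(p) <- gene_ids
  if (engine == "paired_nb") {
    fit_paired_nb(m, p, sheet, config, dispersion_mode = dispersion_mode)
  } else {
    rows <- lapply(seq_along(gene_ids), function(i) {
      r <- betabin_lrt(m[i, ], p[i, ], sheet$genotype, phi = config$betabin_phi)
      data.frame(gene_id = gene_ids[i], engine = "betabin",
                 lrt_statistic = r$lrt_statistic, df = r$df, p = r$p,
                 reason = r$reason, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}

#' Apply the dual differential-imprinting calling rule
#'
#' Benjamini-Hochberg adjusts the engine p-values across the tested genes,
#' computes the change in mean silent-allele proportion (unweighted mean of
#' per-sample proportions, test genotype minus wild type) for every
#' contrast, and calls a gene when the adjusted p-value is below
#' `fdr_alpha` and the absolute change exceeds `delta_silent_min` for at
#' least one contrast. When more than one Cre line is present the change is
#' computed per Cre stratum (against the wild-type samples of the same
#' stratum), so the effect-size criterion can be met by either Cre line.
#'
#' @param results engine output from [test_differential_imprinting()].
#' @param silent_table matrix from [silent_allele_proportions()].
#' @param sheet sample sheet used for the test.
#' @param config an [analysis_config()].
#' @return data.frame of class `diff_imprinting`: results columns plus
#'   p_adj, one `delta.*` column per contrast, max_abs_delta and called.
#' @export
call_differential <- function(results, silent_table, sheet,
                              config = analysis_config()) {
  sheet <- validate_sample_sheet(sheet)
  res <- results
  res$p_adj <- bh_adjust(res$p)
  genos <- setdiff(unique(sheet$genotype), "wt")
  cres <- unique(sheet$cre)
  st <- silent_table[res$gene_id, , drop = FALSE]
  grp_mean <- function(samples) {
    v <- st[, samples, drop = FALSE]
    out <- rowMeans(v, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  deltas <- list()
  for (g in genos) {
    if (length(cres) > 1) {
      for (cr in cres) {
        ts <- sheet$sample_id[sheet$genotype == g & sheet$cre == cr]
        ws <- sheet$sample_id[sheet$genotype == "wt" & sheet$cre == cr]
        if (length(ts) && length(ws))
          deltas[[paste0("delta.", g, ".", cr)]] <- grp_mean(ts) - grp_mean(ws)
      }
    } else {
      ts <- sheet$sample_id[sheet$genotype == g]
      ws <- sheet$sample_id[sheet$genotype == "wt"]
      deltas[[paste0("delta.", g)]] <- grp_mean(ts) - grp_mean(ws)
    }
  }
  for (nm in names(deltas)) res[[nm]] <- deltas[[nm]]
  dmat <- abs(as.matrix(as.data.frame(deltas)))
  res$max_abs_delta <- if (length(deltas)) {
    suppressWarnings(apply(dmat, 1, max, na.rm = TRUE))
  } else NA_real_
  res$max_abs_delta[!is.finite(res$max_abs_delta)] <- NA_real_
  res$called <- !is.na(res$p_adj) & res$p_adj < config$fdr_alpha &
    !is.na(res$max_abs_delta) & res$max_abs_delta > config$delta_silent_min
  class(res) <- c("diff_imprinting", "data.frame")
  res
}

#' @export
print.diff_imprinting <- function(x, ...) {
  eng <- if ("engine" %in% names(x)) paste(unique(x$engine), collapse = "/")
         else "unknown"
  cat(sprintf("diff_imprinting: %d genes tested (%s engine), %d called\n",
              nrow(x), eng, sum(x$called)))
  NextMethod()
}
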