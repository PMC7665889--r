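#' Run the imprinting analysis pipeline end to end
#'
#' Orchestrates the stages `simulate`, `segment`, `call-imprinted`, `test`,
#' `methylation` and `report` on a synthetic scenario, writing deterministic
#' TSV outputs and a JSON run manifest (configuration snapshot, seed,
#' per-stage row counts and output digests) to `out_dir`. Identical
#' configuration, scenario and seed give byte-identical result files. The
#' `segment` stage runs only for N1 scenarios; `test` picks the paired
#' negative-binomial engine when informativeness is complete and the
#' beta-binomial engine otherwise (overridable via `engine`). A stage whose
#' upstream outputs are missing aborts with a dependency error naming the
#' missing file.
#'
#' @param config an [analysis_config()].
#' @param scenario a [simulation_scenario()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, in order.
#' @param seed optional integer overriding the scenario seed.
#' @param engine optional engine override for the `test` stage.
#' @return invisibly, the path of the manifest file.
#' @export
run_pipeline <- function(config = analysis_config(),
                         scenario = simulation_scenario(),
                         out_dir,
                         stages = c("simulate", "segment", "call-imprinted",
                                    "test", "methylation", "report"),
                         seed = NULL, engine = NULL) {
  known <- c("simulate", "segment", "call-imprinted", "test", "methylation",
             "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pp(f)))
      stop(sprintf("dependency error: stage '%s' requires missing file '%s'",
                   stage, f))
  }
  wtsv <- function(x, f) utils::write.table(
    x, pp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  rtsv <- function(f) utils::read.delim(pp(f), sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE)
  manifest <- list(tool = "imprintcall",
                   version = as.character(utils::packageVersion("imprintcall")),
                   seed = scenario$seed,
                   config = unclass(config),
                   stages = list())
  log_stage <- function(stage, files) {
    message(sprintf("[%s] wrote %s", stage, paste(files, collapse = ", ")))
    manifest$stages[[stage]] <<- list(
      files = files,
      rows = vapply(files, function(f) {
        if (grepl("\\.tsv$", f)) nrow(rtsv(f)) else NA_integer_
      }, 0L),
      md5 = vapply(file.path(out_dir, files), function(f)
        unname(tools::md5sum(f)), ""))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- simulate_expression(scenario)
      write_allele_counts(sim$counts, pp("counts.tsv"))
      wtsv(sim$counts$genes, "genes.tsv")
      wtsv(sim$sheet, "samples.tsv")
      wtsv(sim$truth, "truth.tsv")
      files <- c("counts.tsv", "genes.tsv", "samples.tsv", "truth.tsv")
      if (scenario$cross == "N1") {
        bins <- simulate_backcross_bins(scenario, bin_width = config$bin_width)
        wtsv(bins$track, "bins.tsv")
        wtsv(bins$truth, "segments_truth.tsv")
        files <- c(files, "bins.tsv", "segments_truth.tsv")
      }
      meth <- simulate_methylation(scenario, sheet = sim$sheet)
      wtsv(meth$counts, "methylation.tsv")
      wtsv(meth$truth, "methylation_truth.tsv")
      files <- c(files, "methylation.tsv", "methylation_truth.tsv")
      log_stage(stage, files)
    } else if (stage == "segment") {
      if (!file.exists(pp("bins.tsv"))) {
        message("[segment] no bin track (F1 scenario); skipping")
        next
      }
      track <- rtsv("bins.tsv")
      genes <- rtsv("genes.tsv")
      segs <- lapply(split(track, track$sample_id), segment_allelic_proportions,
                     config = config)
      seg_tab <- do.call(rbind, lapply(segs, function(m)
        cbind(sample_id = m$sample_id, m$segments)))
      wtsv(seg_tab, "segments.tsv")
      inf <- project_informativeness(segs, genes)
      wtsv(data.frame(gene_id = rownames(inf), inf, check.names = FALSE),
           "informative.tsv")
      log_stage(stage, c("segments.tsv", "informative.tsv"))
    } else if (stage == "call-imprinted") {
      for (f in c("counts.tsv", "genes.tsv", "samples.tsv")) need(f, stage)
      counts <- read_allele_counts(pp("counts.tsv"), rtsv("genes.tsv"))
      sheet <- read_sample_sheet(pp("samples.tsv"))
      calls <- call_imprinted(counts, sheet, config)
      wtsv(as.data.frame(calls), "imprinting_calls.tsv")
      st <- silent_allele_proportions(counts, calls)
      wtsv(data.frame(gene_id = rownames(st), round(st, 6), check.names = FALSE),
           "silent_allele_proportions.tsv")
      log_stage(stage, c("imprinting_calls.tsv", "silent_allele_proportions.tsv"))
    } else if (stage == "test") {
      for (f in c("counts.tsv", "genes.tsv", "samples.tsv",
                  "imprinting_calls.tsv")) need(f, stage)
      counts <- read_allele_counts(pp("counts.tsv"), rtsv("genes.tsv"))
      sheet <- read_sample_sheet(pp("samples.tsv"))
      calls <- rtsv("imprinting_calls.tsv")
      if (is.null(engine)) {
        idx <- match(calls$gene_id[calls$testable], counts$genes$gene_id)
        complete <- all(counts$informative[idx, , drop = FALSE])
        engine <- if (complete) "paired_nb" else "betabin"
      }
      res <- test_differential_imprinting(counts, sheet, calls, config,
                                          engine = engine)
      st <- silent_allele_proportions(counts, calls)
      res <- call_differential(res, st, sheet, config)
      wtsv(as.data.frame(res), "differential_imprinting.tsv")
      log_stage(stage, "differential_imprinting.tsv")
    } else if (stage == "methylation") {
      for (f in c("methylation.tsv", "samples.tsv")) need(f, stage)
      mc <- rtsv("methylation.tsv")
      sheet <- read_sample_sheet(pp("samples.tsv"))
      test_geno <- setdiff(unique(sheet$genotype), "wt")[1]
      dmr <- mc[grepl("DMR", mc$class), , drop = FALSE]
      testable <- select_testable_dmrs(dmr, sheet, config, test_geno)
      dres <- test_dmr_differential(dmr, testable, sheet, config, test_geno)
      wtsv(dres, "dmr_results.tsv")
      gw <- test_genomewide_methylation(mc, sheet, config, test_geno)
      wtsv(gw, "genomewide_methylation.tsv")
      log_stage(stage, c("dmr_results.tsv", "genomewide_methylation.tsv"))
    } else if (stage == "report") {
      need("differential_imprinting.tsv", stage)
      rep <- report(out_dir)
      wtsv(rep, "report.tsv")
      log_stage(stage, "report.tsv")
    }
  }
  jsonlite::write_json(manifest, pp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(pp("manifest.json"))
}

#' Summarise differential-imprinting results
#'
#' Builds a per-gene summary table (gene, cluster, engine, silent-allele
#' change, adjusted p-value, call) from a pipeline results directory. A pure
#' function of the directory contents: rerunning on the same directory
#' returns the identical table.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @return data.frame, one row per tested gene, ordered by gene id.
#' @export
report <- function(results_dir) {
  fp <- function(f) file.path(results_dir, f)
  for (f in c("differential_imprinting.tsv", "imprinting_calls.tsv")) {
    if (!file.exists(fp(f)))
      stop(sprintf("dependency error: report requires missing file '%s'", f))
  }
  res <- utils::read.delim(fp("differential_imprinting.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  calls <- utils::read.delim(fp("imprinting_calls.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  if (!nrow(res)) {
    return(data.frame(gene_id = character(), cluster = character(),
                      engine = character(), silent_allele = character(),
                      max_abs_delta = numeric(), p_adj = numeric(),
                      called = logical(), stringsAsFactors = FALSE))
  }
  i <- match(res$gene_id, calls$gene_id)
  out <- data.frame(gene_id = res$gene_id,
                    cluster = calls$cluster[i],
                    engine = res$engine,
                    silent_allele = calls$silent_allele[i],
                    max_abs_delta = res$max_abs_delta,
                    p_adj = res$p_adj,
                    called = res$called,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}
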