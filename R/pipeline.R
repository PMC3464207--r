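#' Run the full screening pipeline on a simulated experiment
#'
#' Executes the stages in fixed order on data generated from a
#' [SimConfig-class]: array simulation, preprocessing, splicing-index
#' screen, RT-PCR-style validation of the called events (psi and the
#' fold-change criterion), gene-level differential expression, and motif
#' analysis of simulated splice-site windows. Thresholds default to the
#' screen's standard values: per-probe-set alpha 0.05, psi fold 1.5,
#' expression fold 1.5, FDR 0.15, 50-nt motif windows.
#'
#' When `outDir` is given, each result table is written as TSV with a
#' header comment carrying the seed, so identical configurations produce
#' byte-identical outputs.
#'
#' @param config a [SimConfig-class].
#' @param alpha per-probe-set significance threshold.
#' @param psiFold RT-PCR fold-change criterion.
#' @param exprFold,maxFdr expression selection cutoffs.
#' @param motifWindow intron window length for the motif stage.
#' @param outDir optional output directory for TSV results.
#' @return list with `truth`, `calls`, `tests`, `psi`, `expression`,
#'   `motif` (k-mer enrichment + discovered model) and `performance`
#'   (tier-1 recall/precision against the truth table).
#' @examples
#' res <- runPipeline(SimConfig(nGenes = 8, nCassetteEvents = 2, seed = 1))
#' res$performance
#' @export
runPipeline <- function(config, alpha = 0.05, psiFold = 1.5, exprFold = 1.5,
                        maxFdr = 0.15, motifWindow = 50L, outDir = NULL) {
  stopifnot(is(config, "SimConfig"))
  se <- simulateArray(config)
  truth <- simTruth(se)
  screen <- screenSplicingEvents(se, alpha = alpha)

  bands <- simulateRtPcr(truth, bandNoiseCv = 0.05, seed = config@seed)
  psi_tab <- psiFromBands(bands, fold = psiFold)

  expr <- differentialExpression(screen$signals)
  changed <- selectChangedGenes(expr, minFold = exprFold, maxFdr = maxFdr)

  win <- simulateSpliceSiteWindows(
    nFg = max(10L, config@nCassetteEvents), nBg = max(10L, config@nCassetteEvents),
    windowLen = motifWindow, seed = config@seed)
  fg <- as.character(win$sequences[win$truth$is_foreground])
  bg <- as.character(win$sequences[!win$truth$is_foreground])
  enrich <- kmerEnrichment(fg, bg, k = 3L)
  model <- discoverMotifZoops(fg, w = 3L, seed = config@seed)

  perf <- tierPerformance(screen$calls, truth)
  out <- list(truth = truth, calls = screen$calls, tests = screen$tests,
              psi = psi_tab, expression = expr, changed_genes = changed,
              motif = list(enrichment = enrich, model = model,
                           windows = win$truth),
              performance = perf)
  if (!is.null(outDir)) write_pipeline_outputs(out, config, outDir)
  out
}

#' Tier-1 recall and precision against a truth table
#'
#' @param calls event calls from [callSplicingEvents()].
#' @param truth truth table ([simTruth()]).
#' @return named numeric with `recall`, `precision`, `n_tier1`,
#'   `n_differential`. Precision is NA when nothing reached tier 1.
#' @export
tierPerformance <- function(calls, truth) {
  tier1 <- calls$event_id[calls$tier == "tier1"]
  pos <- truth$event_id[truth$is_differential]
  tp <- length(intersect(tier1, pos))
  c(recall = if (length(pos)) tp / length(pos) else NA_real_,
    precision = if (length(tier1)) tp / length(tier1) else NA_real_,
    n_tier1 = length(tier1), n_differential = length(pos))
}

write_pipeline_outputs <- function(res, config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# spliceScreen seed=%d nGenes=%d nEvents=%d",
                   config@seed, config@nGenes, config@nCassetteEvents)
  write_tsv <- function(df, name) {
    path <- file.path(outDir, name)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  }
  write_tsv(res$truth, "truth.tsv")
  write_tsv(res$calls, "event_calls.tsv")
  write_tsv(res$tests, "probe_set_tests.tsv")
  write_tsv(res$psi, "psi.tsv")
  write_tsv(res$expression, "expression.tsv")
  write_tsv(res$motif$enrichment, "kmer_enrichment.tsv")
  invisible(outDir)
}
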