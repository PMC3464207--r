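#' Construct a simulation configuration
#'
#' Defaults encode the benchmark conditions used throughout the package: a
#' 50-gene array with 10 cassette-exon events whose inclusion rate drops
#' from 0.8 in controls to 0.5 in mutants, 4 biological replicates per
#' genotype, log-normal measurement noise of 0.15 on the log2 scale, and a
#' modest exponential optical background.
#'
#' An equal number of silent genes accompanies the expressed ones by
#' default, so that — as on a real whole-transcriptome junction array —
#' the intensity mode sits at background level, where the RMA background
#' estimator expects it.
#'
#' @param nGenes,nUnexpressedGenes,nCassetteEvents,replicatesPerGenotype
#'   see class slots.
#' @param psiControl,psiMutant numeric vectors (recycled to
#'   `nCassetteEvents`) of per-event inclusion rates in each genotype.
#' @param noiseSdLog2,backgroundMean,affinitySdLog2 noise model parameters.
#' @param constitutiveSetsPerGene,probesPerSet array design parameters.
#' @param exprMeanLog2,exprSdLog2 per-gene expression distribution (log2).
#' @param seed integer seed.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nGenes = 10, nCassetteEvents = 2, seed = 1)
#' @export
SimConfig <- function(nGenes = 50L, nUnexpressedGenes = nGenes,
                      nCassetteEvents = 10L,
                      replicatesPerGenotype = 4L,
                      psiControl = 0.8, psiMutant = 0.5,
                      noiseSdLog2 = 0.15, backgroundMean = 20,
                      affinitySdLog2 = 0.25,
                      constitutiveSetsPerGene = 4L, probesPerSet = 4L,
                      exprMeanLog2 = 9, exprSdLog2 = 1, seed = 1L) {
  nCassetteEvents <- as.integer(nCassetteEvents)
  psi <- cbind(control = rep_len(as.numeric(psiControl), nCassetteEvents),
               mutant  = rep_len(as.numeric(psiMutant), nCassetteEvents))
  if (nCassetteEvents == 0L)
    psi <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("control", "mutant")))
  new("SimConfig",
      nGenes = as.integer(nGenes),
      nUnexpressedGenes = as.integer(nUnexpressedGenes),
      nCassetteEvents = nCassetteEvents,
      replicatesPerGenotype = as.integer(replicatesPerGenotype),
      psi = psi,
      noiseSdLog2 = as.numeric(noiseSdLog2),
      backgroundMean = as.numeric(backgroundMean),
      affinitySdLog2 = as.numeric(affinitySdLog2),
      constitutiveSetsPerGene = as.integer(constitutiveSetsPerGene),
      probesPerSet = as.integer(probesPerSet),
      exprMeanLog2 = as.numeric(exprMeanLog2),
      exprSdLog2 = as.numeric(exprSdLog2),
      seed = as.integer(seed))
}

#' @describeIn SimConfig display a configuration summary.
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nCassetteEvents,
      "cassette events,", object@replicatesPerGenotype, "replicates/genotype\n")
  cat("  noiseSdLog2 =", object@noiseSdLog2,
      " backgroundMean =", object@backgroundMean,
      " affinitySdLog2 =", object@affinitySdLog2, "\n")
  cat("  seed =", object@seed, "\n")
})

#' Construct a probe-level junction-array experiment
#'
#' @param intensity probe x sample matrix of positive intensities; rownames
#'   are probe ids, colnames sample ids.
#' @param probeAnnotation data.frame with one row per probe carrying at
#'   least `probe_set_id`, `gene_id`, `event_id`, `role` and the five filter
#'   flags (`flag_constitutive`, `flag_multi_gene`, `flag_alt_promoter`,
#'   `flag_conserved`, `flag_neuron_specific`).
#' @param genotype character/factor of per-sample genotypes
#'   (`"control"`/`"mutant"`).
#' @param metadata optional list stored as experiment metadata.
#' @return A [JunctionArrayExperiment-class].
#' @export
JunctionArrayExperiment <- function(intensity, probeAnnotation, genotype,
                                    metadata = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = as.matrix(intensity)),
    rowData = S4Vectors::DataFrame(probeAnnotation),
    colData = S4Vectors::DataFrame(genotype = factor(genotype)),
    metadata = metadata)
  new("JunctionArrayExperiment", se)
}

#' @describeIn JunctionArrayExperiment the per-sample genotype factor.
#' @param x a `JunctionArrayExperiment`.
#' @export
sampleGenotype <- function(x) {
  factor(SummarizedExperiment::colData(x)$genotype)
}

#' @describeIn JunctionArrayExperiment truth table of a simulated
#'   experiment (one row per event: `event_id`, `psi_control`,
#'   `psi_mutant`, `is_differential`), or NULL for real data.
#' @export
simTruth <- function(x) {
  S4Vectors::metadata(x)$truth
}

#' Accessors for summarized signals
#'
#' @param x a [SpliceSignals-class] object.
#' @return `probeSetSignal`/`geneSignal` return linear-scale signal
#'   matrices; `setAnnotation` the per-probe-set annotation data.frame.
#' @name SpliceSignals-accessors
NULL

#' @rdname SpliceSignals-accessors
#' @export
probeSetSignal <- function(x) x@probeSetSignal

#' @rdname SpliceSignals-accessors
#' @export
geneSignal <- function(x) x@geneSignal

#' @rdname SpliceSignals-accessors
#' @export
setAnnotation <- function(x) x@annotation

setMethod("show", "SpliceSignals", function(object) {
  cat("SpliceSignals:", nrow(object@probeSetSignal), "probe sets,",
      nrow(object@geneSignal), "genes,", ncol(object@probeSetSignal),
      "samples\n")
  cat("  genotypes:", paste(sprintf("%s (%d)", levels(object@genotype),
                                    table(object@genotype)), collapse = ", "), "\n")
})

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel: width", ncol(object@pfm), "consensus", object@consensus, "\n")
  cat("  gamma =", signif(object@gamma, 4),
      " logLik =", signif(object@logLik, 8),
      " (", length(object@logLikTrace), "EM iterations )\n")
})

#' @describeIn MotifModel consensus string of the fitted motif.
#' @param x a `MotifModel`.
#' @export
motifConsensus <- function(x) x@consensus

#' @describeIn MotifModel position-frequency matrix (rows A, C, G, U).
#' @export
motifPFM <- function(x) x@pfm

#' @describeIn MotifModel per-sequence most probable site starts (1-based).
#' @export
motifSiteStarts <- function(x) x@siteStart

setMethod("show", "DeletionCall", function(object) {
  cat("DeletionCall: [", object@start, ", ", object@end, ") on wild type, ",
      object@length, " bp deleted\n", sep = "")
  if (object@ambiguity > 1L)
    cat("  breakpoint can slide over", object@ambiguity,
        "equivalent placements (leftmost reported)\n")
})

#' @describeIn DeletionCall deletion length in bp.
#' @param x a `DeletionCall`.
#' @export
deletionLength <- function(x) x@length

#' @describeIn DeletionCall 0-based half-open deleted interval on the wild
#'   type, as `c(start, end)`.
#' @export
deletionInterval <- function(x) c(start = x@start, end = x@end)

#' @describeIn DeletionCall number of equivalent breakpoint placements.
#' @export
deletionAmbiguity <- function(x) x@ambiguity
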