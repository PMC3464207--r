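#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

PROBE_SET_ROLES <- c("cassette_exon", "upstream_junction", "downstream_junction",
                     "skipping_junction", "constitutive")
INCLUSION_ROLES <- c("cassette_exon", "upstream_junction", "downstream_junction")

ANNOTATION_COLS <- c("probe_set_id", "gene_id", "event_id", "role",
                     "flag_constitutive", "flag_multi_gene", "flag_alt_promoter",
                     "flag_conserved", "flag_neuron_specific")

#' Simulation configuration for a synthetic exon-junction array experiment
#'
#' Holds the study conditions under which a synthetic junction-array data set
#' is generated: how many genes and cassette-exon events, the per-genotype
#' exon inclusion rates (psi), the replicate count, and the noise model
#' parameters. Identical configurations (including the seed) produce
#' bit-identical simulated data.
#'
#' @slot nGenes number of expressed genes on the simulated array.
#' @slot nUnexpressedGenes number of additional genes whose probe sets
#'   measure only optical background (expression 0). Real junction arrays
#'   interrogate the whole transcriptome, so in any one tissue most probe
#'   sets sit at background level — the regime the RMA background
#'   estimator (mode/half-width heuristic) relies on.
#' @slot nCassetteEvents number of cassette-exon splicing events; each event
#'   lives in its own expressed gene, so this may not exceed `nGenes`.
#' @slot replicatesPerGenotype biological replicates per genotype (>= 2).
#' @slot psi numeric matrix with one row per event and columns
#'   `control`/`mutant`: the exon inclusion rate in each genotype, in \[0, 1\].
#' @slot noiseSdLog2 standard deviation of the multiplicative log-normal
#'   measurement noise, on the log2 scale.
#' @slot backgroundMean mean of the additive exponential optical background
#'   (linear intensity units); 0 disables background.
#' @slot affinitySdLog2 standard deviation (log2) of fixed per-probe
#'   affinities, removable by median polish.
#' @slot constitutiveSetsPerGene constitutive exon probe sets per gene.
#' @slot probesPerSet individual probes per probe set.
#' @slot exprMeanLog2,exprSdLog2 log2-normal distribution of per-gene
#'   expression levels.
#' @slot seed integer seed; the single source of randomness.
#' @export
setClass("SimConfig",
  representation(
    nGenes = "integer",
    nUnexpressedGenes = "integer",
    nCassetteEvents = "integer",
    replicatesPerGenotype = "integer",
    psi = "matrix",
    noiseSdLog2 = "numeric",
    backgroundMean = "numeric",
    affinitySdLog2 = "numeric",
    constitutiveSetsPerGene = "integer",
    probesPerSet = "integer",
    exprMeanLog2 = "numeric",
    exprSdLog2 = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nUnexpressedGenes < 0L) msg <- c(msg, "nUnexpressedGenes must be >= 0")
  if (object@nCassetteEvents < 0L) msg <- c(msg, "nCassetteEvents must be >= 0")
  if (object@nCassetteEvents > object@nGenes)
    msg <- c(msg, "nCassetteEvents must not exceed nGenes")
  if (object@replicatesPerGenotype < 2L)
    msg <- c(msg, "replicatesPerGenotype must be >= 2")
  if (nrow(object@psi) != object@nCassetteEvents)
    msg <- c(msg, "psi must have one row per cassette event")
  if (ncol(object@psi) != 2L || !identical(colnames(object@psi), c("control", "mutant")))
    msg <- c(msg, "psi must have columns 'control' and 'mutant'")
  if (any(object@psi < 0 | object@psi > 1))
    msg <- c(msg, "all inclusion rates (psi) must lie in [0, 1]")
  if (object@noiseSdLog2 < 0) msg <- c(msg, "noiseSdLog2 must be non-negative")
  if (object@backgroundMean < 0) msg <- c(msg, "backgroundMean must be non-negative")
  if (object@affinitySdLog2 < 0) msg <- c(msg, "affinitySdLog2 must be non-negative")
  if (object@constitutiveSetsPerGene < 1L)
    msg <- c(msg, "constitutiveSetsPerGene must be >= 1")
  if (object@probesPerSet < 1L) msg <- c(msg, "probesPerSet must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Probe-level exon-junction array experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the raw probe x
#' sample intensity matrix in assay `"intensity"`. `rowData` carries the
#' probe-set annotation (probe set, gene, splicing event, role, and the
#' filter flags); `colData` carries the per-sample `genotype`
#' (`"control"`/`"mutant"`). For simulated objects, the truth table and the
#' noise-free expected probe means are stored in `metadata`.
#'
#' @export
setClass("JunctionArrayExperiment", contains = "SummarizedExperiment")

setValidity("JunctionArrayExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    x <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(x)) msg <- c(msg, "intensities must not contain missing values")
    else if (any(x <= 0)) msg <- c(msg, "intensities must be strictly positive")
  }
  rd <- SummarizedExperiment::rowData(object)
  missing_cols <- setdiff(ANNOTATION_COLS[-1L], colnames(rd))
  if (length(missing_cols))
    msg <- c(msg, paste("rowData lacks columns:", paste(missing_cols, collapse = ", ")))
  else if (!all(rd$role %in% PROBE_SET_ROLES))
    msg <- c(msg, paste("unknown probe-set role(s):",
                        paste(unique(setdiff(rd$role, PROBE_SET_ROLES)), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!"genotype" %in% colnames(cd))
    msg <- c(msg, "colData lacks a 'genotype' column")
  else {
    tab <- table(cd$genotype)
    if (length(tab) < 2L || any(tab < 2L))
      msg <- c(msg, "need >= 2 samples in each of >= 2 genotypes")
  }
  if (length(msg)) msg else TRUE
})

#' Summarized probe-set and gene signals
#'
#' Result of [preprocessArray()]: background-corrected, quantile-normalized,
#' median-polish-summarized probe-set signals (linear scale) together with
#' the per-gene expression signal (the median over exon-type probe sets),
#' the per-probe-set annotation and the sample genotypes.
#'
#' @slot probeSetSignal probe set x sample matrix, linear scale, positive.
#' @slot geneSignal gene x sample matrix, linear scale, positive.
#' @slot annotation data.frame with one row per probe set (annotation columns
#'   as in [JunctionArrayExperiment()] rowData).
#' @slot genotype factor of per-sample genotypes.
#' @export
setClass("SpliceSignals",
  representation(
    probeSetSignal = "matrix",
    geneSignal = "matrix",
    annotation = "data.frame",
    genotype = "factor"
  )
)

setValidity("SpliceSignals", function(object) {
  msg <- character()
  if (any(object@probeSetSignal <= 0)) msg <- c(msg, "probe-set signals must be positive")
  if (any(object@geneSignal <= 0)) msg <- c(msg, "gene signals must be positive")
  if (nrow(object@annotation) != nrow(object@probeSetSignal))
    msg <- c(msg, "annotation must have one row per probe set")
  if (length(object@genotype) != ncol(object@probeSetSignal))
    msg <- c(msg, "genotype must have one entry per sample")
  if (ncol(object@geneSignal) != ncol(object@probeSetSignal))
    msg <- c(msg, "gene and probe-set matrices must share samples")
  if (length(msg)) msg else TRUE
})

#' Discovered sequence motif (ZOOPS model)
#'
#' Position-frequency matrix over the RNA alphabet fitted by expectation-
#' maximization under the zero-or-one-occurrence-per-sequence (ZOOPS) model,
#' with the best site per sequence and the log-likelihood trace.
#'
#' @slot pfm 4 x w position-frequency matrix (rows A, C, G, U; columns sum
#'   to 1).
#' @slot consensus consensus string (RNA alphabet).
#' @slot sitePosterior per-sequence posterior probability that the sequence
#'   contains a motif occurrence.
#' @slot siteStart per-sequence most probable site start (1-based; NA when
#'   the no-site model dominates).
#' @slot gamma fitted prior probability that a sequence contains a site.
#' @slot logLik final ZOOPS log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood of the best restart
#'   (non-decreasing).
#' @export
setClass("MotifModel",
  representation(
    pfm = "matrix",
    consensus = "character",
    sitePosterior = "numeric",
    siteStart = "integer",
    gamma = "numeric",
    logLik = "numeric",
    logLikTrace = "numeric"
  )
)

setValidity("MotifModel", function(object) {
  msg <- character()
  if (nrow(object@pfm) != 4L) msg <- c(msg, "pfm must have 4 rows (A, C, G, U)")
  if (any(abs(colSums(object@pfm) - 1) > 1e-8))
    msg <- c(msg, "pfm columns must each sum to 1")
  if (nchar(object@consensus) != ncol(object@pfm))
    msg <- c(msg, "consensus length must equal motif width")
  if (length(msg)) msg else TRUE
})

#' Single-deletion call between a wild-type and a mutant sequence
#'
#' Breakpoints of the unique (left-aligned) deletion that turns the
#' wild-type sequence into the mutant sequence. Coordinates are 0-based,
#' half-open on the wild-type sequence, mirroring BED/VCF left-alignment
#' conventions.
#'
#' @slot start,end deleted interval \[start, end) on the wild-type sequence.
#' @slot length deletion length in bp (`end - start`).
#' @slot ambiguity number of equivalent breakpoint placements (>= 1); values
#'   above 1 arise from repeated bases flanking the deletion.
#' @export
setClass("DeletionCall",
  representation(
    start = "integer",
    end = "integer",
    length = "integer",
    ambiguity = "integer"
  )
)

setValidity("DeletionCall", function(object) {
  msg <- character()
  if (object@length != object@end - object@start)
    msg <- c(msg, "length must equal end - start")
  if (object@length < 0L) msg <- c(msg, "length must be >= 0")
  if (object@ambiguity < 1L) msg <- c(msg, "ambiguity span must be >= 1")
  if (length(msg)) msg else TRUE
})
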