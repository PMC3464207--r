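#' Simulate a probe-level exon-junction array experiment with known truth
#'
#' Generates a synthetic junction-array data set that mirrors the cassette
#' exon probe-set design of exon-junction microarrays: each cassette event
#' carries exactly 4 probe sets (the cassette exon itself, the upstream and
#' downstream inclusion junctions, and the skipping junction), and every
#' gene additionally carries constitutive exon probe sets that anchor the
#' gene-level expression signal.
#'
#' The generative model per probe is
#' `mean = affinity * expression * f(psi)`, where `f` is `psi` for
#' inclusion-reporting probe sets, `1 - psi` for the skipping junction and
#' `1` for constitutive sets, and the observation is
#' `mean * 2^Normal(0, noiseSdLog2) + Exponential(backgroundMean)` — the
#' multiplicative/additive convolution that RMA-style background correction
#' inverts. Probe affinities are log-normal and fixed across samples, so
#' median polish can remove them.
#'
#' @param config a [SimConfig-class] object.
#' @return A [JunctionArrayExperiment-class]; `simTruth()` returns its truth
#'   table and `metadata(.)$probeMeans` the noise-free expected probe means
#'   per genotype.
#' @examples
#' se <- simulateArray(SimConfig(nGenes = 10, nCassetteEvents = 2, seed = 1))
#' table(SummarizedExperiment::rowData(se)$role)
#' @export
simulateArray <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(config@seed, simulate_array_impl(config))
}

simulate_array_impl <- function(config) {
  nG <- config@nGenes
  nE <- config@nCassetteEvents
  nrep <- config@replicatesPerGenotype
  nset_const <- config@constitutiveSetsPerGene
  npp <- config@probesPerSet

  nU <- config@nUnexpressedGenes
  gene_ids <- sprintf("gene%03d", seq_len(nG))
  silent_ids <- if (nU > 0) sprintf("geneU%03d", seq_len(nU)) else character()
  all_gene_ids <- c(gene_ids, silent_ids)
  event_ids <- if (nE > 0) sprintf("event%03d", seq_len(nE)) else character()
  event_gene <- gene_ids[seq_len(nE)]          # one event per gene, genes 1..nE

  # probe-set annotation: constitutive sets for every gene (expressed and
  # silent), then 4 sets per cassette event
  n_all <- length(all_gene_ids)
  const_ann <- data.frame(
    probe_set_id = sprintf("%s_const%d", rep(all_gene_ids, each = nset_const),
                           rep(seq_len(nset_const), times = n_all)),
    gene_id = rep(all_gene_ids, each = nset_const),
    event_id = NA_character_,
    role = "constitutive",
    flag_constitutive = TRUE, flag_multi_gene = FALSE, flag_alt_promoter = FALSE,
    flag_conserved = FALSE, flag_neuron_specific = FALSE,
    stringsAsFactors = FALSE)
  event_roles <- c("cassette_exon", "upstream_junction",
                   "downstream_junction", "skipping_junction")
  if (nE > 0) {
    event_ann <- data.frame(
      probe_set_id = sprintf("%s_%s", rep(event_ids, each = 4L),
                             rep(c("exon", "ju", "jd", "js"), times = nE)),
      gene_id = rep(event_gene, each = 4L),
      event_id = rep(event_ids, each = 4L),
      role = rep(event_roles, times = nE),
      flag_constitutive = FALSE, flag_multi_gene = FALSE, flag_alt_promoter = FALSE,
      flag_conserved = TRUE, flag_neuron_specific = TRUE,
      stringsAsFactors = FALSE)
    set_ann <- rbind(const_ann, event_ann)
  } else set_ann <- const_ann

  # expand probe sets into probes
  probe_ann <- set_ann[rep(seq_len(nrow(set_ann)), each = npp), , drop = FALSE]
  probe_ann$probe_id <- sprintf("%s_p%d", probe_ann$probe_set_id,
                                rep(seq_len(npp), times = nrow(set_ann)))
  rownames(probe_ann) <- probe_ann$probe_id

  genotype <- rep(c("control", "mutant"), each = nrep)
  sample_ids <- c(sprintf("ctrl_%d", seq_len(nrep)), sprintf("mut_%d", seq_len(nrep)))

  expression <- stats::setNames(
    c(2^stats::rnorm(nG, config@exprMeanLog2, config@exprSdLog2), rep(0, nU)),
    all_gene_ids)
  affinity <- 2^stats::rnorm(nrow(probe_ann), 0, config@affinitySdLog2)

  # per-probe psi factor by genotype
  psi_factor <- function(geno) {
    f <- rep(1, nrow(probe_ann))
    if (nE > 0) {
      idx <- match(probe_ann$event_id, event_ids)
      psi <- config@psi[, geno][idx]
      incl <- probe_ann$role %in% INCLUSION_ROLES
      skip <- probe_ann$role == "skipping_junction"
      f[incl] <- psi[incl]
      f[skip] <- 1 - psi[skip]
    }
    f
  }
  base_mean <- affinity * expression[probe_ann$gene_id]
  mean_by_geno <- cbind(control = base_mean * psi_factor("control"),
                        mutant = base_mean * psi_factor("mutant"))
  rownames(mean_by_geno) <- probe_ann$probe_id

  nprobe <- nrow(probe_ann)
  intensity <- matrix(NA_real_, nprobe, length(sample_ids),
                      dimnames = list(probe_ann$probe_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- mean_by_geno[, genotype[j]]
    noise <- 2^stats::rnorm(nprobe, 0, config@noiseSdLog2)
    bg <- if (config@backgroundMean > 0)
      stats::rexp(nprobe, rate = 1 / config@backgroundMean) else 0
    intensity[, j] <- mu * noise + bg
  }
  # the convolution keeps everything positive, but guard exact zeros
  intensity[intensity <= 0] <- .Machine$double.eps

  truth <- data.frame(
    event_id = event_ids,
    psi_control = config@psi[, "control"],
    psi_mutant = config@psi[, "mutant"],
    is_differential = abs(config@psi[, "control"] - config@psi[, "mutant"]) > 0,
    stringsAsFactors = FALSE)

  JunctionArrayExperiment(
    intensity = intensity,
    probeAnnotation = probe_ann[, c("probe_id", ANNOTATION_COLS)],
    genotype = genotype,
    metadata = list(truth = truth, probeMeans = mean_by_geno,
                    expression = expression, config = config))
}

#' Simulate 3'-splice-site-proximal intron windows with a planted motif
#'
#' Emulates the last `windowLen` nucleotides of introns upstream of cassette
#' exons: a 5' purine filler, a polypyrimidine tract, and the splice
#' acceptor "AG" at the 3' end. Foreground windows carry the motif planted
#' at a fixed offset from the 3' end of the tract (negative offsets place it
#' inside the tract, as observed for the GC motif near the tract end);
#' background windows carry a tract but no planted motif. Sequences are
#' written in the DNA alphabet (T, not U).
#'
#' @param nFg,nBg number of foreground/background windows.
#' @param windowLen window length in nt (default 50, the intronic stretch
#'   directly adjacent to the exon).
#' @param motif motif to plant, RNA or DNA alphabet (default "TGC").
#' @param offsetFromPptEnd signed offset of the motif start from the tract
#'   3' end (0 = motif begins immediately after the tract). The default -4
#'   places a 3-nt motif wholly inside the tract with one pyrimidine
#'   trailing it, so the +1/-1.5 tract-scoring rule of
#'   [findPolypyrimidineTract()] retains the motif's purine and recovers
#'   the planted tract end exactly in noise-free data; at -3 the scanner
#'   would truncate the tract just before the motif.
#' @param tractLen polypyrimidine tract length.
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and `truth`
#'   (data.frame: `name`, `is_foreground`, `tract_start`, `tract_end`,
#'   `motif_start`; 0-based half-open coordinates, `motif_start` NA for
#'   background).
#' @examples
#' sim <- simulateSpliceSiteWindows(nFg = 5, nBg = 5, seed = 1)
#' sim$truth
#' @export
simulateSpliceSiteWindows <- function(nFg, nBg, windowLen = 50L, motif = "TGC",
                                      offsetFromPptEnd = -4L, tractLen = 15L,
                                      seed = 1L) {
  motif <- toupper(gsub("U", "T", motif))
  if (nchar(motif) < 1L) stop("motif must be non-empty")
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over the ACGU/ACGT alphabet")
  windowLen <- as.integer(windowLen)
  tractLen <- as.integer(tractLen)
  offsetFromPptEnd <- as.integer(offsetFromPptEnd)
  if (windowLen < nchar(motif) + tractLen)
    stop("windowLen must be at least motif length + tract length")
  # window layout (0-based): [filler][tract)[AG]; tract ends 2 nt before end
  tract_end <- windowLen - 2L
  tract_start <- tract_end - tractLen
  if (tract_start < 0L) stop("tract does not fit in the window")
  motif_start <- tract_end + offsetFromPptEnd
  if (motif_start < tract_start || motif_start + nchar(motif) > windowLen)
    stop("offsetFromPptEnd places the motif outside the window/tract region")

  withr::with_seed(seed, {
    make_window <- function(plant) {
      filler <- sample(c("A", "G"), tract_start, replace = TRUE)
      tract <- sample(c("C", "T"), tractLen, replace = TRUE, prob = c(0.5, 0.5))
      win <- c(filler, tract, "A", "G")
      if (plant)
        win[(motif_start + 1L):(motif_start + nchar(motif))] <-
          strsplit(motif, "")[[1]]
      paste(win, collapse = "")
    }
    fg <- vapply(seq_len(nFg), function(i) make_window(TRUE), character(1))
    bg <- vapply(seq_len(nBg), function(i) make_window(FALSE), character(1))
  })
  names_fg <- if (nFg > 0) sprintf("fg_%03d", seq_len(nFg)) else character()
  names_bg <- if (nBg > 0) sprintf("bg_%03d", seq_len(nBg)) else character()
  seqs <- Biostrings::DNAStringSet(stats::setNames(c(fg, bg), c(names_fg, names_bg)))
  truth <- data.frame(
    name = c(names_fg, names_bg),
    is_foreground = rep(c(TRUE, FALSE), c(nFg, nBg)),
    tract_start = tract_start, tract_end = tract_end,
    motif_start = ifelse(rep(c(TRUE, FALSE), c(nFg, nBg)), motif_start, NA_integer_),
    stringsAsFactors = FALSE)
  list(sequences = seqs, truth = truth)
}

#' Simulate an RT-PCR band-intensity table from a truth table
#'
#' Emulates gel densitometry of a two-band RT-PCR assay across replicate
#' lanes: the inclusion band is proportional to the exon inclusion rate psi
#' and the skipping band to 1 - psi, with multiplicative noise of a given
#' coefficient of variation.
#'
#' @param truth truth table as returned by [simTruth()] (columns `event_id`,
#'   `psi_control`, `psi_mutant`).
#' @param bandNoiseCv coefficient of variation of the multiplicative band
#'   noise (0 = noise free).
#' @param lanesPerGenotype replicate lanes per genotype.
#' @param scale expected total band intensity per lane.
#' @param seed integer seed.
#' @return data.frame with columns `event_id`, `sample`, `genotype`,
#'   `inclusion_band`, `skipping_band`.
#' @export
simulateRtPcr <- function(truth, bandNoiseCv = 0.1, lanesPerGenotype = 3L,
                          scale = 100, seed = 1L) {
  if (!NROW(truth)) stop("truth table must be non-empty")
  if (bandNoiseCv < 0) stop("bandNoiseCv must be non-negative")
  lanes <- as.integer(lanesPerGenotype)
  grid <- expand.grid(lane = seq_len(lanes),
                      genotype = c("control", "mutant"),
                      event_id = truth$event_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  psi <- ifelse(grid$genotype == "control",
                truth$psi_control[match(grid$event_id, truth$event_id)],
                truth$psi_mutant[match(grid$event_id, truth$event_id)])
  withr::with_seed(seed, {
    n <- nrow(grid)
    noise_inc <- 1 + stats::rnorm(n, 0, bandNoiseCv)
    noise_skip <- 1 + stats::rnorm(n, 0, bandNoiseCv)
  })
  data.frame(
    event_id = grid$event_id,
    sample = sprintf("%s_lane%d", ifelse(grid$genotype == "control", "ctrl", "mut"),
                     grid$lane),
    genotype = grid$genotype,
    inclusion_band = pmax(0, scale * psi * noise_inc),
    skipping_band = pmax(0, scale * (1 - psi) * noise_skip),
    stringsAsFactors = FALSE)
}

#' Apply a single deletion to a sequence
#'
#' Returns the wild-type sequence together with a mutant carrying the
#' deletion `[delStart, delStart + delLen)` (0-based, half-open).
#'
#' @param seq character scalar sequence (A/C/G/T/N).
#' @param delStart 0-based deletion start.
#' @param delLen deletion length in bp.
#' @return list with elements `wt` and `mutant` (character scalars).
#' @examples
#' simulateDeletion("ACGTACGT", delStart = 2, delLen = 3)$mutant  # "ACCGT"
#' @export
simulateDeletion <- function(seq, delStart, delLen) {
  seq <- toupper(as.character(seq))
  delStart <- as.integer(delStart)
  delLen <- as.integer(delLen)
  n <- nchar(seq)
  if (delStart < 0L || delLen < 0L || delStart + delLen > n)
    stop("deletion coordinates out of range")
  mutant <- paste0(substr(seq, 1L, delStart), substr(seq, delStart + delLen + 1L, n))
  list(wt = seq, mutant = mutant)
}

#' Random DNA sequence
#'
#' Uniform i.i.d. sequence over A/C/G/T; convenience generator for deletion
#' round-trip benchmarks.
#'
#' @param n sequence length.
#' @param seed integer seed.
#' @return character scalar of length-`n` DNA.
#' @export
randomDna <- function(n, seed = 1L) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
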