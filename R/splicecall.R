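#' Normalized splicing index (I_norm)
#'
#' Divides each probe set's background-corrected linear signal by the
#' expression signal of its gene, per sample. The resulting index isolates
#' splicing change from expression change: a constitutive probe set keeps a
#' genotype ratio of 1, inclusion-reporting probe sets track the exon
#' inclusion rate and the skipping junction tracks its complement.
#'
#' @param signals a [SpliceSignals-class].
#' @return probe set x sample matrix of I_norm values (probe sets whose
#'   gene has no expression estimate are dropped with a warning).
#' @export
splicingIndex <- function(signals) {
  stopifnot(is(signals, "SpliceSignals"))
  sig <- probeSetSignal(signals)
  gene <- geneSignal(signals)
  ann <- setAnnotation(signals)
  keep <- ann$gene_id %in% rownames(gene)
  if (!all(keep))
    warning(sum(!keep), " probe set(s) without a gene expression signal dropped")
  sig <- sig[keep, , drop = FALSE]
  g <- gene[ann$gene_id[keep], , drop = FALSE]
  bad <- rowSums(g <= 0) > 0
  if (any(bad)) {
    warning(sum(bad), " probe set(s) with non-positive gene signal excluded")
    sig <- sig[!bad, , drop = FALSE]
    g <- g[!bad, , drop = FALSE]
  }
  sig / g
}

#' Pooled-variance two-sample t test
#'
#' Two-tailed Student t test with pooled variance and
#' `df = n_a + n_b - 2` (via [stats::t.test] with `var.equal = TRUE`).
#' Degenerate zero-variance groups are handled explicitly: equal means give
#' `t = 0, P = 1`; unequal means with zero pooled variance give an
#' essentially-zero P reported at the double minimum.
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @return named numeric `c(t = ..., p = ...)`, with `t` oriented as
#'   `mean(groupA) - mean(groupB)`.
#' @examples
#' pooledTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
pooledTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(groupA) - mean(groupB)) * Inf, p = .Machine$double.xmin))
  }
  fit <- stats::t.test(groupA, groupB, var.equal = TRUE)
  c(t = unname(fit$statistic), p = fit$p.value)
}

#' Per-probe-set genotype tests on the splicing index
#'
#' Computes I_norm for every probe set and tests the genotype difference
#' per probe set with a pooled two-tailed t test.
#'
#' @param signals a [SpliceSignals-class].
#' @return data.frame with one row per probe set: annotation columns,
#'   `mean_control`, `mean_mutant` (mean I_norm per genotype), `t` and `p`.
#' @export
probeSetTests <- function(signals) {
  inorm <- splicingIndex(signals)
  ann <- setAnnotation(signals)
  ann <- ann[rownames(inorm), , drop = FALSE]
  geno <- signals@genotype
  ctrl <- geno == "control"
  mut <- geno == "mutant"
  res <- t(apply(inorm, 1, function(v) {
    tt <- pooledTTest(v[mut], v[ctrl])   # oriented mutant - control
    c(mean_control = mean(v[ctrl]), mean_mutant = mean(v[mut]),
      t = tt[["t"]], p = tt[["p"]])
  }))
  cbind(ann, as.data.frame(res))
}

#' Filter probe sets from candidate consideration
#'
#' Removes probe sets flagged as constitutive, as cross-hybridizing with
#' more than one gene, or as measuring alternative promoter activity.
#' Constitutive sets remain available upstream for the gene-expression
#' estimate; this filter only governs which probe sets may vote for a
#' splicing event.
#'
#' @param records data.frame of probe-set records carrying the flag columns.
#' @return the retained rows of `records`.
#' @export
applyProbeSetFilters <- function(records) {
  if (!all(records$role %in% PROBE_SET_ROLES))
    stop("unknown probe-set role(s): ",
         paste(unique(setdiff(records$role, PROBE_SET_ROLES)), collapse = ", "))
  keep <- !(records$flag_constitutive | records$flag_multi_gene |
              records$flag_alt_promoter)
  records[keep, , drop = FALSE]
}

#' Tiered splicing-event calls by probe-set voting
#'
#' A probe set votes for its event when its genotype P value falls below
#' `alpha`. Each vote carries an implied direction of inclusion change:
#' for inclusion-reporting probe sets (cassette exon, upstream/downstream
#' junction) the sign of the mutant-minus-control mean I_norm; for the
#' skipping junction, the opposite sign — probe sets targeting competing
#' isoforms must show opposite I_norm trends to agree. An event is tier 1
#' when at least two votes agree on the inclusion direction; votes implying
#' opposite directions cancel the event (direction "ambiguous"); exactly
#' one vote promotes the event to tier-2 candidate only when the event is
#' flagged both conserved and neuron-specific.
#'
#' @param records filtered probe-set records (output of [probeSetTests()]
#'   after [applyProbeSetFilters()]).
#' @param alpha per-probe-set significance threshold (screening threshold,
#'   default 0.05; no multiplicity correction at this stage).
#' @return data.frame with one row per event: `event_id`, `tier`
#'   (`"tier1"`, `"tier2_candidate"`, `"none"`), `direction`
#'   (`"inclusion_down"`, `"inclusion_up"`, `"ambiguous"`, `"none"`),
#'   `n_significant_probe_sets`, `voting_probe_sets` (comma-separated).
#' @export
callSplicingEvents <- function(records, alpha = 0.05) {
  records <- records[!is.na(records$event_id), , drop = FALSE]
  events <- unique(records$event_id)
  calls <- lapply(events, function(ev) {
    rec <- records[records$event_id == ev, , drop = FALSE]
    votes <- rec[rec$p < alpha, , drop = FALSE]
    n <- nrow(votes)
    if (n == 0L)
      return(data.frame(event_id = ev, tier = "none", direction = "none",
                        n_significant_probe_sets = 0L, voting_probe_sets = "",
                        stringsAsFactors = FALSE))
    delta <- votes$mean_mutant - votes$mean_control
    incl_dir <- ifelse(votes$role == "skipping_junction", -sign(delta), sign(delta))
    voting <- paste(votes$probe_set_id, collapse = ",")
    if (n >= 2L && length(unique(incl_dir)) > 1L)
      return(data.frame(event_id = ev, tier = "none", direction = "ambiguous",
                        n_significant_probe_sets = n, voting_probe_sets = voting,
                        stringsAsFactors = FALSE))
    dir <- if (incl_dir[1] < 0) "inclusion_down" else "inclusion_up"
    if (n >= 2L)
      tier <- "tier1"
    else if (all(rec$flag_conserved) && all(rec$flag_neuron_specific))
      tier <- "tier2_candidate"
    else {
      tier <- "none"
      dir <- "none"
    }
    data.frame(event_id = ev, tier = tier, direction = dir,
               n_significant_probe_sets = n, voting_probe_sets = voting,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Screen a junction-array experiment for differential splicing events
#'
#' Convenience wrapper running the full probe-set pipeline: preprocessing,
#' splicing index, per-probe-set t tests, candidate filters, and tiered
#' event calling.
#'
#' @param x a [JunctionArrayExperiment-class].
#' @param alpha per-probe-set significance threshold.
#' @return list with `signals` ([SpliceSignals-class]), `tests` (probe-set
#'   records) and `calls` (event-level calls).
#' @export
screenSplicingEvents <- function(x, alpha = 0.05) {
  signals <- preprocessArray(x)
  tests <- probeSetTests(signals)
  candidates <- applyProbeSetFilters(tests)
  calls <- callSplicingEvents(candidates, alpha = alpha)
  list(signals = signals, tests = tests, calls = calls)
}

#' Cross-tissue concordance of splicing-index ratios
#'
#' Pearson correlation (with the t-approximation P value of
#' [stats::cor.test]) between per-probe-set genotype I_norm ratios measured
#' in two tissues; used to ask whether the splicing changes seen in one
#' tissue reproduce in another.
#'
#' @param ratiosA,ratiosB paired numeric vectors (same probe sets, two
#'   tissues), length >= 3.
#' @return named numeric `c(r = ..., p = ...)`.
#' @export
crossTissueConcordance <- function(ratiosA, ratiosB) {
  if (length(ratiosA) != length(ratiosB) || length(ratiosA) < 3L)
    stop("need >= 3 paired values")
  if (stats::sd(ratiosA) == 0 || stats::sd(ratiosB) == 0)
    stop("correlation undefined: zero variance in one tissue")
  fit <- stats::cor.test(ratiosA, ratiosB)
  c(r = unname(fit$estimate), p = fit$p.value)
}
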