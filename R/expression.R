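#' Benjamini-Hochberg step-up q values
#'
#' `q_(i) = min_{j >= i} (p_(j) * n / j)`, capped at 1 and returned in the
#' input order (delegates to [stats::p.adjust]).
#'
#' @param pvalues numeric vector of P values in \[0, 1\].
#' @return numeric vector of q values.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bhFdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("P values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-level differential expression between genotypes
#'
#' Pooled two-tailed t test per gene on the log2 gene expression signals,
#' with the linear fold change (mutant over control, ratio of per-genotype
#' geometric means) and Benjamini-Hochberg q values.
#'
#' @param signals a [SpliceSignals-class] (uses its gene signal matrix), or
#'   a gene x sample linear signal matrix with `genotype` supplied.
#' @param genotype factor of per-sample genotypes (ignored when `signals`
#'   is a [SpliceSignals-class]).
#' @return data.frame with one row per gene: `gene_id`, `mean_control`,
#'   `mean_mutant` (linear geometric means), `fold_change`, `t`, `p`, `q`.
#' @export
differentialExpression <- function(signals, genotype = NULL) {
  if (is(signals, "SpliceSignals")) {
    mat <- geneSignal(signals)
    genotype <- signals@genotype
  } else {
    mat <- as.matrix(signals)
    if (is.null(genotype)) stop("genotype is required for a plain matrix")
    genotype <- factor(genotype)
  }
  if (any(mat <= 0)) stop("gene signals must be positive")
  logmat <- log2(mat)
  ctrl <- genotype == "control"
  mut <- genotype == "mutant"
  res <- t(apply(logmat, 1, function(v) {
    tt <- pooledTTest(v[mut], v[ctrl])
    c(mc = mean(v[ctrl]), mm = mean(v[mut]), t = tt[["t"]], p = tt[["p"]])
  }))
  out <- data.frame(gene_id = rownames(mat),
                    mean_control = 2^res[, "mc"],
                    mean_mutant = 2^res[, "mm"],
                    fold_change = 2^(res[, "mm"] - res[, "mc"]),
                    t = res[, "t"], p = res[, "p"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- bhFdr(out$p)
  out
}

#' Select differentially expressed genes by fold and FDR cutoffs
#'
#' Genes changed at least `minFold`-fold in either direction (boundary
#' inclusive) at a q value of at most `maxFdr`, split into up- and
#' down-regulated lists. Optionally also returns the `topN` genes ranked by
#' the strongest reduction.
#'
#' @param results data.frame from [differentialExpression()].
#' @param minFold minimal linear fold change (default 1.5).
#' @param maxFdr maximal BH q value (default 0.15).
#' @param topN optional count of most-reduced genes to report regardless of
#'   cutoff.
#' @return list with `up`, `down` (character vectors of gene ids) and,
#'   when `topN` is given, `most_reduced`.
#' @export
selectChangedGenes <- function(results, minFold = 1.5, maxFdr = 0.15,
                               topN = NULL) {
  stopifnot(minFold > 0, maxFdr > 0)
  pass <- results$q <= maxFdr &
    (results$fold_change >= minFold | results$fold_change <= 1 / minFold)
  up <- results$gene_id[pass & results$fold_change >= minFold]
  down <- results$gene_id[pass & results$fold_change <= 1 / minFold]
  out <- list(up = up, down = down)
  if (!is.null(topN)) {
    ord <- order(results$fold_change)
    out$most_reduced <- results$gene_id[ord][seq_len(min(topN, nrow(results)))]
  }
  out
}

#' Chi-squared overrepresentation test of a gene set in a selection
#'
#' Pearson chi-squared test (df = 1, no continuity correction) on the 2x2
#' membership table of a selected gene list against a reference gene set
#' within a common universe. When any expected cell count falls below 1,
#' a warning is issued and the Fisher exact P value is reported alongside.
#'
#' @param selected,referenceSet,universe character vectors of gene ids;
#'   `selected` and `referenceSet` must be subsets of `universe`.
#' @return list with `chisq`, `p`, `table` (the 2x2 table) and, when
#'   expected counts are small, `fisher_p`.
#' @export
geneSetChi2 <- function(selected, referenceSet, universe) {
  selected <- unique(selected); referenceSet <- unique(referenceSet)
  universe <- unique(universe)
  if (!all(selected %in% universe) || !all(referenceSet %in% universe))
    stop("selected and referenceSet must be subsets of universe")
  in_sel <- universe %in% selected
  in_ref <- universe %in% referenceSet
  tab <- table(selected = factor(in_sel, c(TRUE, FALSE)),
               reference = factor(in_ref, c(TRUE, FALSE)))
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(chisq = unname(fit$statistic), p = fit$p.value, table = tab)
  if (any(fit$expected < 1)) {
    warning("expected cell count below 1; reporting Fisher exact P as well")
    out$fisher_p <- stats::fisher.test(tab)$p.value
  }
  out
}
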