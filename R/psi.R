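#' Exon inclusion rate (psi) from two RT-PCR band intensities
#'
#' `psi = inclusion / (inclusion + skipping)`, the fraction of transcripts
#' including the cassette exon. Undefined (NA, with a warning) when both
#' bands are zero.
#'
#' @param inclusionBand,skippingBand non-negative band intensities
#'   (vectorized).
#' @return numeric psi in \[0, 1\] (NA where both bands are 0).
#' @examples
#' inclusionRate(3, 1)  # 0.75
#' @export
inclusionRate <- function(inclusionBand, skippingBand) {
  if (any(inclusionBand < 0, na.rm = TRUE) || any(skippingBand < 0, na.rm = TRUE))
    stop("band intensities must be non-negative")
  total <- inclusionBand + skippingBand
  out <- ifelse(total > 0, inclusionBand / total, NA_real_)
  if (anyNA(out)) warning("psi undefined where both bands are zero")
  out
}

#' Fold-change criterion for differential exon inclusion
#'
#' TRUE when the two inclusion rates differ by at least `fold` as a ratio
#' (`max/min >= fold`, boundary inclusive); a completely skipped exon in
#' one condition (`min = 0 < max`) always qualifies. Symmetric in its
#' arguments.
#'
#' @param psiA,psiB inclusion rates in \[0, 1\] (vectorized).
#' @param fold minimal fold difference (default 1.5).
#' @return logical (NA where both rates are 0 or either is NA).
#' @examples
#' differentialPsi(0.6, 0.4)  # TRUE: ratio exactly 1.5
#' differentialPsi(0, 0.3)    # TRUE: complete skipping
#' @export
differentialPsi <- function(psiA, psiB, fold = 1.5) {
  stopifnot(fold > 0)
  hi <- pmax(psiA, psiB)
  lo <- pmin(psiA, psiB)
  # relative tolerance keeps the inclusive boundary inclusive in floating
  # point (0.6/0.4 must count as 1.5-fold)
  ifelse(is.na(hi) | (hi == 0 & lo == 0), NA,
         ifelse(lo == 0, TRUE, hi / lo >= fold * (1 - 1e-9)))
}

#' Per-event inclusion rates and fold-change calls from a band table
#'
#' Computes per-lane psi from an RT-PCR band-intensity table, aggregates
#' replicate lanes by the mean psi per genotype, and applies the fold
#' criterion per event.
#'
#' @param bands data.frame as returned by [simulateRtPcr()]: columns
#'   `event_id`, `genotype`, `inclusion_band`, `skipping_band`.
#' @param fold minimal fold difference (default 1.5).
#' @return data.frame with one row per event: `event_id`, `psi_control`,
#'   `psi_mutant`, `is_differential`.
#' @export
psiFromBands <- function(bands, fold = 1.5) {
  stopifnot(all(c("event_id", "genotype", "inclusion_band", "skipping_band")
                %in% colnames(bands)))
  psi <- inclusionRate(bands$inclusion_band, bands$skipping_band)
  agg <- stats::aggregate(psi ~ event_id + genotype,
                          data = cbind(bands, psi = psi), FUN = mean)
  wide <- stats::reshape(agg, idvar = "event_id", timevar = "genotype",
                         direction = "wide")
  out <- data.frame(event_id = wide$event_id,
                    psi_control = wide$psi.control,
                    psi_mutant = wide$psi.mutant,
                    stringsAsFactors = FALSE)
  out$is_differential <- differentialPsi(out$psi_control, out$psi_mutant, fold)
  out[order(out$event_id), , drop = FALSE]
}
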