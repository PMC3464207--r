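#' Map a single deletion between a wild-type and a mutant sequence
#'
#' Locates the unique deletion turning the wild-type sequence into the
#' mutant by longest common prefix/suffix matching: with prefix length p
#' and suffix length s (capped so that p + s does not exceed the mutant
#' length), every breakpoint start between `len(mutant) - s` and `p` yields
#' an exact reconstruction; the leftmost placement is reported (mirroring
#' VCF-style left alignment) together with the ambiguity span — the number
#' of equivalent placements the breakpoint can slide across, which exceeds
#' 1 when the deletion flanks repeat. The reconstruction is verified
#' exactly before returning. `N` matches nothing (conservative for
#' breakpoint placement), so sequences disagreeing at an `N` are rejected.
#'
#' @param wt,mutant character scalars over A/C/G/T/N with
#'   `nchar(mutant) <= nchar(wt)`.
#' @return A [DeletionCall-class] (length 0 when the sequences are equal).
#' @examples
#' call <- mapSingleDeletion("ACTTTG", "ACG")
#' deletionInterval(call)  # start 2, end 5: "TTT" deleted
#' @export
mapSingleDeletion <- function(wt, mutant) {
  wt <- toupper(as.character(wt)); mutant <- toupper(as.character(mutant))
  if (!grepl("^[ACGTN]*$", wt) || !grepl("^[ACGTN]*$", mutant))
    stop("sequences must be over the A/C/G/T/N alphabet")
  nw <- nchar(wt); nm <- nchar(mutant)
  if (nm > nw) stop("mutant must not be longer than wild type")
  d <- nw - nm
  a <- strsplit(wt, "")[[1]]
  b <- if (nm > 0) strsplit(mutant, "")[[1]] else character()
  eq <- function(x, y) x == y & x != "N" & y != "N"

  if (nm == 0L) {
    p <- 0L; s <- 0L
  } else {
    pref_match <- eq(a[seq_len(nm)], b)
    p <- if (all(pref_match)) nm else which.min(pref_match) - 1L
    suff_match <- eq(rev(a)[seq_len(nm)], rev(b))
    s <- if (all(suff_match)) nm else which.min(suff_match) - 1L
  }
  if (nm - s > p)
    stop("mutant is not a single deletion of wild type; first mismatch at ",
         "position ", p, " (0-based) suggests additional variants")
  start <- max(0L, nm - s)              # leftmost valid placement
  end <- start + d
  ambiguity <- p - start + 1L
  reconstructed <- paste0(substr(wt, 1L, start), substr(wt, end + 1L, nw))
  if (!identical(reconstructed, mutant))
    stop("internal error: reconstruction failed")   # nocov
  new("DeletionCall", start = as.integer(start), end = as.integer(end),
      length = as.integer(d), ambiguity = as.integer(ambiguity))
}
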