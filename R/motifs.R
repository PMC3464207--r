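#' Find the polypyrimidine tract in a 3'-splice-site-proximal window
#'
#' Scores every position +1 for a pyrimidine (C/U/T) and -1.5 for a purine,
#' and returns the maximal-scoring contiguous segment of length at least
#' `minLen` — a linear-time prefix-sum scan (Kadane-style with a minimum
#' length constraint). Ties are broken leftmost first, then longest. The
#' purine penalty lets a single interrupting purine extend a tract while
#' purine-rich stretches terminate it; both weights are exposed.
#'
#' @param window character scalar over A/C/G/T/U (typically the last 50 nt
#'   of an intron, ending at the 3' splice site); length >= 10.
#' @param minLen minimal tract length (default 8).
#' @param pyrScore,purScore per-base scores (defaults +1 / -1.5).
#' @return list with `start`, `end` (0-based half-open within the window),
#'   `score` and `pyrimidine_fraction`, or NULL when no segment of minimal
#'   length scores above 0.
#' @examples
#' findPolypyrimidineTract(paste(rep("T", 50), collapse = ""))
#' @export
findPolypyrimidineTract <- function(window, minLen = 8L, pyrScore = 1,
                                    purScore = -1.5) {
  window <- toupper(gsub("U", "T", as.character(window)))
  if (!grepl("^[ACGT]*$", window)) stop("window contains non-ACGU/ACGT characters")
  L <- nchar(window)
  if (L < 10L) stop("window must be at least 10 nt long")
  base <- strsplit(window, "")[[1]]
  s <- ifelse(base %in% c("C", "T"), pyrScore, purScore)
  prefix <- c(0, cumsum(s))              # prefix[i+1] = score of window[1..i]
  best <- NULL                           # (score, start, end), 0-based half-open
  min_idx <- 1L                          # index into prefix of the running min
  for (e in seq.int(minLen, L)) {
    cand <- e - minLen + 1L              # prefix index newly eligible as start
    if (prefix[cand] < prefix[min_idx]) min_idx <- cand
    score <- prefix[e + 1L] - prefix[min_idx]
    start <- min_idx - 1L
    if (is.null(best) ||
        score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           (start < best$start ||
              (start == best$start && e > best$end)))) {
      best <- list(score = score, start = start, end = e)
    }
  }
  if (is.null(best) || best$score <= 0) return(NULL)
  seg <- base[(best$start + 1L):best$end]
  list(start = best$start, end = best$end, score = best$score,
       pyrimidine_fraction = mean(seg %in% c("C", "T")))
}

#' k-mer presence enrichment between foreground and background windows
#'
#' For each k-mer observed in either set, counts the windows containing at
#' least one occurrence and tests the 2x2 presence/absence table with a
#' two-sided Fisher exact test. Alphabets are unified on DNA (U -> T).
#'
#' @param fgWindows,bgWindows character vectors (or `DNAStringSet`) of
#'   foreground and background windows; both non-empty.
#' @param k k-mer length (>= 2, at most the shortest window length).
#' @return data.frame sorted by P: `kmer`, `fg_present`, `fg_total`,
#'   `bg_present`, `bg_total`, `p`, `fold` (ratio of presence fractions;
#'   Inf when absent from the background).
#' @export
kmerEnrichment <- function(fgWindows, bgWindows, k) {
  fg <- toupper(gsub("U", "T", as.character(fgWindows)))
  bg <- toupper(gsub("U", "T", as.character(bgWindows)))
  if (!length(fg) || !length(bg)) stop("foreground and background must be non-empty")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > min(nchar(c(fg, bg)))) stop("k exceeds the shortest window length")
  kmers_of <- function(s) {
    n <- nchar(s)
    unique(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
  }
  fg_sets <- lapply(fg, kmers_of)
  bg_sets <- lapply(bg, kmers_of)
  all_kmers <- sort(unique(c(unlist(fg_sets), unlist(bg_sets))))
  fg_present <- vapply(all_kmers, function(m)
    sum(vapply(fg_sets, function(s) m %in% s, logical(1))), integer(1))
  bg_present <- vapply(all_kmers, function(m)
    sum(vapply(bg_sets, function(s) m %in% s, logical(1))), integer(1))
  nf <- length(fg); nb <- length(bg)
  p <- vapply(seq_along(all_kmers), function(i) {
    tab <- matrix(c(fg_present[i], nf - fg_present[i],
                    bg_present[i], nb - bg_present[i]), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  fold <- (fg_present / nf) / (bg_present / nb)
  out <- data.frame(kmer = all_kmers, fg_present = fg_present, fg_total = nf,
                    bg_present = bg_present, bg_total = nb, p = p, fold = fold,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$kmer), , drop = FALSE]
}

#' Offset of a motif site from the polypyrimidine-tract 3' end
#'
#' `offset = siteStart - tract$end` in window coordinates (both 0-based):
#' 0 means the motif begins immediately after the tract, negative values
#' place it inside the tract (as for a GC motif near the tract's 3' end).
#'
#' @param tract tract as returned by [findPolypyrimidineTract()].
#' @param siteStart 0-based motif start within the same window.
#' @return signed integer offset.
#' @export
motifOffset <- function(tract, siteStart) {
  if (is.null(tract)) stop("tract is undefined")
  as.integer(siteStart) - as.integer(tract$end)
}

#' Predict the splicing effect of a point substitution near a GC element
#'
#' Applies the mutagenesis rule table for the intronic GC element required
#' for splicing-factor-dependent exon inclusion: G-to-A at the element's G
#' and C-to-U at its C disrupt inclusion; substituting the U that typically
#' precedes the GC is neutral; substitutions outside the annotated element
#' (or combinations not covered by the table) are unknown.
#'
#' @param window character scalar sequence (RNA or DNA alphabet).
#' @param gcStart 0-based position of the element's G within `window`.
#' @param position 0-based substitution position.
#' @param from,to single bases (RNA or DNA alphabet); `from` must match the
#'   sequence at `position`.
#' @return one of `"disrupting"`, `"neutral"`, `"unknown"`.
#' @examples
#' predictSubstitutionEffect("AAATTTTGCAG", gcStart = 7, position = 7,
#'                           from = "G", to = "A")  # disrupting
#' @export
predictSubstitutionEffect <- function(window, gcStart, position, from, to) {
  norm <- function(x) toupper(gsub("U", "T", x))
  window <- norm(as.character(window))
  from <- norm(from); to <- norm(to)
  gcStart <- as.integer(gcStart); position <- as.integer(position)
  if (position < 0L || position >= nchar(window))
    stop("substitution position outside the window")
  actual <- substr(window, position + 1L, position + 1L)
  if (actual != from)
    stop("from-base '", from, "' disagrees with sequence base '", actual, "'")
  if (substr(window, gcStart + 1L, gcStart + 2L) != "GC")
    stop("no GC element at the annotated position")
  if (position == gcStart && from == "G" && to == "A") return("disrupting")
  if (position == gcStart + 1L && from == "C" && to == "T") return("disrupting")
  if (position == gcStart - 1L && from == "T" && to %in% c("C", "G", "A"))
    return("neutral")
  "unknown"
}
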