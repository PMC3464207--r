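RNA_BASES <- c("A", "C", "G", "U")

# encode a DNA/RNA string as integers 1..4 over A,C,G,U (T == U)
encode_rna <- function(s) {
  s <- toupper(gsub("U", "T", as.character(s)))
  v <- match(strsplit(chartr("T", "U", s), "")[[1]], RNA_BASES)
  if (anyNA(v)) stop("sequence contains non-ACGU/ACGT characters")
  v
}

#' Discover an ungapped motif by ZOOPS expectation-maximization
#'
#' Fits the zero-or-one-occurrence-per-sequence (ZOOPS) motif model by EM:
#' each sequence either contains one motif site (prior probability `gamma`,
#' uniform over positions) emitted by a position-frequency matrix, or is
#' emitted entirely by a 0th-order background estimated once from all
#' input. The E step computes the posterior over site positions (plus the
#' no-site alternative), the M step re-estimates the matrix and `gamma`.
#' Iteration stops when the log-likelihood improves by less than `tol`.
#'
#' Starting points follow the classic motif-discovery recipe: every
#' distinct w-mer occurring in the input seeds one candidate matrix, each
#' candidate runs a short EM burn-in, and the `nRefine` most promising
#' candidates are refined to convergence; the highest-likelihood fit wins.
#' When more than `maxStarts` distinct w-mers exist, a seeded random
#' subset is used, so the result is deterministic given `seed`.
#'
#' @param sequences character vector or `DNAStringSet`; every sequence must
#'   be at least `w` long. T and U are equivalent; the model works on the
#'   RNA alphabet.
#' @param w motif width (>= 2).
#' @param seed integer seed (used only when starting points are subsampled).
#' @param nRefine number of top burn-in candidates refined to convergence.
#' @param maxStarts cap on the number of distinct w-mer starting points.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter iteration cap per refined run.
#' @param pseudocount Dirichlet pseudocount in the M step.
#' @return A [MotifModel-class].
#' @examples
#' seqs <- paste0(substr(c("ACGAAG", "CGTAAC", "GGATCC"), 1, 6), "TGC", "AAAA")
#' motifConsensus(discoverMotifZoops(seqs, w = 3, seed = 1))
#' @export
discoverMotifZoops <- function(sequences, w, seed = 1L, nRefine = 3L,
                               maxStarts = 100L, tol = 1e-6, maxIter = 200L,
                               pseudocount = 1e-3) {
  w <- as.integer(w)
  if (w < 2L) stop("motif width must be >= 2")
  enc <- lapply(as.character(sequences), encode_rna)
  if (any(lengths(enc) < w)) stop("every sequence must be at least w long")
  n <- length(enc)
  if (n < 2L) stop("need at least 2 sequences")

  # fixed 0th-order background
  bg <- tabulate(unlist(enc), nbins = 4L) + 1
  bg <- bg / sum(bg)

  # per-sequence site machinery: index matrix of the w bases at each start
  site_idx <- lapply(enc, function(x) {
    m <- length(x) - w + 1L
    matrix(x[outer(seq_len(m), 0:(w - 1L), "+")], m, w)
  })
  bg_loglik <- vapply(enc, function(x) sum(log(bg[x])), numeric(1))

  run_em <- function(pfm0, iter_cap) {
    pfm <- pfm0
    gamma <- 0.5
    trace <- numeric(0)
    prev <- -Inf
    repeat {
      lpfm_ratio <- log(pfm) - log(bg)         # 4 x w
      # E step: per sequence, log-weights of no-site vs each site
      stats <- lapply(seq_len(n), function(i) {
        si <- site_idx[[i]]
        m <- nrow(si)
        site_lr <- rowSums(matrix(lpfm_ratio[cbind(as.vector(si),
                                                   rep(seq_len(w), each = m))],
                                  m, w))
        lw <- c(log1p(-gamma), log(gamma) - log(m) + site_lr)
        mx <- max(lw)
        wts <- exp(lw - mx)
        list(post = wts / sum(wts),           # element 1 = no site
             loglik = bg_loglik[i] + mx + log(sum(wts)))
      })
      ll <- sum(vapply(stats, `[[`, numeric(1), "loglik"))
      trace <- c(trace, ll)
      if (ll - prev < tol) break
      prev <- ll
      # M step
      counts <- matrix(pseudocount, 4L, w)
      site_mass <- 0
      for (i in seq_len(n)) {
        post <- stats[[i]]$post[-1L]
        site_mass <- site_mass + sum(post)
        si <- site_idx[[i]]
        for (k in seq_len(w)) {
          tab <- vapply(1:4, function(a) sum(post[si[, k] == a]), numeric(1))
          counts[, k] <- counts[, k] + tab
        }
      }
      gamma <- min(max(site_mass / n, 1e-6), 1 - 1e-6)
      pfm <- sweep(counts, 2, colSums(counts), "/")
      if (length(trace) >= iter_cap) break
    }
    list(pfm = pfm, gamma = gamma, trace = trace, stats = stats,
         loglik = trace[length(trace)])
  }

  # starting-point search: one candidate matrix per distinct w-mer
  all_mers <- unique(do.call(rbind, site_idx))
  if (nrow(all_mers) > maxStarts)
    all_mers <- withr::with_seed(seed,
      all_mers[sample.int(nrow(all_mers), maxStarts), , drop = FALSE])
  seed_pfm <- function(mer) {
    pfm0 <- matrix(0.1, 4L, w)
    pfm0[cbind(mer, seq_len(w))] <- 0.7
    sweep(pfm0, 2, colSums(pfm0), "/")
  }
  burnin <- lapply(seq_len(nrow(all_mers)), function(i)
    run_em(seed_pfm(all_mers[i, ]), iter_cap = 5L))
  top <- order(vapply(burnin, `[[`, numeric(1), "loglik"),
               decreasing = TRUE)[seq_len(min(nRefine, length(burnin)))]
  fits <- lapply(top, function(i) run_em(burnin[[i]]$pfm, iter_cap = maxIter))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  post_site <- vapply(best$stats, function(s) 1 - s$post[1L], numeric(1))
  site_start <- vapply(best$stats, function(s) {
    if (s$post[1L] >= max(s$post[-1L])) NA_integer_
    else which.max(s$post[-1L])
  }, integer(1))
  rownames(best$pfm) <- RNA_BASES
  consensus <- paste(RNA_BASES[apply(best$pfm, 2, which.max)], collapse = "")
  new("MotifModel", pfm = best$pfm, consensus = consensus,
      sitePosterior = post_site, siteStart = site_start,
      gamma = best$gamma, logLik = best$loglik, logLikTrace = best$trace)
}

#' Information content of a motif model
#'
#' Total information content (bits) of the position-frequency matrix
#' relative to the uniform background: `sum over columns of
#' 2 + sum_a f log2 f`.
#'
#' @param model a [MotifModel-class].
#' @return numeric, bits.
#' @export
motifInformationContent <- function(model) {
  f <- motifPFM(model)
  sum(apply(f, 2, function(col) {
    nz <- col > 0
    2 + sum(col[nz] * log2(col[nz]))
  }))
}
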