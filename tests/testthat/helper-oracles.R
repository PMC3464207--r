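# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive implementation kept separate from the package code
# paths it checks.

# exhaustive maximal-scoring segment with minimum length; leftmost start,
# then longest, on score ties
oracle_ppt <- function(window, minLen = 8L, pyrScore = 1, purScore = -1.5) {
  base <- strsplit(toupper(gsub("U", "T", window)), "")[[1]]
  s <- ifelse(base %in% c("C", "T"), pyrScore, purScore)
  L <- length(s)
  best <- NULL
  for (st in 0:(L - minLen)) {
    for (en in (st + minLen):L) {
      sc <- sum(s[(st + 1):en])
      if (is.null(best) || sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
             (st < best$start || (st == best$start && en > best$end))))
        best <- list(start = st, end = en, score = sc)
    }
  }
  if (best$score <= 0) NULL else best
}

# iterative row-then-column median sweeps for the additive two-way model
oracle_medpolish <- function(block, tol = 1e-6, maxiter = 10L) {
  overall <- 0
  row_eff <- rep(0, nrow(block))
  col_eff <- rep(0, ncol(block))
  r <- block
  for (i in seq_len(maxiter)) {
    rm_ <- apply(r, 1, median)
    r <- sweep(r, 1, rm_)
    row_eff <- row_eff + rm_
    cm0 <- median(col_eff)
    col_eff <- col_eff - cm0
    overall <- overall + cm0
    cm_ <- apply(r, 2, median)
    r <- sweep(r, 2, cm_)
    col_eff <- col_eff + cm_
    rm0 <- median(row_eff)
    row_eff <- row_eff - rm0
    overall <- overall + rm0
    if (max(abs(c(rm_, cm_))) < tol) break
  }
  overall + col_eff
}

# BH step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# two-sided Fisher P by full hypergeometric enumeration of the 2x2 table
# (a successes among n1 foreground, b among n2 background)
oracle_fisher <- function(a, n1, b, n2) {
  k <- a + b
  xs <- max(0, k - n2):min(n1, k)
  probs <- dhyper(xs, n1, n2, k)
  obs <- dhyper(a, n1, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive single-deletion search: every (start, len) pair
oracle_delmap <- function(wt, mutant) {
  nw <- nchar(wt); nm <- nchar(mutant)
  d <- nw - nm
  hits <- integer(0)
  for (st in 0:nm) {
    cand <- paste0(substr(wt, 1, st), substr(wt, st + d + 1, nw))
    if (identical(cand, mutant)) hits <- c(hits, st)
  }
  if (!length(hits)) return(NULL)
  list(start = min(hits), ambiguity = length(hits))
}

# exhaustive two-sided permutation p for the pooled t at n = 4 + 4
oracle_perm_p <- function(a, b) {
  obs <- pooledTTest(a, b)[["t"]]
  x <- c(a, b)
  idx <- utils::combn(8, 4)
  ts <- apply(idx, 2, function(k) pooledTTest(x[k], x[-k])[["t"]])
  mean(abs(ts) >= abs(obs) - 1e-12)
}

# random sequences with one planted occurrence of `motif` per sequence
planted_sequences <- function(n, len, motif, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), character(1))
    pos <- sample.int(len - nchar(motif) + 1L, n, replace = TRUE)
    vapply(seq_len(n), function(i) {
      s <- seqs[i]
      substr(s, pos[i], pos[i] + nchar(motif) - 1L) <- motif
      s
    }, character(1))
  })
}
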