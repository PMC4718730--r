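# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and, where possible, the same stats primitives): tails are
# summed term by term, windows are scored with string operations, and
# permutation nulls are enumerated over bitmasks.

# Exact conditional binomial two-sided p by term-wise enumeration.
oracle_pair_p <- function(a, b, lib_a, lib_b) {
  n <- a + b
  if (n == 0) return(1)
  pr <- lib_a / (lib_a + lib_b)
  logpmf <- vapply(0:n, function(k) {
    lchoose(n, k) + k * log(pr) + (n - k) * log(1 - pr)
  }, numeric(1))
  pmf <- exp(logpmf)
  lower <- sum(pmf[seq_len(a + 1)])          # P(X <= a)
  upper <- sum(pmf[(a + 1):(n + 1)])         # P(X >= a)
  min(1, 2 * min(lower, upper))
}

# Brute-force PWM scan: score every window of both strands with substring
# arithmetic on the log-odds matrix.
oracle_scan <- function(seq, p) {
  L <- p$length
  n <- nchar(seq)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  score_window <- function(w) {
    chars <- strsplit(w, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(vapply(seq_len(L), function(j) p$score_matrix[idx[j], j], numeric(1)))
  }
  rows <- list()
  if (n >= L) {
    for (o in 0:(n - L)) {
      w <- substr(seq, o + 1, o + L)
      s_f <- score_window(w)
      if (!is.na(s_f) && s_f >= p$threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          offset = o, strand = "+", score = s_f, stringsAsFactors = FALSE
        )
      }
      s_r <- score_window(revcomp(w))
      if (!is.na(s_r) && s_r >= p$threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          offset = o, strand = "-", score = s_r, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One-sided hypergeometric upper tail P(X >= k) by choose() enumeration.
oracle_hyper_p <- function(k, K, N, n_draw) {
  kk <- max(0, k):min(K, n_draw)
  sum(choose(K, kk) * choose(N - K, n_draw - kk)) / choose(N, n_draw)
}

# Exhaustive two-group mean-difference permutation p over bitmasks.
oracle_perm_p <- function(x, is_a) {
  n <- length(x)
  n_a <- sum(is_a)
  obs <- mean(x[is_a]) - mean(x[!is_a])
  tol <- 1e-12 * (1 + abs(obs))
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(sel) != n_a) next
    total <- total + 1L
    s <- mean(x[sel]) - mean(x[!sel])
    if (abs(s) >= abs(obs) - tol) hits <- hits + 1L
  }
  hits / total
}

# Hand-applied Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
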