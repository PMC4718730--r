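# Small fixtures built in code.

# A count matrix with `reps` replicates per group, Poisson counts around
# group-specific means (same composition unless tweaked by the caller).
make_counts <- function(n_genes = 200, reps = 3, seed = 1,
                        mean_count = 50,
                        groups = SAMPLE_GROUPS) {
  set.seed(seed)
  cols <- list()
  grp <- character(0)
  for (g in groups) {
    for (k in seq_len(reps)) {
      cols[[paste0(g, "_rep", k)]] <- rpois(n_genes, mean_count)
      grp <- c(grp, g)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  count_matrix(counts, lengths_bp = rep(1000, n_genes), groups = grp)
}

# A random informative PWM of length L (gamma frequencies, one dominant
# base per position so the 0.85-of-max threshold is attainable).
make_pwm <- function(L = 8, seed = 1, name = "TF", threshold_fraction = 0.85,
                     dominance = 6) {
  set.seed(seed)
  m <- matrix(rgamma(4 * L, 1), 4, L)
  dom <- sample.int(4, L, replace = TRUE)
  m[cbind(dom, seq_len(L))] <- m[cbind(dom, seq_len(L))] + dominance
  pwm(m, tf_name = name, threshold_fraction = threshold_fraction)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
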