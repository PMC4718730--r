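test_that("TPM matches the closed form and handles degenerate columns", {
  cm <- count_matrix(
    matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    lengths_bp = c(1000, 2000), groups = "egfp_pos"
  )
  tpm <- compute_tpm(cm)
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  one <- count_matrix(
    matrix(7, 1, 1, dimnames = list("g1", "s1")), 500, "egfp_pos"
  )
  expect_equal(unname(compute_tpm(one)[1, 1]), 1e6)

  zero <- count_matrix(
    matrix(c(5, 2, 0, 0), 2, 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    c(1000, 1000), c("egfp_pos", "egfp_neg")
  )
  expect_warning(tpm0 <- compute_tpm(zero), "all-zero")
  expect_equal(unname(tpm0[, "s2"]), c(0, 0))
})

test_that("TPM columns sum to 1e6 and are scale-invariant per sample", {
  for (seed in 1:5) {
    cm <- make_counts(n_genes = 100, reps = 2, seed = seed)
    tpm <- compute_tpm(cm)
    expect_equal(unname(colSums(tpm)), rep(1e6, ncol(tpm)), tolerance = 1e-9)
    scaled <- cm
    scaled$counts[, 1] <- scaled$counts[, 1] * 17
    expect_equal(compute_tpm(scaled)[, 1], tpm[, 1], tolerance = 1e-12)
  }
})

test_that("count_matrix rejects invalid inputs", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("a", "b")))
  expect_error(count_matrix(m, c(100, 100), c("egfp_pos", "egfp_neg")),
               "duplicate")
  m2 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(count_matrix(m2, c(0, 100), c("egfp_pos", "egfp_neg")),
               "positive")
  expect_error(count_matrix(m2, c(100, 100), c("egfp_pos", "nope")),
               "unknown sample group")
})

test_that("TMM factors: identity, doubling, and outlier trimming", {
  cm <- make_counts(n_genes = 300, reps = 1, seed = 2,
                    groups = c("egfp_pos", "egfp_neg"))
  cm$counts[, 2] <- cm$counts[, 1]
  expect_equal(unname(tmm_factors(cm, 1)), c(1, 1))

  cm$counts[, 2] <- 2 * cm$counts[, 1]
  expect_equal(unname(tmm_factors(cm, 1)[2]), 2, tolerance = 1e-12)

  # one wild composition outlier is trimmed away
  cm$counts[, 2] <- cm$counts[, 1]
  cm$counts[5, 2] <- cm$counts[5, 1] * 100
  f <- unname(tmm_factors(cm, 1)[2])
  expect_equal(f, 1, tolerance = 1e-6)
  # brute-force check: trimmed mean without the outlier is exactly 0
  keep <- cm$counts[, 1] > 0 & cm$counts[, 2] > 0
  m_vals <- log2(cm$counts[keep, 2] / cm$counts[keep, 1])
  expect_equal(sum(m_vals != 0), 1)  # only the outlier deviates
})

test_that("TMM scale-equivariance: scaling a sample scales its factor", {
  # exact in the no-composition-change case (all M equal)
  cm <- make_counts(n_genes = 400, reps = 1, seed = 3,
                    groups = c("egfp_pos", "egfp_neg"))
  cm$counts[, 2] <- cm$counts[, 1] * 5
  expect_equal(unname(tmm_factors(cm, 1)[2]), 5, tolerance = 1e-12)
  # approximate under sampling noise (weights change with the scale)
  noisy <- make_counts(n_genes = 400, reps = 1, seed = 3,
                       groups = c("egfp_pos", "egfp_neg"))
  f1 <- tmm_factors(noisy, 1)[2]
  noisy$counts[, 2] <- noisy$counts[, 2] * 5
  f5 <- tmm_factors(noisy, 1)[2]
  expect_equal(unname(f5 / f1), 5, tolerance = 0.01)
})

test_that("TMM factors divided by library size agree with edgeR up to a constant", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  counts <- matrix(rpois(500 * 3, rlnorm(500, 4, 1)), 500, 3)
  counts[1:50, 2] <- counts[1:50, 2] * 4  # composition bias in sample 2
  rownames(counts) <- sprintf("g%03d", 1:500)
  colnames(counts) <- c("a", "b", "c")
  cm <- count_matrix(counts, rep(1000, 500),
                     c("egfp_pos", "egfp_neg", "whole_head"))
  ours <- tmm_factors(cm, 1)
  theirs <- edgeR::calcNormFactors(counts, refColumn = 1,
                                   logratioTrim = 0.3, sumTrim = 0.05)
  rel_ours <- (ours / colSums(counts)) / (ours / colSums(counts))[1]
  rel_theirs <- theirs / theirs[1]
  expect_equal(unname(rel_ours), unname(rel_theirs), tolerance = 0.02)
})

test_that("pool_replicates sums within groups and commutes with permutations", {
  cm <- make_counts(n_genes = 50, reps = 3, seed = 5)
  pooled <- pool_replicates(cm)
  expect_equal(ncol(pooled$counts), 3)
  for (g in SAMPLE_GROUPS) {
    expect_equal(pooled$counts[, g],
                 rowSums(cm$counts[, cm$groups == g, drop = FALSE]))
  }
  expect_equal(sum(pooled$counts[, "egfp_pos"]),
               sum(cm$counts[, cm$groups == "egfp_pos"]))

  # permuting replicate columns within a group changes nothing
  perm <- c(3, 1, 2, 4:9)
  cm_p <- count_matrix(cm$counts[, perm], cm$lengths_bp, cm$groups[perm])
  expect_equal(pool_replicates(cm_p)$counts, pooled$counts)

  one <- make_counts(n_genes = 20, reps = 1, seed = 6)
  expect_equal(pool_replicates(one)$counts[, "egfp_pos"],
               one$counts[, "egfp_pos_rep1"])
})

test_that("fold change uses the larger control and the pseudocount rule", {
  expect_equal(fold_change(300, c(10, 10), pseudocount = 0), 30)
  expect_equal(fold_change(50, c(50, 10), pseudocount = 0), 1)
  expect_equal(fold_change(9, c(0, 0), pseudocount = 1), 10)
  expect_equal(fold_change(10, c(2, 5), pseudocount = 0), 2)
  expect_error(fold_change(-1, c(1, 1)), "non-negative")
  # matrix form takes the row-wise max
  ctl <- cbind(c(1, 10), c(4, 2))
  expect_equal(fold_change(c(8, 20), ctl, pseudocount = 0), c(2, 2))
})
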