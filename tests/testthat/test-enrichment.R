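test_that("pair test matches hand values and basic contracts", {
  expect_equal(poisson_pair_test(10, 1, 10, 1), 1)
  expect_equal(poisson_pair_test(20, 1, 0, 1), 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(poisson_pair_test(0, 1, 0, 1), 1)
  expect_error(poisson_pair_test(-1, 1, 1, 1), "non-negative")
  expect_error(poisson_pair_test(1, 0, 1, 1), "positive")
  expect_error(poisson_pair_test(1, 1, 1, 1, phi = 0.5), ">= 1")
})

test_that("pair test is symmetric under swapping the two samples", {
  set.seed(10)
  for (i in 1:50) {
    a <- rpois(1, 30); b <- rpois(1, 10)
    la <- runif(1, 0.5, 5); lb <- runif(1, 0.5, 5)
    expect_equal(poisson_pair_test(a, la, b, lb),
                 poisson_pair_test(b, lb, a, la), tolerance = 1e-12)
  }
})

test_that("pair test with phi = 1 equals the enumeration oracle on a grid", {
  for (a in c(0, 1, 3, 7, 20)) {
    for (b in c(0, 2, 5, 19)) {
      for (r in c(1, 2, 5)) {
        expect_equal(poisson_pair_test(a, 1, b, r),
                     oracle_pair_p(a, b, 1, r), tolerance = 1e-9,
                     info = sprintf("a=%d b=%d ratio=%g", a, b, r))
      }
    }
  }
})

test_that("phi deflates counts before testing", {
  # a=40, b=0, phi=2 behaves like the exact test on 20 vs 0
  expect_equal(poisson_pair_test(40, 1, 0, 1, phi = 2),
               poisson_pair_test(20, 1, 0, 1))
})

test_that("overdispersion estimation recovers the generative factor", {
  sim1 <- simulate_count_experiment(count_sim_config(
    n_genes = 3000, overdispersion_factor = 1, seed = 11
  ))
  expect_equal(estimate_overdispersion(sim1$dataset), 1)

  sim4 <- simulate_count_experiment(count_sim_config(
    n_genes = 5000, overdispersion_factor = 4, seed = 12
  ))
  phi4 <- estimate_overdispersion(sim4$dataset)
  expect_gte(phi4, 3)
  expect_lte(phi4, 5)

  single <- make_counts(n_genes = 100, reps = 1, seed = 13)
  expect_warning(phi1 <- estimate_overdispersion(single), "replicates")
  expect_equal(phi1, 1)
})

test_that("tier classification applies both threshold sets", {
  cfg <- enrichment_config()
  expect_equal(
    classify_enrichment(300, 30, 1e-5, 100, cfg), "strict"
  )
  expect_equal(
    classify_enrichment(50, 10, 1e-5, 100, cfg), "relaxed"
  )
  expect_equal(classify_enrichment(0, 1, NA, 0, cfg), "none")
  # significance or the reads floor alone can demote
  expect_equal(classify_enrichment(300, 30, 0.5, 100, cfg), "none")
  expect_equal(classify_enrichment(300, 30, 1e-5, 10, cfg), "none")
  expect_error(enrichment_config(relaxed_tpm = 200), "relaxed")
})

test_that("pipeline output is sorted, tier-nested and Bonferroni-consistent", {
  sim <- simulate_count_experiment(count_sim_config(
    n_genes = 3000, n_planted = 30, planted_fold = 10,
    planted_min_tpm = 150, overdispersion_factor = 2, seed = 21
  ))
  res <- run_enrichment_pipeline(sim$dataset)
  expect_true(all(diff(res$fold_vs_max_control) <= 1e-12))
  expect_true(all(res$fold_vs_max_control > 3.6))
  m <- attr(res, "n_tested")
  tested <- !is.na(res$p_adjusted)
  expect_equal(res$p_adjusted[tested],
               pmin(1, m * res$p_raw[tested]))
  expect_true(all(res$p_adjusted[tested] >= res$p_raw[tested]))
  # strict records satisfy the relaxed criteria too
  strict <- res[res$tier == "strict", ]
  expect_true(all(strict$tpm_egfp_pos >= 10 &
                    strict$fold_vs_max_control >= 3.6))
})

test_that("planted genes are recovered and alpha is monotone", {
  sim <- simulate_count_experiment(count_sim_config(
    n_genes = 3000, n_planted = 30, planted_fold = 10,
    planted_min_tpm = 150, overdispersion_factor = 2, seed = 22
  ))
  res <- run_enrichment_pipeline(sim$dataset)
  strict <- res$gene_id[res$tier == "strict"]
  expect_gte(mean(sim$truth$gene_id %in% strict), 0.9)
  if (length(strict)) {
    expect_lte(mean(!strict %in% sim$truth$gene_id), 0.05)
  }
  # raising alpha never removes calls
  res_loose <- run_enrichment_pipeline(
    sim$dataset, enrichment_config(alpha = 0.05)
  )
  called <- res$gene_id[res$tier != "none"]
  called_loose <- res_loose$gene_id[res_loose$tier != "none"]
  expect_true(all(called %in% called_loose))
})

test_that("pipeline demands all three sample groups", {
  cm <- make_counts(n_genes = 50, reps = 2, seed = 23,
                    groups = c("egfp_pos", "egfp_neg"))
  expect_error(run_enrichment_pipeline(cm), "whole_head")
})

test_that("per-replicate pooling mode runs and is at least as conservative", {
  sim <- simulate_count_experiment(count_sim_config(
    n_genes = 500, n_planted = 10, planted_fold = 10,
    planted_min_tpm = 150, overdispersion_factor = 1, seed = 24
  ))
  pooled <- run_enrichment_pipeline(
    sim$dataset, enrichment_config(overdispersion = "fixed", phi = 1)
  )
  per_rep <- run_enrichment_pipeline(
    sim$dataset,
    enrichment_config(overdispersion = "fixed", phi = 1,
                      pooling = "per_replicate")
  )
  shared <- intersect(pooled$gene_id, per_rep$gene_id)
  p1 <- pooled$p_raw[match(shared, pooled$gene_id)]
  p2 <- per_rep$p_raw[match(shared, per_rep$gene_id)]
  expect_true(all(p2 >= p1 - 1e-12))
})
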