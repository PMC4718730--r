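test_that("conservation filter keeps planted sites and drops singletons", {
  pw <- make_pwm(L = 8, seed = 30)
  sim <- simulate_promoter_set(
    n_genes = 60, n_foreground = 48, promoter_length = 200, motif = pw,
    planted_fraction_foreground = 30 / 48, background_rate = 0.3,
    n_species = 3, seed = 11
  )
  species <- paste0("sp", 1:3)
  hits <- scan_promoters(sim$promoters, pw)
  cons <- filter_conserved_hits(hits, species)
  planted <- sim$truth[sim$truth$species == "all", ]
  expect_equal(nrow(planted), 30)
  expect_true(all(planted$gene_id %in% cons$gene_id))
  # planted offsets are recovered within the tolerance window
  idx <- match(planted$gene_id, cons$gene_id)
  expect_true(all(abs(cons$offset[idx] - planted$offset) <= 10))
  # single-species background placements in the reference must not survive
  lonely <- sim$truth$gene_id[sim$truth$species == "sp1"]
  spurious <- setdiff(intersect(lonely, cons$gene_id), planted$gene_id)
  expect_length(spurious, 0)
})

test_that("one species degenerates the filter to plain scanning", {
  pw <- make_pwm(L = 6, seed = 31)
  sim <- simulate_promoter_set(
    n_genes = 20, promoter_length = 150, motif = pw,
    planted_fraction_foreground = 0.5, background_rate = 0,
    n_species = 1, seed = 12
  )
  hits <- scan_promoters(sim$promoters, pw)
  cons <- filter_conserved_hits(hits, "sp1")
  expect_equal(cons, hits[hits$species == "sp1", ])
})

test_that("nothing planted and no background yields no conserved hits", {
  pw <- make_pwm(L = 10, seed = 32)
  sim <- simulate_promoter_set(
    n_genes = 30, promoter_length = 120, motif = pw,
    planted_fraction_foreground = 0, background_rate = 0,
    n_species = 3, seed = 13
  )
  expect_equal(nrow(sim$truth), 0)
  hits <- scan_promoters(sim$promoters, pw)
  cons <- filter_conserved_hits(hits, paste0("sp", 1:3))
  expect_equal(nrow(cons), 0)
})

test_that("requiring more species never adds conserved hits", {
  pw <- make_pwm(L = 7, seed = 33, threshold_fraction = 0.6)
  sim <- simulate_promoter_set(
    n_genes = 40, promoter_length = 300, motif = pw,
    planted_fraction_foreground = 0.4, background_rate = 0.4,
    n_species = 3, seed = 14
  )
  hits <- scan_promoters(sim$promoters, pw)
  c2 <- filter_conserved_hits(hits, paste0("sp", 1:2))
  c3 <- filter_conserved_hits(hits, paste0("sp", 1:3))
  key <- function(h) paste(h$gene_id, h$offset, h$strand)
  expect_true(all(key(c3) %in% key(c2)))
})

test_that("combined score sums the above-threshold excess", {
  h0 <- data.frame(score = numeric(0))
  expect_equal(combined_gene_score(h0, threshold = 5), 0)
  h <- data.frame(score = c(6, 7))
  expect_equal(combined_gene_score(h, threshold = 5), 3)
  expect_equal(combined_gene_score(h, threshold = 5, method = "max"), 2)
  expect_equal(combined_gene_score(h, threshold = 5, method = "count"), 2)
  # adding a hit never decreases the score
  h2 <- rbind(h, data.frame(score = 5.1))
  expect_gte(combined_gene_score(h2, 5), combined_gene_score(h, 5))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(40)
  p <- runif(25)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  # monotone in the raw ranks
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypergeometric enrichment equals the enumeration oracle", {
  bg <- sprintf("g%03d", 1:480)
  fg <- bg[1:48]
  hit <- c(fg[1:25], bg[300:324])  # 25/48 in foreground, 50/480 overall
  res <- tf_set_enrichment(fg, bg, list(TFX = hit))
  expect_equal(res$p_raw, oracle_hyper_p(25, 50, 480, 48), tolerance = 1e-12)
  # a TF hitting every gene cannot be enriched
  res_all <- tf_set_enrichment(fg, bg, list(TFY = bg))
  expect_equal(res_all$p_raw, 1)
  expect_error(tf_set_enrichment(character(0), bg, list(a = hit)), "empty")
  expect_error(tf_set_enrichment(c(fg, "zzz"), bg, list(a = hit)), "subset")
})

test_that("enrichment table is sorted by p with deterministic ties", {
  bg <- sprintf("g%03d", 1:100)
  fg <- bg[1:10]
  hits <- list(b_tf = fg[1:5], a_tf = fg[1:5], weak = bg[50:60])
  res <- tf_set_enrichment(fg, bg, hits)
  expect_equal(res$tf_name[1:2], c("a_tf", "b_tf"))
  expect_true(all(diff(res$p_raw) >= 0))
})

test_that("full TF analysis ranks the planted factor first", {
  planted_pwm <- make_pwm(L = 8, seed = 50, name = "planted")
  decoys <- lapply(1:3, function(i) {
    make_pwm(L = 8, seed = 60 + i, name = paste0("decoy", i))
  })
  sim <- simulate_promoter_set(
    n_genes = 120, n_foreground = 48, promoter_length = 200,
    motif = planted_pwm, planted_fraction_foreground = 30 / 48,
    background_rate = 0.05, n_species = 3, seed = 15
  )
  res <- run_tf_analysis(
    sim$promoters, c(list(planted_pwm), decoys),
    foreground = attr(sim$truth, "foreground")
  )
  expect_equal(res$enrichment$tf_name[1], "planted")
  expect_lt(res$enrichment$p_bh[1], 0.05)
  # combined scores exist exactly for genes with conserved hits
  expect_setequal(names(res$combined_scores$planted),
                  unique(res$conserved_hits$planted$gene_id))
  expect_true(all(res$combined_scores$planted >= 0))
})
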