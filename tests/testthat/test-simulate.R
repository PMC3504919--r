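tiny_params <- function(n_hotspots = 8, ...) {
  sim_params(K = 10, H = 60, N = 40, M = 300, chrom_length_bp = 1e6,
             n_hotspots = n_hotspots, ...)
}

hot_intervals <- function(panel) {
  hot <- findInterval(panel$hotspots$pos, panel$positions)
  unique(hot[hot >= 1 & hot < length(panel$positions)])
}

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(mask_fraction = 0), "\\(0, 1\\)")
  expect_error(sim_params(lambda_bp = -1), "positive")
  expect_error(sim_params(hotspot_penalty = 2), "\\(0, 1\\]")
  expect_error(sim_params(H = 51), "even")
  expect_error(sim_params(K = 0), ">= 1")
})

test_that("panel generation is deterministic given the seed and seed-sensitive", {
  p <- tiny_params(seed = 3)
  a <- generate_panel(p)
  b <- generate_panel(p)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$hotspots, b$hotspots)
  d <- generate_panel(tiny_params(seed = 4))
  expect_false(identical(a$haplotypes, d$haplotypes))
  expect_true(all(a$haplotypes %in% c(0L, 1L)))
  expect_true(all(diff(a$positions) > 0))
  expect_true(all(pmin(a$founder_freq, 1 - a$founder_freq) >= 0.01))
})

test_that("hotspot odds of 1 leave switch counts uniform across intervals", {
  hot_tot <- bg_tot <- 0; n_hot <- n_bg <- 0
  for (s in 1:30) {
    pan <- generate_panel(tiny_params(seed = 100 + s, hotspot_odds = 1))
    hi <- hot_intervals(pan)
    hot_tot <- hot_tot + sum(pan$switch_counts[hi])
    bg_tot <- bg_tot + sum(pan$switch_counts[-hi])
    n_hot <- n_hot + length(hi)
    n_bg <- n_bg + (length(pan$positions) - 1 - length(hi))
  }
  p_hot <- n_hot / (n_hot + n_bg)
  test <- stats::chisq.test(c(hot_tot, bg_tot), p = c(p_hot, 1 - p_hot))
  expect_gt(test$p.value, 0.01)
})

test_that("hotspot odds of 50 concentrate switches in hotspot intervals", {
  for (s in 1:20) {
    pan <- generate_panel(tiny_params(seed = 200 + s, hotspot_odds = 50))
    hi <- hot_intervals(pan)
    expect_gt(mean(pan$switch_counts[hi]), mean(pan$switch_counts[-hi]))
  }
})

test_that("study genotypes track panel allele frequencies", {
  pan <- generate_panel(tiny_params(seed = 5))
  g <- sample_study(pan, N = 120, seed = 9)
  expect_true(all(g %in% 0:2))
  expect_identical(g, sample_study(pan, N = 120, seed = 9))
  f_panel <- colMeans(pan$haplotypes)
  f_study <- colMeans(g) / 2
  se <- sqrt(pmax(f_panel * (1 - f_panel), 1e-12) / (2 * 120))
  within3 <- abs(f_study - f_panel) <= 3 * se + 1e-12
  expect_gte(mean(within3), 0.95)
})

test_that("surrogate posteriors are normalized and collapse to Hardy-Weinberg far from typed SNPs", {
  p <- tiny_params(seed = 6)
  pan <- generate_panel(p)
  g <- sample_study(pan, N = 30, seed = 7)
  typed <- seq(1, 300, by = 3)
  masked <- c(2, 50, 299)
  post <- surrogate_impute(g, pan, typed, masked, p)
  expect_equal(apply(post, c(1, 2), sum), matrix(1, 3, 30), tolerance = 1e-9,
               ignore_attr = TRUE)
  # lambda far below the typed spacing: alpha ~ 0, posterior = panel HW
  p0 <- tiny_params(seed = 6, lambda_bp = 1e-3)
  post0 <- surrogate_impute(g, pan, typed, masked, p0)
  for (k in seq_along(masked)) {
    fb <- mean(pan$haplotypes[, masked[k]])
    hw <- c((1 - fb)^2, 2 * fb * (1 - fb), fb^2)
    expect_equal(post0[k, , ], matrix(hw, 30, 3, byrow = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(surrogate_impute(g, pan, integer(0), masked, p), "empty")
  expect_error(surrogate_impute(g, pan, typed, c(1, 4), p), "disjoint")
})

test_that("a masked SNP in perfect LD with a close typed SNP is recovered", {
  p <- tiny_params(seed = 8, lambda_bp = 1e9, n_hotspots = 1)
  pan <- generate_panel(p)
  # force hotspot away from the probed region
  pan$hotspots <- hotspot_map(p$chrom, max(pan$positions) - 1, 10)
  s <- 151
  pan$haplotypes[, s] <- pan$haplotypes[, 150]  # duplicate of a typed column
  g <- sample_study(pan, N = 80, seed = 3)
  post <- surrogate_impute(g, pan, seq(2, 298, 2), s, p)
  pm <- post[1, , ]
  p_true <- pm[cbind(seq_len(80), g[, s] + 1)]
  expect_gte(mean(p_true >= 0.95), 0.95)
})

test_that("the paired fixture has disjoint SNP sets and is seed-reproducible", {
  fx <- small_fixture()
  expect_length(intersect(fx$train$imputed_idx, fx$test$imputed_idx), 0)
  expect_length(intersect(fx$train$typed_idx, fx$train$imputed_idx), 0)
  expect_length(intersect(fx$test$typed_idx, fx$test$imputed_idx), 0)
  # training typed set is the old platform minus its masked SNPs
  expect_setequal(c(fx$train$typed_idx, fx$train$imputed_idx),
                  fx$test$typed_idx)
  fx2 <- build_fixture(small_params())
  expect_identical(fx2$test$posteriors, fx$test$posteriors)
  fx3 <- build_fixture(small_params(seed = 12))
  expect_false(identical(fx3$test$posteriors, fx$test$posteriors))
})

test_that("true quality links to distance and posterior-confidence features", {
  fx <- small_fixture()
  sc <- scenario_scores(fx$test)
  fe <- scenario_features(fx$test)
  ok <- !is.na(sc$iqs)
  expect_lt(stats::cor(sc$iqs[ok], fe$dist_nearest_typed_bp[ok],
                       method = "spearman"), 0)
  expect_gte(stats::cor(sc$iqs[ok], fe$mean_posterior[ok],
                        method = "spearman"), 0.2)
})
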