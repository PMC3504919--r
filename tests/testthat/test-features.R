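test_that("feature vector layout is frozen", {
  expect_identical(iqs_feature_names(),
                   c("chrom_code", "pos_bp", "platform_maf", "mean_baf",
                     "panel_maf", "ratio_aa_ab", "ratio_bb_ab",
                     "dist_nearest_typed_bp", "dist_nearest_hotspot_bp",
                     "hotspot_rate_cM_per_Mb", "mean_posterior",
                     "mean_b_dosage"))
})

test_that("panel genotype ratios apply the additive pseudocount", {
  r <- panel_ratios(40, 20, 10, pseudocount = 1)
  expect_equal(r$ratio_aa_ab, 41 / 21)
  expect_equal(r$ratio_bb_ab, 11 / 21)
  empty <- panel_ratios(0, 0, 0, pseudocount = 1)
  expect_equal(c(empty$ratio_aa_ab, empty$ratio_bb_ab), c(1, 1))
  sym <- panel_ratios(7, 7, 7, pseudocount = 0)
  expect_equal(c(sym$ratio_aa_ab, sym$ratio_bb_ab), c(1, 1))
  expect_error(panel_ratios(3, 0, 1, pseudocount = 0), "pseudocount")
  expect_error(panel_ratios(-1, 2, 3), "nonnegative")
})

test_that("nearest typed-SNP distance matches a linear-scan oracle", {
  expect_equal(nearest_typed_distance(150, c(100, 200)), 50)
  expect_equal(nearest_typed_distance(100, c(100, 250, 300)), 0)
  expect_error(nearest_typed_distance(5, numeric(0)), "non-empty")
  set.seed(21)
  typed <- sort(sample.int(1e6, 400))
  q <- sample.int(1e6, 1000, replace = TRUE)
  oracle <- vapply(q, function(p) min(abs(p - typed)), numeric(1))
  expect_identical(nearest_typed_distance(q, typed), oracle)
})

test_that("nearest hotspot picks minimal distance with lower-position ties", {
  hs <- hotspot_map(chrom = c(1, 1), pos = c(400, 700), rate = c(12, 3))
  nh <- nearest_hotspot(500, hs, chrom = 1)
  expect_equal(nh$distance_bp, 100)
  expect_equal(nh$rate_cM_per_Mb, 12)
  tie <- hotspot_map(chrom = c(1, 1), pos = c(400, 600), rate = c(2, 9))
  expect_equal(nearest_hotspot(500, tie, 1)$rate_cM_per_Mb, 2)
  expect_error(nearest_hotspot(500, hs, chrom = 2), "no recombination hotspot")
  set.seed(22)
  hpos <- sort(sample.int(1e6, 50))
  hrate <- runif(50, 0, 60)
  map <- hotspot_map(rep(1L, 50), hpos, hrate)
  q <- sample.int(1e6, 500, replace = TRUE)
  res <- nearest_hotspot(q, map, 1)
  for (i in seq_along(q)) {
    d <- abs(q[i] - hpos)
    j <- which(d == min(d))[1]  # lower position on ties
    expect_equal(res$distance_bp[i], d[j])
    expect_equal(res$rate_cM_per_Mb[i], hrate[j])
  }
})

test_that("posterior summaries follow their defining formulas", {
  expect_equal(mean_posterior(rbind(c(1, 0, 0), c(1, 0, 0))), 1)
  expect_equal(mean_posterior(c(1, 1, 1) / 3), 1 / 3)
  expect_equal(mean_posterior(rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))), 0.55)
  expect_equal(mean_b_dosage(c(0.2, 0.5, 0.3)), 1.1)
  expect_equal(mean_b_dosage(rbind(c(1, 0, 0), c(1, 0, 0))), 0)
  expect_equal(mean_b_dosage(rbind(c(0, 0, 1), c(0, 0, 1))), 2)
  # half the mean B dosage is exactly the posterior-implied B-allele frequency
  for (i in 1:25) {
    p <- random_posteriors(40, seed = 100 + i)
    implied_baf <- mean(p %*% c(0, 1, 2)) / 2
    expect_equal(mean_b_dosage(p) / 2, implied_baf, tolerance = 1e-12)
  }
})

test_that("genotype-derived B-allele frequency averages b counts over two alleles", {
  expect_equal(mean_baf(c("AA", "BB")), 0.5)
  expect_equal(mean_baf(c("AB", "AB")), 0.5)
  expect_equal(mean_baf(c("AA", "AB", "BB", "BB")), 0.625)
  expect_equal(mean_baf(c("AA", NA, "BB")), 0.5)
  expect_error(mean_baf(c(NA, NA)), "missing")
})

test_that("assemble_features composes component features deterministically", {
  hs <- hotspot_map(chrom = 1, pos = 400, rate = 12)
  post <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3))
  args <- list(snp_id = "rs1", chrom = 1, pos = 500, platform_maf = 0.2,
               panel_counts = c(40, 20, 10), typed_positions = c(100, 640),
               map = hs, posteriors = post,
               baf_genotypes = c("AA", "AB", "BB", "BB"))
  v <- do.call(assemble_features, args)
  expect_identical(names(v), iqs_feature_names())
  expect_equal(unname(v), c(1, 500, 0.2, 0.625, min(40 / 140, 100 / 140),
                            41 / 21, 11 / 21, 140, 100, 12, 0.55,
                            (0.5 + 1.1) / 2))
  expect_identical(v, do.call(assemble_features, args))
  args$map <- hotspot_map(chrom = 2, pos = 400, rate = 12)
  expect_error(do.call(assemble_features, args), "rs1")
})
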