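test_that("the panel-MAF filter removes strictly below 1%", {
  snps <- data.frame(snp_id = c("a", "b", "c"), maf = c(0.3, 0.3, 0.3))
  panel <- data.frame(snp_id = c("a", "b", "c"), maf = c(0.005, 0.01, 0.3))
  out <- apply_snp_filters(snps, panel)
  expect_identical(out$retained$snp_id, c("b", "c"))
  expect_equal(out$log$n_maf_removed, 1)
  expect_equal(out$log$n_retained, 2)
})

test_that("allele reconciliation flips strands and drops irreconcilable or ambiguous SNPs", {
  snps <- data.frame(snp_id = c("flip", "bad", "at_safe", "at_risky"),
                     maf = c(0.2, 0.2, 0.2, 0.45),
                     allele_a = c("A", "A", "A", "A"),
                     allele_b = c("C", "G", "T", "T"))
  panel <- data.frame(snp_id = snps$snp_id, maf = c(0.2, 0.2, 0.2, 0.45),
                      allele_a = c("G", "A", "A", "A"),
                      allele_b = c("T", "C", "T", "T"))
  out <- apply_snp_filters(snps, panel)
  expect_identical(out$retained$snp_id, c("flip", "at_safe"))
  expect_equal(out$log$n_inconsistent_removed, 1)
  expect_equal(out$log$n_ambiguous_removed, 1)
})

test_that("training-mask is an exact, reproducible partition", {
  typed <- paste0("s", 1:1000)
  m1 <- mask_training_snps(typed, fraction = 0.1, seed = 5)
  expect_length(m1$masked, 100)
  expect_setequal(c(m1$kept, m1$masked), typed)
  expect_length(intersect(m1$kept, m1$masked), 0)
  m2 <- mask_training_snps(typed, fraction = 0.1, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(m1$masked,
                         mask_training_snps(typed, 0.1, seed = 6)$masked))
  expect_error(mask_training_snps(typed, fraction = 0), "\\(0, 1\\)")
  expect_error(mask_training_snps(typed, fraction = 1.2), "\\(0, 1\\)")
})

test_that("regression metrics follow their definitions", {
  y <- c(0.1, 0.4, 0.9)
  expect_equal(regression_metrics(y, y), list(mse = 0, pearson_r = 1))
  m <- regression_metrics(y, y + 0.1)
  expect_equal(m$mse, 0.01)
  expect_equal(m$pearson_r, 1)
  m2 <- regression_metrics(c(0, 1), c(1, 0))
  expect_equal(m2$mse, 1)
  expect_equal(m2$pearson_r, -1)
  expect_true(is.na(regression_metrics(c(1, 1), c(0, 1))$pearson_r))
  expect_error(regression_metrics(1:3, 1:2), "equal length")
})

test_that("filtering labels use a strict below-threshold rule", {
  expect_true(filtering_labels(0.49, 0.5))
  expect_false(filtering_labels(0.5, 0.5))
  iqs_vals <- seq(0, 1, by = 0.05)
  l05 <- filtering_labels(iqs_vals, 0.5)
  l09 <- filtering_labels(iqs_vals, 0.9)
  expect_true(all(l09[l05]))  # 0.9 positives are a superset
  expect_error(filtering_labels(c(0.2, NA), 0.5), "defined")
})

test_that("ROC/AUC matches brute-force pair counting and handles ties", {
  # lower quality score = more positive; perfect separation
  perfect <- roc_auc(scores = c(1, 2, 3, 10, 11), labels = c(T, T, T, F, F))
  expect_equal(perfect$auc, 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  pair_count_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (p in pos) tot <- tot + sum(neg > p) + 0.5 * sum(neg == p)
    tot / (length(pos) * length(neg))
  }
  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC/AUC agrees with pROC on a labelled example", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- runif(200)
  labels <- runif(200) < plogis(5 * (0.5 - scores))
  ours <- roc_auc(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = labels,
                                              predictor = scores,
                                              direction = ">")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("a full scenario run is reproducible and keeps consistent bookkeeping", {
  fx <- small_fixture()
  r1 <- run_scenario(fx$train, fx$test, seed = 1)
  r2 <- run_scenario(fx$train, fx$test, seed = 1)
  r1$models <- r2$models <- NULL  # svm handles carry environments
  expect_identical(r1, r2)
  expect_equal(r1$counts$n_test, r1$filter_log_test$n_used)
  expect_equal(r1$counts$n_train, r1$filter_log_train$n_used)
  expect_equal(nrow(r1$predictions), r1$counts$n_test)
  expect_true(all(c("iqs", "po", "pc", "iqs_from_po_pc") %in%
                    r1$metrics$target))
  expect_true(all(r1$roc$auc_predicted_iqs >= 0 &
                    r1$roc$auc_predicted_iqs <= 1, na.rm = TRUE))
})

test_that("in-distribution evaluation beats the train-test shifted run", {
  fx <- small_fixture()
  shifted <- run_scenario(fx$train, fx$test, targets = "po", seed = 1)
  self <- run_scenario(fx$train, fx$train, targets = "po", seed = 1)
  expect_gte(self$metrics$pearson_r[1], shifted$metrics$pearson_r[1])
})
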