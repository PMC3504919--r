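COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

allele_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}

#' Pre-imputation SNP filters
#'
#' Applies the two data-preparation rules: SNPs whose reference-panel MAF is
#' below 1% (strict inequality) are removed, and SNPs whose platform alleles
#' cannot be reconciled with the panel alleles are excluded. Reconciliation
#' first compares the unordered allele pairs directly, then after strand
#' complementation; strand-ambiguous A/T and C/G SNPs (their complement is
#' themselves) are oriented by allele-frequency proximity and dropped when
#' either frequency is within 0.1 of 0.5, where orientation is not
#' decidable.
#'
#' @param snps data frame with columns `snp_id`, `maf` (platform MAF) and
#'   optionally `allele_a`, `allele_b`.
#' @param panel data frame with columns `snp_id`, `maf` and optionally
#'   `allele_a`, `allele_b` (see [panel_genotype_stats()]).
#' @param maf_min MAF threshold (default 0.01; strict `<` removal).
#' @return a list with `retained` (the filtered `snps` data frame) and
#'   `log`, a named list of per-rule counts.
#' @export
apply_snp_filters <- function(snps, panel, maf_min = 0.01) {
  snps <- as.data.frame(snps)
  panel <- as.data.frame(panel)
  m <- match(snps$snp_id, panel$snp_id)
  if (anyNA(m)) {
    stop(sum(is.na(m)), " SNP(s) missing from the reference panel, e.g. ",
         snps$snp_id[which(is.na(m))[1]])
  }
  panel_maf <- panel$maf[m]
  drop_maf <- panel_maf < maf_min

  drop_incons <- rep(FALSE, nrow(snps))
  drop_ambig <- rep(FALSE, nrow(snps))
  has_alleles <- all(c("allele_a", "allele_b") %in% names(snps)) &&
    all(c("allele_a", "allele_b") %in% names(panel))
  if (has_alleles) {
    pa <- toupper(panel$allele_a[m]); pb <- toupper(panel$allele_b[m])
    sa <- toupper(snps$allele_a);     sb <- toupper(snps$allele_b)
    same <- allele_pair_key(sa, sb) == allele_pair_key(pa, pb)
    flip <- allele_pair_key(unname(COMPLEMENT[sa]), unname(COMPLEMENT[sb])) ==
      allele_pair_key(pa, pb)
    drop_incons <- !(same | flip)
    ambiguous <- sa == unname(COMPLEMENT[sb])  # A/T or C/G pairs
    near_half <- abs(snps$maf - 0.5) < 0.1 | abs(panel_maf - 0.5) < 0.1
    drop_ambig <- !drop_incons & ambiguous & near_half
  }
  keep <- !(drop_maf | drop_incons | drop_ambig)
  list(retained = snps[keep, , drop = FALSE],
       log = list(n_input = nrow(snps),
                  n_maf_removed = sum(drop_maf),
                  n_inconsistent_removed = sum(drop_incons & !drop_maf),
                  n_ambiguous_removed = sum(drop_ambig & !drop_maf),
                  n_retained = sum(keep)))
}

#' Mask a fraction of typed SNPs for training
#'
#' Seeded uniform sample without replacement of `round(fraction * n)` SNPs
#' from the typed set; the masked SNPs play the role of "missing" genotypes
#' whose imputations, compared against the erased truth, become regression
#' training examples.
#'
#' @param typed_set vector of typed SNP identifiers or indices.
#' @param fraction fraction to mask, in `(0, 1)` (default 0.10).
#' @param seed integer seed.
#' @return a list with `kept` and `masked`, a disjoint partition of
#'   `typed_set`.
#' @export
mask_training_snps <- function(typed_set, fraction = 0.10, seed = 42) {
  n <- length(typed_set)
  if (fraction <= 0 || fraction >= 1) stop("mask fraction must lie in (0, 1)")
  if (n < 10) stop("typed set too small to mask (need >= 10 SNPs)")
  k <- round(fraction * n)
  pick <- with_local_seed(seed, sample.int(n, k))
  list(kept = typed_set[-pick], masked = typed_set[sort(pick)])
}

#' Regression error metrics
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return a list with `mse` (mean squared residual) and `pearson_r` (sample
#'   Pearson correlation; `NA` when either vector has zero variance).
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  r <- if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) NA_real_
  else stats::cor(y_true, y_pred)
  list(mse = mean((y_true - y_pred)^2), pearson_r = r)
}

#' Binary false-positive labels from true IQS
#'
#' An imputed SNP whose true IQS falls below the threshold is treated as a
#' presumed false positive that a quality filter should remove (positive
#' label). The boundary is strict: `iqs == threshold` is negative.
#'
#' @param true_iqs numeric vector of true IQS values (no `NA`).
#' @param threshold filtering threshold, conventionally 0.5 or 0.9.
#' @return logical vector, `TRUE` = should be filtered out.
#' @export
filtering_labels <- function(true_iqs, threshold) {
  if (anyNA(true_iqs)) stop("true IQS must be defined for all SNPs")
  true_iqs < threshold
}

#' ROC curve and AUC for quality-score filtering
#'
#' Ranks SNPs by predicted quality, lowest first (a lower predicted score
#' means more likely to be a false positive), sweeps a threshold over the
#' unique score values, and reports the ROC points and the trapezoidal AUC
#' (equal to the Mann-Whitney concordance statistic, with tied scores
#' contributing half).
#'
#' @param scores numeric predicted quality scores (higher = better quality).
#' @param labels logical (or 0/1) labels from [filtering_labels()];
#'   `TRUE` = positive (should be filtered).
#' @return a list with `points` (data frame `fpr`, `tpr`, one row per
#'   distinct score plus the origin) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present (positives: ", n_pos,
         ", negatives: ", n_neg, ")")
  }
  r <- -scores  # lower quality -> ranked first
  o <- order(r, decreasing = TRUE)
  r <- r[o]; lab <- labels[o]
  # group tied ranking scores
  grp <- cumsum(!duplicated(r))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' True agreement scores of a scenario
#'
#' Computes Po, Pc and IQS for every imputed SNP of a scenario by comparing
#' the stored posteriors with the study truth.
#'
#' @param scenario an [imputation_scenario()].
#' @param mode contingency mode, `"soft"` (default) or `"hard"`.
#' @return data frame `snp_id`, `po`, `pc`, `iqs` (the latter `NA` for
#'   monomorphic tables).
#' @export
scenario_scores <- function(scenario, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  ii <- scenario$imputed_idx
  out <- data.frame(snp_id = scenario$snp_ids[ii], po = NA_real_,
                    pc = NA_real_, iqs = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(ii)) {
    sc <- iqs(build_contingency(scenario$truth[, ii[k]],
                                scenario$posteriors[k, , ], mode = mode))
    out$po[k] <- sc$po; out$pc[k] <- sc$pc; out$iqs[k] <- sc$iqs
  }
  out
}

#' Feature table of a scenario
#'
#' Assembles the 12-feature descriptor for every imputed SNP of a scenario
#' (see [assemble_features()] and [iqs_feature_names()]).
#'
#' @param scenario an [imputation_scenario()].
#' @return data frame with `snp_id` plus the 12 feature columns.
#' @export
scenario_features <- function(scenario) {
  ii <- scenario$imputed_idx
  ids <- scenario$snp_ids[ii]
  ann <- scenario$annotation[match(ids, scenario$annotation$snp_id), ]
  st <- scenario$panel_stats[match(ids, scenario$panel_stats$snp_id), ]
  typed_pos <- scenario$positions[scenario$typed_idx]
  baf_col <- if ("baf" %in% names(ann)) ann$baf else rep(NA_real_, nrow(ann))
  X <- matrix(NA_real_, length(ii), 12,
              dimnames = list(ids, iqs_feature_names()))
  for (k in seq_along(ii)) {
    X[k, ] <- assemble_features(
      snp_id = ids[k], chrom = ann$chrom[k], pos = ann$pos[k],
      platform_maf = ann$maf[k],
      panel_counts = c(st$n_aa[k], st$n_ab[k], st$n_bb[k]),
      typed_positions = typed_pos, map = scenario$hotspots,
      posteriors = scenario$posteriors[k, , ],
      baf_genotypes = if (is.na(baf_col[k])) scenario$baf_genotypes[, ii[k]] else NULL,
      baf = if (is.na(baf_col[k])) NULL else baf_col[k])
  }
  data.frame(snp_id = ids, X, stringsAsFactors = FALSE, row.names = NULL)
}

#' Run a full platform-masking evaluation
#'
#' The complete experiment: filter imputed SNPs (panel MAF and allele
#' consistency), compute features and true agreement scores on both
#' scenarios, train one nu-SVR per requested target on the training
#' scenario's masked SNPs, predict on the test scenario, and report mean
#' squared error and Pearson correlation per target plus ROC/AUC
#' false-positive filtering at each true-IQS threshold. The filtering
#' comparison ranks test SNPs by (a) predicted IQS, (b) predicted imputation
#' accuracy — the Po-target model, since accuracy is equivalent to Po — and
#' (c) true Po as a reference. When both `po` and `pc` are among the
#' targets, their combination `(po - pc) / (1 - pc)` is evaluated as an
#' additional IQS estimate.
#'
#' @param train,test [imputation_scenario()] objects with disjoint typed and
#'   imputed sets.
#' @param targets regression targets to fit, subset of
#'   `c("iqs", "po", "pc")`.
#' @param nu fixed nu, or `NULL` (default) for 10-fold CV selection per
#'   target.
#' @param cost SVR penalty C.
#' @param seed seed controlling CV fold assignment.
#' @param thresholds true-IQS filtering thresholds.
#' @param mode contingency mode for the true scores.
#' @param maf_min panel MAF filter threshold.
#' @return an object of class `evaluation_report`: a list with `models`,
#'   `metrics` (data frame), `roc` (data frame of AUCs per threshold),
#'   `counts`, `filter_log_train`, `filter_log_test` and the per-SNP test
#'   `predictions` data frame.
#' @export
run_scenario <- function(train, test, targets = c("iqs", "po", "pc"),
                         nu = NULL, cost = 1, seed = 42,
                         thresholds = c(0.5, 0.9), mode = "soft",
                         maf_min = 0.01) {
  stopifnot(inherits(train, "imputation_scenario"),
            inherits(test, "imputation_scenario"))
  targets <- match.arg(targets, c("iqs", "po", "pc"), several.ok = TRUE)

  prep <- function(scenario) {
    ii <- scenario$imputed_idx
    ids <- scenario$snp_ids[ii]
    ann <- scenario$annotation[match(ids, scenario$annotation$snp_id), ]
    st <- scenario$panel_stats
    snps <- data.frame(snp_id = ids, maf = ann$maf,
                       allele_a = st$allele_a[match(ids, st$snp_id)],
                       allele_b = st$allele_b[match(ids, st$snp_id)],
                       stringsAsFactors = FALSE)
    filt <- apply_snp_filters(snps, st, maf_min = maf_min)
    keep <- scenario$snp_ids[ii] %in% filt$retained$snp_id
    feats <- scenario_features(scenario)
    scores <- scenario_scores(scenario, mode = mode)
    defined <- !is.na(scores$iqs)
    list(feats = feats[keep & defined, , drop = FALSE],
         scores = scores[keep & defined, , drop = FALSE],
         log = c(filt$log, list(n_undefined_iqs = sum(keep & !defined),
                                n_used = sum(keep & defined))))
  }
  tr <- prep(train)
  te <- prep(test)
  if (nrow(tr$feats) < 20) {
    stop("training scenario retains only ", nrow(tr$feats),
         " usable SNPs; need >= 20")
  }
  missing_feat <- te$feats$snp_id[!stats::complete.cases(te$feats)]
  if (length(missing_feat)) {
    stop("missing features for SNP(s): ", paste(missing_feat, collapse = ", "))
  }

  Xtr <- as.matrix(tr$feats[, iqs_feature_names()])
  Xte <- as.matrix(te$feats[, iqs_feature_names()])
  models <- list()
  preds <- data.frame(snp_id = te$feats$snp_id, stringsAsFactors = FALSE)
  metrics <- data.frame()
  for (tg in targets) {
    fitm <- fit_iqs_svr(Xtr, tr$scores[[tg]], target_kind = tg, nu = nu,
                        cost = cost, seed = seed)
    models[[tg]] <- fitm
    p <- predict(fitm, Xte)
    preds[[paste0("pred_", tg)]] <- p
    mm <- regression_metrics(te$scores[[tg]], p)
    metrics <- rbind(metrics,
                     data.frame(target = tg, nu = fitm$nu, mse = mm$mse,
                                pearson_r = mm$pearson_r))
  }
  if (all(c("po", "pc") %in% targets)) {
    comb <- combine_po_pc(preds$pred_po, preds$pred_pc)
    preds$pred_iqs_from_po_pc <- comb
    ok <- !is.na(comb)
    mm <- regression_metrics(te$scores$iqs[ok], comb[ok])
    metrics <- rbind(metrics,
                     data.frame(target = "iqs_from_po_pc", nu = NA_real_,
                                mse = mm$mse, pearson_r = mm$pearson_r))
  }
  preds$true_iqs <- te$scores$iqs
  preds$true_po <- te$scores$po
  preds$true_pc <- te$scores$pc

  roc <- data.frame()
  for (th in thresholds) {
    lab <- filtering_labels(te$scores$iqs, th)
    if (length(unique(lab)) < 2) {
      roc <- rbind(roc, data.frame(threshold = th, n_positive = sum(lab),
                                   auc_predicted_iqs = NA_real_,
                                   auc_predicted_accuracy = NA_real_,
                                   auc_true_accuracy = NA_real_))
      next
    }
    auc_iqs <- if ("iqs" %in% targets) roc_auc(preds$pred_iqs, lab)$auc else NA_real_
    auc_acc <- if ("po" %in% targets) roc_auc(preds$pred_po, lab)$auc else NA_real_
    auc_true <- roc_auc(te$scores$po, lab)$auc
    roc <- rbind(roc, data.frame(threshold = th, n_positive = sum(lab),
                                 auc_predicted_iqs = auc_iqs,
                                 auc_predicted_accuracy = auc_acc,
                                 auc_true_accuracy = auc_true))
  }

  structure(list(models = models, metrics = metrics, roc = roc,
                 counts = list(n_train = nrow(tr$feats), n_test = nrow(te$feats)),
                 filter_log_train = tr$log, filter_log_test = te$log,
                 predictions = preds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("Imputation-quality regression report: %d training / %d test SNPs\n",
              x$counts$n_train, x$counts$n_test))
  cat("\nRegression metrics:\n")
  print(format(x$metrics, digits = digits), row.names = FALSE)
  if (nrow(x$roc)) {
    cat("\nFalse-positive filtering (AUC):\n")
    print(format(x$roc, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the metrics, AUC table, counts and filter logs as JSON (models and
#' per-SNP predictions are omitted; save those with [write_iqs_svr()] and
#' [utils::write.table()]).
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(metrics = report$metrics, roc = report$roc,
              counts = report$counts,
              filter_log_train = report$filter_log_train,
              filter_log_test = report$filter_log_test)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
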