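#' Fit a per-feature min-max scaler
#'
#' RBF kernels are scale-sensitive: with the kernel width fixed at
#' `gamma = 1/d`, unscaled base-pair positions would dominate every other
#' predictor. Each feature is therefore mapped affinely to `[0, 1]` using
#' ranges estimated on the training data only; constant features map to 0.
#'
#' @param X numeric feature matrix (rows = SNPs).
#' @return an object of class `feature_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1 || ncol(X) < 1) stop("cannot fit a scaler on an empty matrix")
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  structure(list(min = lo, range = hi - lo, d = ncol(X),
                 feature_names = colnames(X)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @export
scale_features <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != scaler$d) {
    stop("feature matrix has ", ncol(X), " columns; scaler expects ", scaler$d)
  }
  r <- ifelse(scaler$range > 0, scaler$range, 1)
  out <- sweep(sweep(X, 2, scaler$min), 2, r, "/")
  out[, scaler$range == 0] <- 0
  out
}

#' @rdname fit_scaler
#' @export
unscale_features <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  X <- as.matrix(X)
  if (ncol(X) != scaler$d) {
    stop("feature matrix has ", ncol(X), " columns; scaler expects ", scaler$d)
  }
  sweep(sweep(X, 2, scaler$range, "*"), 2, scaler$min, "+")
}

# LibSVM cannot predict from a model with no support vectors (constant y);
# the decision function then degenerates to the bias term.
svm_predict <- function(fit, X) {
  if (fit$tot.nSV == 0) rep(-fit$rho, nrow(X))
  else unname(stats::predict(fit, X))
}

cv_folds <- function(l, k, seed) {
  idx <- with_local_seed(seed, sample.int(l))
  split(idx, rep_len(seq_len(k), l))
}

#' Select the nu parameter by cross-validation
#'
#' Grid search over `nu` in `{0.1, 0.2, ..., 1.0}` minimizing the mean
#' 10-fold cross-validated mean squared error on the training set, with the
#' RBF kernel width fixed at `gamma = 1/d`. Folds come from a seeded shuffle
#' so the selection is reproducible; ties are broken toward the smaller nu.
#'
#' @param X scaled feature matrix (`l x d`, `l >= 20`).
#' @param y regression targets.
#' @param grid candidate nu values in `(0, 1]`.
#' @param folds number of cross-validation folds (default 10).
#' @param cost the SVR penalty parameter C (default 1, the LibSVM default).
#' @param seed seed for the fold shuffle (default 42).
#' @return a list with `nu` (the selected value) and `cv_mse` (named vector
#'   of mean CV errors across the grid).
#' @export
select_nu <- function(X, y, grid = seq(0.1, 1, by = 0.1), folds = 10,
                      cost = 1, seed = 42) {
  X <- as.matrix(X)
  l <- nrow(X)
  if (length(grid) == 0) stop("nu grid must be non-empty")
  if (any(grid <= 0 | grid > 1)) stop("nu values must lie in (0, 1]")
  if (l < 20) stop("need at least 20 training rows for cross-validation, got ", l)
  if (length(y) != l) stop("X and y disagree on the number of rows")
  fold_idx <- cv_folds(l, folds, seed)
  gamma <- 1 / ncol(X)
  cv_mse <- vapply(grid, function(nu) {
    errs <- vapply(fold_idx, function(te) {
      fit <- e1071::svm(X[-te, , drop = FALSE], y[-te],
                        type = "nu-regression", kernel = "radial",
                        gamma = gamma, nu = nu, cost = cost, scale = FALSE,
                        fitted = FALSE)
      mean((y[te] - svm_predict(fit, X[te, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  names(cv_mse) <- format(grid)
  best <- grid[which.min(cv_mse)]  # which.min returns the first (smallest nu) tie
  list(nu = best, cv_mse = cv_mse)
}

#' Fit a nu-SVR imputation-quality model
#'
#' Fits a nu-support vector regression with an RBF kernel
#' (`gamma = 1/d`, `d` = number of features) predicting IQS, Po or Pc from
#' per-SNP feature vectors. Features are min-max scaled to `[0, 1]` using
#' ranges from the training data; if `nu` is `NULL` it is selected by
#' 10-fold cross-validation over `{0.1, ..., 1.0}` (see [select_nu()]).
#' The penalty C is not part of the search protocol and defaults to the
#' LibSVM default of 1. The quadratic program is solved by LibSVM via
#' \pkg{e1071}.
#'
#' @param X feature matrix, `l x 12` (raw scale; scaling is handled here).
#' @param y training targets (true IQS, Po or Pc; no missing values).
#' @param target_kind one of `"iqs"`, `"po"`, `"pc"`.
#' @param nu the nu parameter in `(0, 1]`, or `NULL` to select by CV.
#' @param cost penalty parameter C (> 0).
#' @param grid,folds,seed passed to [select_nu()] when `nu` is `NULL`.
#' @return an object of class `iqs_svr`.
#' @export
fit_iqs_svr <- function(X, y, target_kind = c("iqs", "po", "pc"), nu = NULL,
                        cost = 1, grid = seq(0.1, 1, by = 0.1), folds = 10,
                        seed = 42) {
  target_kind <- match.arg(target_kind)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) {
    stop("training data contain missing values; exclude undefined-IQS SNPs upstream")
  }
  if (length(y) != nrow(X)) stop("X and y disagree on the number of rows")
  if (cost <= 0) stop("cost must be positive")
  scaler <- fit_scaler(X)
  Xs <- scale_features(scaler, X)
  cv <- NULL
  if (is.null(nu)) {
    cv <- select_nu(Xs, y, grid = grid, folds = folds, cost = cost, seed = seed)
    nu <- cv$nu
  }
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  gamma <- 1 / ncol(Xs)
  fit <- e1071::svm(Xs, y, type = "nu-regression", kernel = "radial",
                    gamma = gamma, nu = nu, cost = cost, scale = FALSE,
                    fitted = FALSE)
  structure(list(target_kind = target_kind, nu = nu, cost = cost,
                 gamma = gamma, scaler = scaler, cv = cv,
                 sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
                 n_train = nrow(Xs), svm = fit),
            class = "iqs_svr")
}

#' @export
print.iqs_svr <- function(x, ...) {
  cat(sprintf(
    "nu-SVR imputation-quality model (target = %s)\n  nu = %g, C = %g, gamma = %g, %d support vectors / %d training SNPs\n",
    toupper(x$target_kind), x$nu, x$cost, x$gamma, nrow(x$sv), x$n_train))
  invisible(x)
}

rbf_decision <- function(model, Xs) {
  d2 <- outer(rowSums(Xs^2), rowSums(model$sv^2), "+") -
    2 * tcrossprod(Xs, model$sv)
  d2[d2 < 0] <- 0
  drop(exp(-model$gamma * d2) %*% model$coefs) - model$rho
}

#' Predict imputation quality for new SNPs
#'
#' Applies a fitted [fit_iqs_svr()] model. Features are transformed with the
#' training scaler; outputs are the raw regression values and are not
#' clipped to `[0, 1]` (kappa can legitimately be negative; clip for display
#' only).
#'
#' @param object an `iqs_svr` model.
#' @param newdata feature matrix with the model's feature dimension.
#' @param ... unused.
#' @return numeric vector of predicted targets.
#' @export
predict.iqs_svr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$scaler$d) {
    stop("newdata has ", ncol(X), " columns; model expects ", object$scaler$d)
  }
  Xs <- scale_features(object$scaler, X)
  if (!is.null(object$svm)) svm_predict(object$svm, Xs)
  else rbf_decision(object, Xs)
}

#' Margin diagnostics of a fitted nu-SVR
#'
#' In the nu formulation the tube width epsilon is optimized rather than
#' fixed, and nu lower-bounds the support-vector fraction while
#' upper-bounding the margin-error fraction (training points outside the
#' tube). The tube width is recovered from the free support vectors (those
#' with dual coefficients strictly inside the box), which lie exactly on the
#' tube boundary.
#'
#' @param model an `iqs_svr` model.
#' @param X,y the training data the model was fitted on.
#' @return a list with `sv_fraction`, `epsilon` and `margin_error_fraction`.
#' @export
svr_margin_diagnostics <- function(model, X, y) {
  stopifnot(inherits(model, "iqs_svr"))
  if (is.null(model$svm)) {
    stop("margin diagnostics require a freshly fitted model (support-vector ",
         "indices are not serialized)")
  }
  res <- y - predict(model, X)
  bound <- max(abs(model$coefs))
  free <- abs(model$coefs) < bound * (1 - 1e-8)
  sv_res <- res[model$svm$index]
  eps <- if (any(free)) stats::median(abs(sv_res[free])) else 0
  list(sv_fraction = nrow(model$sv) / length(y),
       epsilon = eps,
       margin_error_fraction = mean(abs(res) > eps + 1e-6))
}

#' Combine predicted Po and Pc into a predicted IQS
#'
#' Applies the kappa arithmetic `(po - pc) / (1 - pc)` to separately
#' regressed components. Entries where the predicted chance agreement
#' reaches 1 (within `1e-6`) are undefined and returned as `NA`.
#'
#' @param po_hat,pc_hat numeric vectors of predicted observed and chance
#'   agreement.
#' @return numeric vector of combined IQS estimates.
#' @export
combine_po_pc <- function(po_hat, pc_hat) {
  if (length(po_hat) != length(pc_hat)) stop("po_hat and pc_hat lengths differ")
  out <- (po_hat - pc_hat) / (1 - pc_hat)
  out[pc_hat >= 1 - 1e-6] <- NA_real_
  out
}

#' Save / load a fitted model
#'
#' Serializes an [fit_iqs_svr()] model to a single JSON file holding the
#' scaler, hyperparameters and support-vector expansion at full double
#' precision; `read_iqs_svr()` restores a model whose predictions reproduce
#' the original through the explicit RBF kernel expansion.
#'
#' @param model an `iqs_svr` model.
#' @param path output file path.
#' @export
write_iqs_svr <- function(model, path) {
  stopifnot(inherits(model, "iqs_svr"))
  obj <- list(
    format = "iqsreg-nu-svr", version = 1L,
    target_kind = model$target_kind, nu = model$nu, cost = model$cost,
    gamma = model$gamma, n_train = model$n_train, rho = model$rho,
    coefs = model$coefs, sv = model$sv,
    scaler = list(min = unname(model$scaler$min),
                  range = unname(model$scaler$range), d = model$scaler$d,
                  feature_names = model$scaler$feature_names))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       always_decimal = TRUE)
  invisible(path)
}

#' @rdname write_iqs_svr
#' @export
read_iqs_svr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "iqsreg-nu-svr")) {
    stop("file ", path, " is not a serialized iqsreg nu-SVR model")
  }
  scaler <- structure(list(min = as.numeric(obj$scaler$min),
                           range = as.numeric(obj$scaler$range),
                           d = as.integer(obj$scaler$d),
                           feature_names = obj$scaler$feature_names),
                      class = "feature_scaler")
  structure(list(target_kind = obj$target_kind, nu = obj$nu, cost = obj$cost,
                 gamma = obj$gamma, scaler = scaler, cv = NULL,
                 sv = matrix(as.numeric(obj$sv), nrow = nrow(obj$sv)),
                 coefs = as.numeric(obj$coefs), rho = as.numeric(obj$rho),
                 n_train = obj$n_train, svm = NULL),
            class = "iqs_svr")
}
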