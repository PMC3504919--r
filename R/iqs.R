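GENO_LEVELS <- c("AA", "AB", "BB")

#' Convert genotype calls to B-allele counts
#'
#' Accepts genotype calls either as character labels (`"AA"`, `"AB"`, `"BB"`,
#' with `NA`, `""`, `"NA"`, `"--"` or `"MISSING"` treated as missing) or as
#' numeric B-allele counts in `{0, 1, 2}`, and returns integer B-allele
#' counts (`0` = AA, `1` = AB, `2` = BB, `NA` = missing).
#'
#' @param g character or numeric vector of genotype calls.
#' @return integer vector of B-allele counts with `NA` for missing calls.
#' @examples
#' genotype_b_counts(c("AA", "AB", "BB", NA))
#' @export
genotype_b_counts <- function(g) {
  if (is.numeric(g)) {
    bad <- !is.na(g) & !g %in% c(0, 1, 2)
    if (any(bad)) {
      stop("numeric genotypes must be B-allele counts in {0, 1, 2}; got: ",
           paste(unique(g[bad]), collapse = ", "))
    }
    return(as.integer(g))
  }
  g <- toupper(as.character(g))
  g[g %in% c("", "NA", "--", "MISSING", "NN")] <- NA_character_
  g[g == "BA"] <- "AB"
  bad <- !is.na(g) & !g %in% GENO_LEVELS
  if (any(bad)) {
    stop("unrecognized genotype call(s): ", paste(unique(g[bad]), collapse = ", "))
  }
  out <- match(g, GENO_LEVELS) - 1L
  out
}

#' Convert B-allele counts to genotype labels
#'
#' @param b integer vector of B-allele counts (0/1/2, `NA` allowed).
#' @return character vector of `"AA"`/`"AB"`/`"BB"` with `NA` preserved.
#' @export
genotype_labels <- function(b) {
  GENO_LEVELS[genotype_b_counts(b) + 1L]
}

#' Validate and normalize posterior genotype probabilities
#'
#' Coerces posterior genotype probabilities to an `n x 3` numeric matrix with
#' columns `AA`, `AB`, `BB`. Each row must be nonnegative and sum to 1 within
#' `tol`; rows are renormalized to sum exactly to 1.
#'
#' @param p numeric matrix (or coercible) with 3 columns, one row per
#'   individual, or a numeric vector of length 3 for a single individual.
#' @param tol permitted deviation of each row sum from 1 before the row is
#'   rejected (default `1e-6`).
#' @return numeric matrix with columns `AA`, `AB`, `BB`, rows summing to 1.
#' @examples
#' as_posterior_matrix(c(0.6, 0.3, 0.1))
#' @export
as_posterior_matrix <- function(p, tol = 1e-6) {
  if (is.null(dim(p))) {
    if (length(p) %% 3L != 0L) stop("posterior vector length must be a multiple of 3")
    p <- matrix(as.numeric(p), ncol = 3L, byrow = TRUE)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("posterior matrix must have 3 columns (AA, AB, BB)")
  storage.mode(p) <- "double"
  if (anyNA(p)) stop("posterior probabilities must not be missing")
  if (any(p < -tol)) stop("posterior probabilities must be nonnegative")
  p[p < 0] <- 0
  s <- rowSums(p)
  off <- abs(s - 1) > tol
  if (any(off)) {
    stop(sprintf("posterior row(s) %s do not sum to 1 within %g",
                 paste(utils::head(which(off), 5L), collapse = ", "), tol))
  }
  p <- p / s
  colnames(p) <- GENO_LEVELS
  p
}

#' Cross-classify imputed versus true genotypes
#'
#' Builds the 3x3 contingency table whose cell `(i, j)` holds the mass of
#' individuals with imputed genotype `i` and true genotype `j`. In `"soft"`
#' mode each individual contributes its posterior probability vector to the
#' column of its true genotype, so cells may be fractional; in `"hard"` mode
#' each individual contributes a single count to the row of its
#' maximum-posterior genotype (ties broken in the order AA, AB, BB).
#' Individuals with missing truth are skipped in both modes, so the table
#' total equals the number of informative individuals.
#'
#' @param truth genotype calls (see [genotype_b_counts()]), one per individual.
#' @param posteriors posterior probabilities, one row per individual (see
#'   [as_posterior_matrix()]).
#' @param mode `"soft"` (default) or `"hard"`.
#' @param tol row-sum tolerance passed to [as_posterior_matrix()].
#' @return an object of class `iqs_table`: a 3x3 matrix with `dimnames`
#'   `imputed` x `true`.
#' @examples
#' tab <- build_contingency(c("AA", "AB"),
#'                          rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3)))
#' iqs(tab)
#' @export
build_contingency <- function(truth, posteriors, mode = c("soft", "hard"),
                              tol = 1e-6) {
  mode <- match.arg(mode)
  b <- genotype_b_counts(truth)
  p <- as_posterior_matrix(posteriors, tol = tol)
  if (length(b) != nrow(p)) {
    stop("truth (", length(b), ") and posteriors (", nrow(p),
         ") must describe the same individuals")
  }
  keep <- !is.na(b)
  if (!any(keep)) stop("no informative individuals (all truth genotypes missing)")
  b <- b[keep]
  p <- p[keep, , drop = FALSE]
  if (mode == "hard") {
    # max.col with ties.method = "first" resolves ties in the order AA < AB < BB
    imp <- max.col(p, ties.method = "first")
    p <- matrix(0, nrow(p), 3L)
    p[cbind(seq_along(imp), imp)] <- 1
  }
  ind <- matrix(0, length(b), 3L)
  ind[cbind(seq_along(b), b + 1L)] <- 1
  n <- crossprod(p, ind)  # rows: imputed genotype, cols: true genotype
  dimnames(n) <- list(imputed = GENO_LEVELS, true = GENO_LEVELS)
  structure(n, class = c("iqs_table", class(n)))
}

as_iqs_table <- function(x) {
  if (inherits(x, "iqs_table")) return(x)
  x <- as.matrix(x)
  if (!all(dim(x) == c(3L, 3L))) stop("a contingency table must be 3x3")
  if (any(x < 0)) stop("contingency cells must be nonnegative")
  dimnames(x) <- list(imputed = GENO_LEVELS, true = GENO_LEVELS)
  structure(x, class = c("iqs_table", class(x)))
}

#' @export
print.iqs_table <- function(x, ...) {
  cat("Imputed-vs-true genotype cross-classification (n = ",
      format(sum(x)), " individuals)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Observed agreement of an imputation contingency table
#'
#' The proportion of (posterior-weighted) individuals whose imputed genotype
#' agrees with the true genotype: the diagonal mass over the table total.
#' This is the quantity usually reported as "imputation accuracy".
#'
#' @param table a 3x3 contingency table (see [build_contingency()]).
#' @return the observed agreement, a proportion in `[0, 1]`.
#' @export
observed_agreement <- function(table) {
  n <- as_iqs_table(table)
  tot <- sum(n)
  if (tot <= 0) stop("contingency table is empty (no informative individuals)")
  sum(diag(n)) / tot
}

#' Chance agreement of an imputation contingency table
#'
#' The agreement expected if imputed and true genotypes were independent with
#' the observed margins: `sum_i n_i. * n_.i / n_..^2`.
#'
#' @inheritParams observed_agreement
#' @return the chance agreement, a proportion in `[0, 1]`.
#' @export
chance_agreement <- function(table) {
  n <- as_iqs_table(table)
  tot <- sum(n)
  if (tot <= 0) stop("contingency table is empty (no informative individuals)")
  sum(rowSums(n) * colSums(n)) / tot^2
}

#' Imputation quality score (Cohen's kappa)
#'
#' Computes the observed agreement Po, the chance agreement Pc, and the
#' imputation quality score IQS = (Po - Pc) / (1 - Pc), i.e. Cohen's kappa of
#' the imputed-vs-true cross-classification. When the chance agreement is 1
#' (a monomorphic table: all margin mass in one genotype) kappa is undefined
#' and the score is returned as `NA`; such SNPs should be excluded from
#' regression training and evaluation.
#'
#' @inheritParams observed_agreement
#' @return an object of class `agreement_scores`: a list with elements `po`,
#'   `pc` and `iqs` (the latter `NA` when undefined).
#' @examples
#' tab <- matrix(c(4, 0, 0, 1, 3, 0, 0, 0, 2), 3, 3)
#' iqs(tab)  # po = 0.9, pc = 0.36, iqs = 0.84375
#' @export
iqs <- function(table) {
  po <- observed_agreement(table)
  pc <- chance_agreement(table)
  score <- if (pc >= 1 - 1e-12) NA_real_ else (po - pc) / (1 - pc)
  structure(list(po = po, pc = pc, iqs = score), class = "agreement_scores")
}

#' @export
print.agreement_scores <- function(x, digits = 4, ...) {
  cat(sprintf("Po = %s, Pc = %s, IQS = %s\n",
              format(x$po, digits = digits), format(x$pc, digits = digits),
              if (is.na(x$iqs)) "undefined (Pc = 1)" else format(x$iqs, digits = digits)))
  invisible(x)
}

#' Imputation quality score from raw calls
#'
#' Convenience wrapper combining [build_contingency()] and [iqs()].
#'
#' @inheritParams build_contingency
#' @return an `agreement_scores` object.
#' @export
iqs_score <- function(truth, posteriors, mode = c("soft", "hard")) {
  iqs(build_contingency(truth, posteriors, mode = mode))
}
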