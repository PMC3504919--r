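#' Names and order of the 12 per-SNP predictors
#'
#' The feature vector layout is frozen: models are only portable across data
#' sets because every producer and consumer agrees on this order.
#'
#' @return character vector of length 12.
#' @export
iqs_feature_names <- function() {
  c("chrom_code", "pos_bp", "platform_maf", "mean_baf", "panel_maf",
    "ratio_aa_ab", "ratio_bb_ab", "dist_nearest_typed_bp",
    "dist_nearest_hotspot_bp", "hotspot_rate_cM_per_Mb",
    "mean_posterior", "mean_b_dosage")
}

#' Reference-panel genotype ratios
#'
#' Ratios of homozygote to heterozygote genotype counts in the reference
#' panel, `(n_AA + s)/(n_AB + s)` and `(n_BB + s)/(n_AB + s)`. The additive
#' pseudocount `s` (default 1) keeps the ratios finite when no heterozygotes
#' were observed, while preserving the ordering of informative counts.
#'
#' @param n_aa,n_ab,n_bb nonnegative genotype counts (vectorized).
#' @param pseudocount additive smoothing constant `s >= 0`.
#' @return a list with numeric elements `ratio_aa_ab` and `ratio_bb_ab`.
#' @examples
#' panel_ratios(40, 20, 10)  # (41/21, 11/21)
#' @export
panel_ratios <- function(n_aa, n_ab, n_bb, pseudocount = 1) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(n_ab == 0)) {
    stop("AB count is zero; use a positive pseudocount")
  }
  list(ratio_aa_ab = (n_aa + pseudocount) / (n_ab + pseudocount),
       ratio_bb_ab = (n_bb + pseudocount) / (n_ab + pseudocount))
}

#' Distance to the nearest typed SNP
#'
#' For each query position, the distance in bp to the nearest position in a
#' set of typed (genotyped) SNPs on the same chromosome. Uses a binary
#' search over the sorted typed positions.
#'
#' @param pos numeric vector of query positions (bp).
#' @param typed_positions numeric vector of typed SNP positions (bp); sorted
#'   internally if needed.
#' @return numeric vector of distances (bp), same length as `pos`.
#' @examples
#' nearest_typed_distance(150, c(100, 200))  # 50
#' @export
nearest_typed_distance <- function(pos, typed_positions) {
  if (length(typed_positions) == 0) stop("typed_positions must be non-empty")
  tp <- sort(as.numeric(typed_positions))
  i <- findInterval(pos, tp)
  left <- ifelse(i >= 1, tp[pmax(i, 1L)], Inf)
  right <- ifelse(i < length(tp), tp[pmin(i + 1L, length(tp))], Inf)
  pmin(abs(pos - left), abs(right - pos))
}

#' Nearest recombination hotspot
#'
#' For each query position, locates the hotspot on the given chromosome that
#' minimizes the distance to the query; ties are broken toward the lower
#' hotspot position. Returns the distance (bp) and the hotspot's
#' recombination rate (cM/Mb).
#'
#' @param pos numeric vector of query positions (bp).
#' @param map a [hotspot_map()] object (or a data frame with columns `chrom`,
#'   `pos`, `rate`).
#' @param chrom chromosome code of the queries.
#' @return a list with numeric elements `distance_bp` and `rate_cM_per_Mb`.
#' @examples
#' hs <- hotspot_map(chrom = c(1, 1), pos = c(400, 700), rate = c(12, 3))
#' nearest_hotspot(500, hs, chrom = 1)
#' @export
nearest_hotspot <- function(pos, map, chrom) {
  map <- as_hotspot_map(map)
  h <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(h) == 0) stop("no recombination hotspot on chromosome ", chrom)
  hp <- h$pos
  i <- findInterval(pos, hp)
  li <- pmax(i, 1L)
  ri <- pmin(i + 1L, length(hp))
  dl <- ifelse(i >= 1, abs(pos - hp[li]), Inf)
  dr <- ifelse(i < length(hp), abs(hp[ri] - pos), Inf)
  use_left <- dl <= dr  # tie -> lower position
  idx <- ifelse(use_left, li, ri)
  list(distance_bp = pmin(dl, dr), rate_cM_per_Mb = h$rate[idx])
}

#' Mean best-guess posterior probability
#'
#' The mean, over individuals, of the maximum posterior genotype probability:
#' the imputation program's average confidence in its best-guess genotype.
#' Bounded between 1/3 (uninformative posteriors) and 1.
#'
#' @inheritParams as_posterior_matrix
#' @return a single number in `[1/3, 1]`.
#' @export
mean_posterior <- function(p, tol = 1e-6) {
  p <- as_posterior_matrix(p, tol = tol)
  if (nrow(p) == 0) stop("no posterior rows")
  mean(pmax(p[, 1], p[, 2], p[, 3]))
}

#' Mean B-allele dosage
#'
#' The mean, over individuals, of the expected B-allele count
#' `0*P(AA) + 1*P(AB) + 2*P(BB)` implied by the posterior probabilities.
#'
#' @inheritParams as_posterior_matrix
#' @return a single number in `[0, 2]`.
#' @examples
#' mean_b_dosage(c(0.2, 0.5, 0.3))  # 1.1
#' @export
mean_b_dosage <- function(p, tol = 1e-6) {
  p <- as_posterior_matrix(p, tol = tol)
  if (nrow(p) == 0) stop("no posterior rows")
  mean(p[, 2] + 2 * p[, 3])
}

#' Mean B-allele frequency from genotype calls
#'
#' The mean fraction of B alleles across individuals with non-missing calls,
#' `mean(b_count) / 2`. This genotype-derived BAF stands in for the
#' intensity-derived quantity when raw array signal files are not used; a
#' pre-computed per-SNP BAF may be supplied downstream to override it.
#'
#' @param genotypes genotype calls (see [genotype_b_counts()]).
#' @return a single number in `[0, 1]`.
#' @export
mean_baf <- function(genotypes) {
  b <- genotype_b_counts(genotypes)
  b <- b[!is.na(b)]
  if (length(b) == 0) stop("all genotype calls are missing")
  mean(b) / 2
}

#' Assemble the 12-feature descriptor of one imputed SNP
#'
#' Combines the annotation, reference-panel, distance and posterior summary
#' features into the fixed 12-element vector used by the regression model
#' (order given by [iqs_feature_names()]). Errors raised by any component are
#' annotated with the SNP id.
#'
#' @param snp_id SNP identifier (used in error messages).
#' @param chrom chromosome code (1-22).
#' @param pos physical position in bp (1-based).
#' @param platform_maf minor allele frequency from the platform annotation.
#' @param panel_counts numeric vector `c(n_aa, n_ab, n_bb)` of reference-panel
#'   genotype counts for the SNP.
#' @param typed_positions positions (bp) of typed SNPs on `chrom`.
#' @param map a [hotspot_map()].
#' @param posteriors posterior probabilities for the SNP, one row per
#'   individual of the inference panel.
#' @param baf_genotypes genotype calls used to derive the B-allele frequency
#'   (an ethnic-matched sample), or `NULL` if `baf` is given directly.
#' @param baf optional pre-computed B-allele frequency overriding
#'   `baf_genotypes`.
#' @param pseudocount smoothing constant for [panel_ratios()].
#' @return named numeric vector of length 12.
#' @export
assemble_features <- function(snp_id, chrom, pos, platform_maf, panel_counts,
                              typed_positions, map, posteriors,
                              baf_genotypes = NULL, baf = NULL,
                              pseudocount = 1) {
  tryCatch({
    stopifnot(length(panel_counts) == 3)
    rr <- panel_ratios(panel_counts[1], panel_counts[2], panel_counts[3],
                       pseudocount = pseudocount)
    n2 <- 2 * sum(panel_counts)
    pmaf <- if (n2 > 0) {
      fb <- (panel_counts[2] + 2 * panel_counts[3]) / n2
      min(fb, 1 - fb)
    } else NA_real_
    if (is.null(baf)) baf <- mean_baf(baf_genotypes)
    hs <- nearest_hotspot(pos, map, chrom)
    v <- c(chrom, pos, platform_maf, baf, pmaf,
           rr$ratio_aa_ab, rr$ratio_bb_ab,
           nearest_typed_distance(pos, typed_positions),
           hs$distance_bp, hs$rate_cM_per_Mb,
           mean_posterior(posteriors), mean_b_dosage(posteriors))
    names(v) <- iqs_feature_names()
    v
  }, error = function(e) {
    stop("feature assembly failed for SNP ", snp_id, ": ",
         conditionMessage(e), call. = FALSE)
  })
}
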