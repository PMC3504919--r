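#' Parameters of the synthetic imputation scenario generator
#'
#' Bundles and validates every knob of the generator. The defaults define
#' the reference conditions used throughout the package's evaluation: a
#' 10 Mb chromosome carrying 4,000 SNPs, a reference panel of 200 haplotypes
#' built as mosaics of 20 founder haplotypes, 300 study individuals, 40
#' recombination hotspots concentrating crossovers, an old platform covering
#' half the SNPs, a 10% training mask, and a surrogate imputer whose
#' fidelity decays with distance to the nearest typed SNP (scale 50 kb) and
#' is penalized when a hotspot separates the imputed SNP from its nearest
#' typed neighbour.
#'
#' @param K number of founder haplotypes.
#' @param H number of reference-panel haplotypes (mosaics of the founders).
#' @param N number of study individuals.
#' @param M number of SNPs on the chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_hotspots number of recombination hotspots.
#' @param hotspot_rate_shape,hotspot_rate_mean shape and mean (cM/Mb) of the
#'   gamma distribution hotspot rates are drawn from.
#' @param p_bg background per-interval founder-switch probability of the
#'   mosaic process.
#' @param hotspot_odds multiplicative odds applied to `p_bg` in intervals
#'   containing a hotspot.
#' @param old_platform_fraction fraction of SNPs covered by the old
#'   (typed) platform.
#' @param platform_block_bp block length (bp) of the old platform's uneven
#'   coverage: each block draws its own inclusion weight, producing the
#'   dense regions and gaps real arrays show, and hence a wide range of
#'   distances to the nearest typed SNP.
#' @param mask_fraction fraction of typed SNPs erased to build the training
#'   set.
#' @param w number of nearest typed SNPs the surrogate imputer conditions on.
#' @param lambda_bp fidelity decay scale of the imputer (bp).
#' @param hotspot_penalty multiplier in `(0, 1]` applied to the imputer
#'   fidelity when a hotspot lies between an imputed SNP and its nearest
#'   typed SNP.
#' @param maf_min lower truncation of the founder allele-frequency spectrum.
#' @param chrom chromosome code assigned to the simulated chromosome.
#' @param seed integer seed; every downstream draw is a deterministic
#'   function of it.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(K = 20, H = 200, N = 300, M = 4000,
                       chrom_length_bp = 10e6, n_hotspots = 40,
                       hotspot_rate_shape = 2, hotspot_rate_mean = 15,
                       p_bg = 0.01, hotspot_odds = 50,
                       old_platform_fraction = 0.5, mask_fraction = 0.1,
                       platform_block_bp = 2.5e5,
                       w = 8, lambda_bp = 5e4, hotspot_penalty = 0.6,
                       maf_min = 0.01, chrom = 1L, seed = 7) {
  p <- list(K = K, H = H, N = N, M = M, chrom_length_bp = chrom_length_bp,
            n_hotspots = n_hotspots, hotspot_rate_shape = hotspot_rate_shape,
            hotspot_rate_mean = hotspot_rate_mean, p_bg = p_bg,
            hotspot_odds = hotspot_odds,
            old_platform_fraction = old_platform_fraction,
            mask_fraction = mask_fraction, platform_block_bp = platform_block_bp,
            w = w, lambda_bp = lambda_bp,
            hotspot_penalty = hotspot_penalty, maf_min = maf_min,
            chrom = as.integer(chrom), seed = seed)
  counts <- c("K", "H", "N", "M", "n_hotspots", "w")
  for (nm in counts) if (p[[nm]] < 1) stop(nm, " must be >= 1")
  for (nm in c("old_platform_fraction", "mask_fraction")) {
    if (p[[nm]] <= 0 || p[[nm]] >= 1) stop(nm, " must lie in (0, 1)")
  }
  if (p$lambda_bp <= 0) stop("lambda_bp must be positive")
  if (p$platform_block_bp <= 0) stop("platform_block_bp must be positive")
  if (p$p_bg <= 0 || p$p_bg > 0.5) stop("p_bg must lie in (0, 0.5]")
  if (p$hotspot_odds <= 0) stop("hotspot_odds must be positive")
  if (p$hotspot_penalty <= 0 || p$hotspot_penalty > 1) {
    stop("hotspot_penalty must lie in (0, 1]")
  }
  if (p$H %% 2 != 0) stop("H must be even (panel haplotypes pair into genotypes)")
  class(p) <- "sim_params"
  p
}

# Mosaic haplotypes over a pool of source haplotypes: per interval, switch
# source with probability p_switch[j]; segments take independently drawn
# source indices.
mosaic_haplotypes <- function(sources, n_out, p_switch) {
  M <- ncol(sources)
  K <- nrow(sources)
  out <- matrix(0L, n_out, M)
  switch_totals <- integer(M - 1)
  for (h in seq_len(n_out)) {
    switches <- stats::rbinom(M - 1, 1L, p_switch)
    switch_totals <- switch_totals + switches
    seg <- c(1L, 1L + cumsum(switches))
    src <- sample.int(K, max(seg), replace = TRUE)
    out[h, ] <- sources[cbind(src[seg], seq_len(M))]
  }
  attr(out, "switch_totals") <- switch_totals
  out
}

interval_switch_probs <- function(positions, hotspot_pos, p_bg, odds) {
  M <- length(positions)
  # interval j spans (positions[j], positions[j+1])
  hot <- findInterval(hotspot_pos, positions)
  hot <- hot[hot >= 1 & hot < M]
  p <- rep(p_bg, M - 1)
  p[unique(hot)] <- pmin(0.5, p_bg * odds)
  p
}

#' Generate a haplotype reference panel
#'
#' Draws per-SNP B-allele frequencies from a Beta(0.5, 0.5) spectrum
#' truncated to MAF >= `maf_min`, builds `K` founder haplotypes site-wise
#' from those frequencies, and derives `H` panel haplotypes as founder
#' mosaics whose per-interval switch probability is `p_bg`, multiplied by
#' `hotspot_odds` in intervals containing a recombination hotspot. Hotspot
#' positions are uniform over the chromosome with gamma-distributed rates.
#' Fully deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `haplotype_panel`: a list with the binary
#'   `haplotypes` matrix (`H x M`), `positions`, `snp_ids`, `allele_a`,
#'   `allele_b`, the generating `founder_freq`, a [hotspot_map()] in
#'   `hotspots`, and the chromosome code.
#' @export
generate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    M <- params$M
    positions <- sort(sample.int(params$chrom_length_bp, M))
    hs_pos <- sort(sample.int(params$chrom_length_bp, params$n_hotspots))
    hs_rate <- stats::rgamma(params$n_hotspots, shape = params$hotspot_rate_shape,
                             scale = params$hotspot_rate_mean / params$hotspot_rate_shape)
    hotspots <- hotspot_map(chrom = rep(params$chrom, params$n_hotspots),
                            pos = hs_pos, rate = hs_rate)
    # truncated Beta(0.5, 0.5) allele-frequency spectrum
    freq <- stats::rbeta(M, 0.5, 0.5)
    for (it in 1:100) {
      low <- pmin(freq, 1 - freq) < params$maf_min
      if (!any(low)) break
      freq[low] <- stats::rbeta(sum(low), 0.5, 0.5)
    }
    founders <- matrix(stats::rbinom(params$K * M, 1L, rep(freq, each = params$K)),
                       params$K, M)
    p_switch <- interval_switch_probs(positions, hotspots$pos,
                                      params$p_bg, params$hotspot_odds)
    haplotypes <- mosaic_haplotypes(founders, params$H, p_switch)
    switch_counts <- attr(haplotypes, "switch_totals")
    attr(haplotypes, "switch_totals") <- NULL
    nt <- c("A", "C", "G", "T")
    allele_a <- sample(nt, M, replace = TRUE)
    allele_b <- vapply(allele_a, function(a) sample(setdiff(nt, a), 1),
                       character(1))
    structure(list(haplotypes = haplotypes, positions = positions,
                   snp_ids = sprintf("snp%05d", seq_len(M)),
                   allele_a = unname(allele_a), allele_b = unname(allele_b),
                   founder_freq = freq, hotspots = hotspots,
                   chrom = params$chrom, p_switch = p_switch,
                   switch_counts = switch_counts, params = params),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype reference panel: %d haplotypes x %d SNPs on chromosome %d (%.1f Mb), %d hotspots\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$chrom,
              max(x$positions) / 1e6, nrow(x$hotspots)))
  invisible(x)
}

#' Per-SNP genotype counts of the reference panel
#'
#' Pairs consecutive panel haplotypes into `H/2` reference individuals and
#' counts AA/AB/BB genotypes per SNP; also reports the panel MAF.
#'
#' @param panel a [generate_panel()] result.
#' @return data frame `snp_id`, `n_aa`, `n_ab`, `n_bb`, `maf`, `allele_a`,
#'   `allele_b`.
#' @export
panel_genotype_stats <- function(panel) {
  hap <- panel$haplotypes
  g <- hap[seq(1, nrow(hap), by = 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), by = 2), , drop = FALSE]
  n_aa <- colSums(g == 0L)
  n_ab <- colSums(g == 1L)
  n_bb <- colSums(g == 2L)
  fb <- colMeans(hap)
  data.frame(snp_id = panel$snp_ids, n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
             maf = pmin(fb, 1 - fb), allele_a = panel$allele_a,
             allele_b = panel$allele_b, stringsAsFactors = FALSE)
}

#' Sample study genotypes from the panel
#'
#' Each study individual is the sum of two mosaic haplotypes drawn over the
#' panel haplotypes with the panel's interval switch probabilities, so study
#' chromosomes share the panel's linkage-disequilibrium structure without
#' duplicating panel haplotypes.
#'
#' @param panel a [generate_panel()] result.
#' @param N number of individuals.
#' @param seed integer seed.
#' @return integer matrix `N x M` of B-allele counts (0/1/2).
#' @export
sample_study <- function(panel, N, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel$haplotypes) < 2) stop("panel must hold at least 2 haplotypes")
  with_local_seed(seed, {
    h1 <- mosaic_haplotypes(panel$haplotypes, N, panel$p_switch)
    h2 <- mosaic_haplotypes(panel$haplotypes, N, panel$p_switch)
    g <- h1 + h2
    attr(g, "switch_totals") <- NULL
    g
  })
}

# For one masked SNP: posterior genotype distribution per individual from
# panel haplotype pairs consistent with the individual's genotypes at the w
# nearest typed SNPs, blended with the panel Hardy-Weinberg distribution.
impute_one_snp <- function(truth, panel, typed_idx, s, params) {
  pos <- panel$positions
  hap <- panel$haplotypes
  N <- nrow(truth)
  dists <- abs(pos[typed_idx] - pos[s])
  w <- min(params$w, length(typed_idx))
  flank <- typed_idx[order(dists, pos[typed_idx])[seq_len(w)]]
  D <- min(dists)
  nearest <- typed_idx[which.min(dists)]
  lo <- min(pos[s], pos[nearest]); hi <- max(pos[s], pos[nearest])
  hot_between <- any(panel$hotspots$pos > lo & panel$hotspots$pos < hi &
                       panel$hotspots$chrom == panel$chrom)
  alpha <- exp(-D / params$lambda_bp) *
    (if (hot_between) params$hotspot_penalty else 1)

  fb <- mean(hap[, s])
  hw <- c((1 - fb)^2, 2 * fb * (1 - fb), fb^2)

  # group panel haplotypes by (flank pattern, masked allele)
  W <- hap[, flank, drop = FALSE]
  a <- hap[, s]
  key <- drop(W %*% 2^(seq_len(w) - 1)) * 2 + a
  uq <- unique(key)
  gi <- match(key, uq)
  cnt <- tabulate(gi, nbins = length(uq))
  first <- match(uq, key)
  U <- W[first, , drop = FALSE]
  au <- a[first]
  G <- length(uq)
  iu <- rep(seq_len(G), each = G)
  iv <- rep(seq_len(G), times = G)
  psum_key <- drop((U[iu, , drop = FALSE] + U[iv, , drop = FALSE]) %*%
                     3^(seq_len(w) - 1))
  pm <- au[iu] + au[iv]
  wp <- as.numeric(cnt[iu]) * cnt[iv]
  agg_key <- psum_key * 3 + pm
  agg <- rowsum(wp, agg_key)          # mass per (flank genotype, masked genotype)
  agg_lookup <- stats::setNames(agg[, 1], rownames(agg))

  gkey <- drop(truth[, flank, drop = FALSE] %*% 3^(seq_len(w) - 1))
  m0 <- agg_lookup[as.character(gkey * 3 + 0)]
  m1 <- agg_lookup[as.character(gkey * 3 + 1)]
  m2 <- agg_lookup[as.character(gkey * 3 + 2)]
  q <- cbind(ifelse(is.na(m0), 0, m0), ifelse(is.na(m1), 0, m1),
             ifelse(is.na(m2), 0, m2))
  tot <- rowSums(q)
  nomatch <- tot <= 0
  q[nomatch, ] <- rep(hw, each = sum(nomatch))
  tot[nomatch] <- 1
  q <- q / tot
  post <- alpha * q + (1 - alpha) * matrix(hw, N, 3, byrow = TRUE)
  colnames(post) <- GENO_LEVELS
  post
}

#' Surrogate genotype imputation
#'
#' A transparent stand-in for an HMM-based imputation engine. For each
#' masked SNP it matches panel haplotype pairs whose genotype at the `w`
#' nearest typed SNPs agrees with the individual's typed genotypes, and
#' blends the genotype distribution among matching pairs with the panel's
#' Hardy-Weinberg distribution: `alpha * matches + (1 - alpha) * HW`, with
#' `alpha = exp(-D / lambda) * r_hot`, `D` the distance to the nearest typed
#' SNP and `r_hot` a penalty applied when a hotspot lies between the masked
#' SNP and its nearest typed neighbour. When no panel pair matches, the
#' Hardy-Weinberg term alone is returned. Imputation accuracy therefore
#' degrades with distance to typed SNPs, low MAF, and hotspot proximity.
#'
#' @param truth integer study genotype matrix `N x M` (B-allele counts).
#' @param panel a [generate_panel()] result.
#' @param typed_idx column indices of typed SNPs.
#' @param masked_idx column indices of SNPs to impute (disjoint from
#'   `typed_idx`).
#' @param params a [sim_params()] object.
#' @return numeric array `length(masked_idx) x N x 3` of posterior genotype
#'   probabilities (AA, AB, BB).
#' @export
surrogate_impute <- function(truth, panel, typed_idx, masked_idx, params) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(params, "sim_params"))
  if (length(typed_idx) == 0) stop("typed SNP set is empty")
  if (length(intersect(typed_idx, masked_idx)) > 0) {
    stop("typed and masked SNP sets must be disjoint")
  }
  N <- nrow(truth)
  post <- array(NA_real_, dim = c(length(masked_idx), N, 3))
  for (k in seq_along(masked_idx)) {
    post[k, , ] <- impute_one_snp(truth, panel, typed_idx, masked_idx[k], params)
  }
  dimnames(post) <- list(panel$snp_ids[masked_idx], NULL, GENO_LEVELS)
  post
}

#' Construct an imputation scenario
#'
#' Validates and bundles the components of one train or test scenario:
#' panel, study truth, disjoint typed and imputed SNP sets, posteriors for
#' every imputed SNP, and the annotation inputs the feature generator needs.
#'
#' @param panel a [generate_panel()] result (or `NULL` for file-based
#'   scenarios).
#' @param truth study genotype matrix `N x M` (B-allele counts; columns
#'   follow `snp_ids`).
#' @param snp_ids,positions,chrom per-SNP identifiers, positions (bp) and the
#'   chromosome code.
#' @param typed_idx,imputed_idx disjoint SNP index sets.
#' @param posteriors array `length(imputed_idx) x N x 3`.
#' @param annotation data frame `snp_id`, `chrom`, `pos`, `maf` covering the
#'   imputed SNPs.
#' @param panel_stats data frame from [panel_genotype_stats()] (or
#'   [read_panel_stats()]).
#' @param hotspots a [hotspot_map()].
#' @param baf_genotypes genotype matrix (individuals x M) of an
#'   ethnic-matched sample used for the B-allele-frequency feature; defaults
#'   to panel-derived genotypes.
#' @param sample_ids study individual ids.
#' @return an object of class `imputation_scenario`.
#' @export
imputation_scenario <- function(panel, truth, snp_ids, positions, chrom,
                                typed_idx, imputed_idx, posteriors,
                                annotation, panel_stats, hotspots,
                                baf_genotypes = NULL, sample_ids = NULL) {
  if (length(intersect(typed_idx, imputed_idx)) > 0) {
    stop("typed and imputed SNP sets must be disjoint")
  }
  if (dim(posteriors)[1] != length(imputed_idx)) {
    stop("posteriors must cover every imputed SNP")
  }
  if (dim(posteriors)[2] != nrow(truth)) {
    stop("posteriors must cover every study individual")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(nrow(truth)))
  if (is.null(baf_genotypes) && !is.null(panel)) {
    hap <- panel$haplotypes
    baf_genotypes <- hap[seq(1, nrow(hap), by = 2), , drop = FALSE] +
      hap[seq(2, nrow(hap), by = 2), , drop = FALSE]
  }
  structure(list(panel = panel, truth = truth, snp_ids = snp_ids,
                 positions = positions, chrom = chrom,
                 typed_idx = sort(typed_idx), imputed_idx = imputed_idx,
                 posteriors = posteriors, annotation = annotation,
                 panel_stats = panel_stats, hotspots = as_hotspot_map(hotspots),
                 baf_genotypes = baf_genotypes, sample_ids = sample_ids),
            class = "imputation_scenario")
}

#' @export
print.imputation_scenario <- function(x, ...) {
  cat(sprintf("Imputation scenario: %d individuals, %d typed SNPs, %d imputed SNPs (chromosome %d)\n",
              nrow(x$truth), length(x$typed_idx), length(x$imputed_idx),
              x$chrom[1]))
  invisible(x)
}

#' Build the paired train/test synthetic scenario
#'
#' Generates the full evaluation fixture: a reference panel, study
#' genotypes, an old-platform (typed) SNP set, and two imputation scenarios.
#' The training scenario erases a fraction (`mask_fraction`) of old-platform
#' SNPs and imputes them from the remaining typed SNPs — the platform-
#' masking trick that yields truth-labelled training examples. The test
#' scenario imputes every new-platform-only SNP from the complete old
#' platform. Per-SNP platform MAF annotation is derived from the study
#' genotypes.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `train` and `test` (both
#'   [imputation_scenario()] objects), the shared `panel` and `params`.
#' @export
build_fixture <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  panel <- generate_panel(params)
  truth <- sample_study(panel, params$N, seed = params$seed + 1)
  M <- params$M
  typed_idx <- with_local_seed(params$seed + 2, {
    # uneven array coverage: per-block inclusion weights (U-shaped) yield
    # dense stretches and near-empty gaps, as real platforms do
    block <- 1 + panel$positions %/% params$platform_block_bp
    wts <- stats::rgamma(max(block), 1, 1)[block] + 0.05
    sort(sample.int(M, round(params$old_platform_fraction * M), prob = wts))
  })
  new_only_idx <- setdiff(seq_len(M), typed_idx)
  mask <- mask_training_snps(typed_idx, fraction = params$mask_fraction,
                             seed = params$seed + 3)
  stats <- panel_genotype_stats(panel)
  study_fb <- colMeans(truth) / 2
  annotation <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                           pos = panel$positions,
                           maf = pmin(study_fb, 1 - study_fb),
                           stringsAsFactors = FALSE)
  train_post <- surrogate_impute(truth, panel, typed_idx = mask$kept,
                                 masked_idx = mask$masked, params = params)
  test_post <- surrogate_impute(truth, panel, typed_idx = typed_idx,
                                masked_idx = new_only_idx, params = params)
  train <- imputation_scenario(panel, truth, panel$snp_ids, panel$positions,
                               panel$chrom, typed_idx = mask$kept,
                               imputed_idx = mask$masked,
                               posteriors = train_post,
                               annotation = annotation, panel_stats = stats,
                               hotspots = panel$hotspots)
  test <- imputation_scenario(panel, truth, panel$snp_ids, panel$positions,
                              panel$chrom, typed_idx = typed_idx,
                              imputed_idx = new_only_idx,
                              posteriors = test_post,
                              annotation = annotation, panel_stats = stats,
                              hotspots = panel$hotspots)
  list(train = train, test = test, panel = panel, params = params)
}

#' Write a scenario's files in the pipeline's native dialects
#'
#' Emits `truth.tsv`, `posteriors.gprobs`, `dosages.dose`, `annotation.tsv`,
#' `panel_stats.tsv` and `hotspots.tsv` under `dir`, so synthetic and real
#' data flow through identical readers.
#'
#' @param scenario an [imputation_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_scenario_files <- function(scenario, dir) {
  stopifnot(inherits(scenario, "imputation_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ii <- scenario$imputed_idx
  ids <- scenario$snp_ids[ii]
  st <- scenario$panel_stats
  al_a <- st$allele_a[match(ids, st$snp_id)]
  al_b <- st$allele_b[match(ids, st$snp_id)]
  paths <- c(truth = file.path(dir, "truth.tsv"),
             gprobs = file.path(dir, "posteriors.gprobs"),
             dose = file.path(dir, "dosages.dose"),
             annotation = file.path(dir, "annotation.tsv"),
             panel = file.path(dir, "panel_stats.tsv"),
             hotspots = file.path(dir, "hotspots.tsv"),
             typed = file.path(dir, "typed_positions.tsv"))
  write_truth_tsv(paths["truth"], ids, t(scenario$truth[, ii, drop = FALSE]),
                  scenario$sample_ids)
  write_gprobs(paths["gprobs"], ids, al_a, al_b, scenario$posteriors,
               scenario$sample_ids)
  dos <- scenario$posteriors[, , 2, drop = FALSE][, , 1] +
    2 * scenario$posteriors[, , 3, drop = FALSE][, , 1]
  write_dose(paths["dose"], ids, al_a, al_b, dos, scenario$sample_ids)
  ann <- scenario$annotation[match(ids, scenario$annotation$snp_id), ]
  if (!"baf" %in% names(ann) && !is.null(scenario$baf_genotypes)) {
    ann$baf <- colMeans(scenario$baf_genotypes[, ii, drop = FALSE]) / 2
  }
  write_annotation(ann, paths["annotation"])
  write_panel_stats(st, paths["panel"])
  write_hotspots(scenario$hotspots, paths["hotspots"])
  utils::write.table(
    data.frame(snp_id = scenario$snp_ids[scenario$typed_idx],
               chrom = scenario$chrom,
               pos = scenario$positions[scenario$typed_idx]),
    paths["typed"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
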