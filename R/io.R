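#' Recombination hotspot map
#'
#' A hotspot map is a data frame with columns `chrom` (integer code), `pos`
#' (bp) and `rate` (cM/Mb), sorted by chromosome then position, with at most
#' one entry per position per chromosome.
#'
#' @param chrom integer chromosome codes.
#' @param pos positions in bp.
#' @param rate recombination rates in cM/Mb (must be nonnegative).
#' @return an object of class `hotspot_map`.
#' @export
hotspot_map <- function(chrom, pos, rate) {
  df <- data.frame(chrom = as.integer(chrom), pos = as.numeric(pos),
                   rate = as.numeric(rate))
  as_hotspot_map(df)
}

#' @rdname hotspot_map
#' @param x a data frame with columns `chrom`, `pos`, `rate`.
#' @export
as_hotspot_map <- function(x) {
  if (inherits(x, "hotspot_map")) return(x)
  x <- as.data.frame(x)
  if (!all(c("chrom", "pos", "rate") %in% names(x))) {
    stop("a hotspot map needs columns chrom, pos, rate")
  }
  if (any(x$rate < 0)) stop("recombination rates must be nonnegative")
  # collapse duplicate positions keeping the maximum rate
  key <- paste(x$chrom, x$pos)
  if (anyDuplicated(key)) {
    x <- do.call(rbind, lapply(split(x, key), function(d) {
      d[which.max(d$rate), , drop = FALSE]
    }))
  }
  x <- x[order(x$chrom, x$pos), c("chrom", "pos", "rate"), drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("hotspot_map", "data.frame")
  x
}

#' Read a recombination hotspot / rate table
#'
#' Reads either a HapMap-style whitespace table with columns
#' `Chromosome Position(bp) Rate(cM/Mb) Map(cM)` (the genetic-map column is
#' ignored; chromosome labels such as `chr7` are accepted) or a two-column
#' `pos rate` TSV for a single chromosome. Rows are sorted by position (a
#' message is emitted if the input was unsorted); duplicated positions are
#' collapsed keeping the maximum rate; negative rates are an error.
#'
#' @param path file path.
#' @param chrom chromosome code assumed for two-column input (default 1).
#' @return a [hotspot_map()].
#' @export
read_hotspots <- function(path, chrom = 1L) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) >= 3) {
    ch <- d[[1]]
    if (is.character(ch)) ch <- sub("^chr", "", ch, ignore.case = TRUE)
    out <- data.frame(chrom = as.integer(ch), pos = as.numeric(d[[2]]),
                      rate = as.numeric(d[[3]]))
  } else if (ncol(d) == 2) {
    out <- data.frame(chrom = as.integer(chrom), pos = as.numeric(d[[1]]),
                      rate = as.numeric(d[[2]]))
  } else {
    stop("hotspot file ", path, ": expected >= 2 columns")
  }
  if (anyNA(out$pos) || anyNA(out$chrom)) {
    stop("hotspot file ", path, ": non-numeric chromosome or position")
  }
  if (any(out$rate < 0)) {
    stop("hotspot file ", path, ": negative recombination rate")
  }
  if (!identical(order(out$chrom, out$pos), seq_len(nrow(out)))) {
    message("hotspot file ", path, ": rows were unsorted; sorting by position")
  }
  as_hotspot_map(out)
}

#' Write a hotspot map as a HapMap-style table
#'
#' @param map a [hotspot_map()].
#' @param path output file path.
#' @export
write_hotspots <- function(map, path) {
  map <- as_hotspot_map(map)
  d <- data.frame(Chromosome = map$chrom, `Position(bp)` = map$pos,
                  `Rate(cM/Mb)` = map$rate, `Map(cM)` = 0,
                  check.names = FALSE)
  utils::write.table(d, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  # fixed notation at full double precision, so write-read-write round-trips
  # are token-exact
  format(x, scientific = FALSE, trim = TRUE, digits = 17)
}

#' Write posterior probabilities in the Beagle genotype-probabilities dialect
#'
#' One header line `marker alleleA alleleB` followed by each sample id three
#' times, then one line per marker with the marker id, the two alleles, and
#' the AA/AB/BB posterior triple of each individual.
#'
#' @param path output file path.
#' @param snp_ids marker identifiers.
#' @param allele_a,allele_b single-character alleles per marker.
#' @param posteriors numeric array `markers x individuals x 3`, or a list of
#'   per-marker posterior matrices.
#' @param sample_ids individual identifiers.
#' @export
write_gprobs <- function(path, snp_ids, allele_a, allele_b, posteriors,
                         sample_ids) {
  if (is.list(posteriors)) {
    posteriors <- simplify2array(posteriors)      # ind x 3 x markers
    posteriors <- aperm(posteriors, c(3, 1, 2))   # markers x ind x 3
  }
  stopifnot(length(dim(posteriors)) == 3, dim(posteriors)[3] == 3,
            dim(posteriors)[1] == length(snp_ids),
            dim(posteriors)[2] == length(sample_ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker", "alleleA", "alleleB",
                     rep(sample_ids, each = 3)), collapse = " "), con)
  n <- length(sample_ids)
  interleave <- as.vector(rbind(seq_len(n), n + seq_len(n), 2 * n + seq_len(n)))
  for (m in seq_along(snp_ids)) {
    probs <- c(posteriors[m, , 1], posteriors[m, , 2], posteriors[m, , 3])
    writeLines(paste(c(snp_ids[m], allele_a[m], allele_b[m],
                       fmt_num(probs[interleave])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a Beagle genotype-probabilities file
#'
#' Parses the whitespace dialect written by [write_gprobs()]: a header line
#' naming each sample three times, then per-marker lines with the marker id,
#' the two alleles and 3 probabilities per individual (AA, AB, BB). Each
#' triple must sum to 1 within `tol` and is renormalized on ingest. Ragged
#' rows and triple-sum violations are reported with their line number.
#'
#' @param path file path.
#' @param tol permitted deviation of each AA/AB/BB triple sum from 1
#'   (default `1e-3`).
#' @return a list with `markers` (data frame `snp_id`, `allele_a`,
#'   `allele_b`), `samples` (ids) and `posteriors`
#'   (array `markers x individuals x 3`).
#' @export
read_gprobs <- function(path, tol = 1e-3) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("gprobs file ", path, ": empty file")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) < 6 || (length(hdr) - 3) %% 3 != 0) {
    stop("gprobs file ", path, ", line 1: malformed header")
  }
  samples <- hdr[seq(4, length(hdr), by = 3)]
  n <- length(samples)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  nm <- length(body)
  markers <- data.frame(snp_id = character(nm), allele_a = character(nm),
                        allele_b = character(nm), stringsAsFactors = FALSE)
  post <- array(NA_real_, dim = c(nm, n, 3))
  for (k in seq_len(nm)) {
    tok <- strsplit(trimws(body[k]), "[ \t]+")[[1]]
    if (length(tok) != 3 + 3 * n) {
      stop("gprobs file ", path, ", line ", k + 1, ": expected ",
           3 + 3 * n, " fields, found ", length(tok))
    }
    markers$snp_id[k] <- tok[1]
    markers$allele_a[k] <- tok[2]
    markers$allele_b[k] <- tok[3]
    pr <- suppressWarnings(as.numeric(tok[-(1:3)]))
    if (anyNA(pr)) stop("gprobs file ", path, ", line ", k + 1,
                        ": non-numeric probability")
    tri <- matrix(pr, ncol = 3, byrow = TRUE)  # rows: individuals
    s <- rowSums(tri)
    if (any(abs(s - 1) > tol)) {
      stop("gprobs file ", path, ", line ", k + 1,
           ": genotype probability triple does not sum to 1 within ", tol)
    }
    # renormalize only when measurably off; exact inputs stay bit-identical
    fix <- abs(s - 1) > 1e-12
    tri[fix, ] <- tri[fix, , drop = FALSE] / s[fix]
    post[k, , ] <- tri
  }
  list(markers = markers, samples = samples, posteriors = post)
}

#' Write B-allele dosages in the Beagle dosage dialect
#'
#' Header `marker alleleA alleleB` plus one column per sample; one line per
#' marker with the expected B-allele count (0-2) of each individual.
#'
#' @inheritParams write_gprobs
#' @param dosages numeric matrix `markers x individuals` with values in
#'   `[0, 2]`.
#' @export
write_dose <- function(path, snp_ids, allele_a, allele_b, dosages, sample_ids) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == length(snp_ids),
            ncol(dosages) == length(sample_ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker", "alleleA", "alleleB", sample_ids),
                   collapse = " "), con)
  for (m in seq_along(snp_ids)) {
    writeLines(paste(c(snp_ids[m], allele_a[m], allele_b[m],
                       fmt_num(dosages[m, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a Beagle dosage file
#'
#' @param path file path.
#' @return a list with `markers` (data frame) , `samples` and `dosages`
#'   (matrix `markers x individuals`).
#' @export
read_dose <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("dose file ", path, ": empty file")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) < 4) stop("dose file ", path, ", line 1: malformed header")
  samples <- hdr[-(1:3)]
  n <- length(samples)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  nm <- length(body)
  markers <- data.frame(snp_id = character(nm), allele_a = character(nm),
                        allele_b = character(nm), stringsAsFactors = FALSE)
  dos <- matrix(NA_real_, nm, n)
  for (k in seq_len(nm)) {
    tok <- strsplit(trimws(body[k]), "[ \t]+")[[1]]
    if (length(tok) != 3 + n) {
      stop("dose file ", path, ", line ", k + 1, ": expected ", 3 + n,
           " fields, found ", length(tok))
    }
    markers$snp_id[k] <- tok[1]
    markers$allele_a[k] <- tok[2]
    markers$allele_b[k] <- tok[3]
    d <- suppressWarnings(as.numeric(tok[-(1:3)]))
    if (anyNA(d)) stop("dose file ", path, ", line ", k + 1,
                       ": non-numeric dosage")
    if (any(d < -1e-9 | d > 2 + 1e-9)) {
      stop("dose file ", path, ", line ", k + 1, ": dosage outside [0, 2]")
    }
    dos[k, ] <- pmin(pmax(d, 0), 2)
  }
  list(markers = markers, samples = samples, dosages = dos)
}

#' Read / write true genotype calls
#'
#' TSV with header `snp_id` followed by one column per individual; genotype
#' cells are `AA`/`AB`/`BB` or `NA` for missing.
#'
#' @param path file path.
#' @return for the reader, a list with `snp_ids`, `samples` and `genotypes`
#'   (integer B-allele-count matrix `markers x individuals`, `NA` = missing).
#' @export
read_truth_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "NA")
  if (names(d)[1] != "snp_id") stop("truth file ", path, ": first column must be snp_id")
  snp_ids <- d[[1]]
  samples <- names(d)[-1]
  g <- as.matrix(d[, -1, drop = FALSE])
  gb <- matrix(genotype_b_counts(as.vector(g)), nrow = nrow(g))
  dimnames(gb) <- list(snp_ids, samples)
  list(snp_ids = snp_ids, samples = samples, genotypes = gb)
}

#' @rdname read_truth_tsv
#' @param snp_ids marker identifiers.
#' @param genotypes matrix `markers x individuals` of B-allele counts or
#'   genotype labels.
#' @param sample_ids individual identifiers.
#' @export
write_truth_tsv <- function(path, snp_ids, genotypes, sample_ids) {
  genotypes <- as.matrix(genotypes)
  lab <- matrix(genotype_labels(as.vector(genotypes)), nrow = nrow(genotypes))
  d <- data.frame(snp_id = snp_ids, lab, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d) <- c("snp_id", sample_ids)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write SNP platform annotation
#'
#' TSV with header `snp_id chrom pos maf` (extra columns preserved).
#'
#' @param path file path.
#' @return data frame with at least `snp_id`, `chrom`, `pos`, `maf`.
#' @export
read_annotation <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "maf")
  if (!all(need %in% names(d))) {
    stop("annotation file ", path, ": needs columns ",
         paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_annotation
#' @param annotation data frame with columns `snp_id`, `chrom`, `pos`, `maf`.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write reference-panel genotype counts
#'
#' TSV with header `snp_id n_aa n_ab n_bb maf` (and optionally `allele_a`,
#' `allele_b`). The panel MAF must be consistent with the counts.
#'
#' @param path file path.
#' @return data frame of per-SNP panel statistics.
#' @export
read_panel_stats <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "n_aa", "n_ab", "n_bb", "maf")
  if (!all(need %in% names(d))) {
    stop("panel stats file ", path, ": needs columns ",
         paste(need, collapse = ", "))
  }
  n2 <- 2 * (d$n_aa + d$n_ab + d$n_bb)
  fb <- ifelse(n2 > 0, (d$n_ab + 2 * d$n_bb) / n2, NA_real_)
  implied <- pmin(fb, 1 - fb)
  bad <- !is.na(implied) & abs(implied - d$maf) > 1e-9
  if (any(bad)) {
    stop("panel stats file ", path, ": maf inconsistent with counts for ",
         sum(bad), " SNP(s), e.g. ", d$snp_id[which(bad)[1]])
  }
  d
}

#' @rdname read_panel_stats
#' @param stats data frame of panel statistics.
#' @export
write_panel_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import genotype posteriors from a VCF with a GP FORMAT field
#'
#' Minimal convenience importer for VCF files carrying per-genotype
#' posterior probabilities in a `GP` (or `GP`-like comma-separated) FORMAT
#' field, ordered AA,AB,BB for biallelic sites. The Beagle text dialects are
#' the canonical input path; this reader covers small, uncompressed VCFs.
#'
#' @param path path to an uncompressed VCF.
#' @param tol triple-sum tolerance (as in [read_gprobs()]).
#' @return a list shaped like the result of [read_gprobs()].
#' @export
read_vcf_gp <- function(path, tol = 1e-3) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("VCF ", path, ": missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t")[[1]]
  if (length(hdr) < 10) stop("VCF ", path, ": no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  nm <- length(body)
  markers <- data.frame(snp_id = character(nm), allele_a = character(nm),
                        allele_b = character(nm), stringsAsFactors = FALSE)
  post <- array(NA_real_, dim = c(nm, length(samples), 3))
  for (k in seq_len(nm)) {
    tok <- strsplit(body[k], "\t")[[1]]
    lineno <- hdr_i + k
    if (length(tok) != length(hdr)) {
      stop("VCF ", path, ", line ", lineno, ": ragged row")
    }
    fmt <- strsplit(tok[9], ":")[[1]]
    gp_i <- match("GP", fmt)
    if (is.na(gp_i)) stop("VCF ", path, ", line ", lineno, ": no GP field")
    markers$snp_id[k] <- if (tok[3] == ".") paste0(tok[1], ":", tok[2]) else tok[3]
    markers$allele_a[k] <- tok[4]
    markers$allele_b[k] <- tok[5]
    for (s in seq_along(samples)) {
      cell <- strsplit(tok[9 + s], ":")[[1]]
      pr <- suppressWarnings(as.numeric(strsplit(cell[gp_i], ",")[[1]]))
      if (length(pr) != 3 || anyNA(pr)) {
        stop("VCF ", path, ", line ", lineno, ": malformed GP for sample ",
             samples[s])
      }
      if (abs(sum(pr) - 1) > tol) {
        stop("VCF ", path, ", line ", lineno, ": GP does not sum to 1")
      }
      post[k, s, ] <- pr / sum(pr)
    }
  }
  list(markers = markers, samples = samples, posteriors = post)
}
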