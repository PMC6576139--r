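#' Sample-level genotype quality control
#'
#' Removes samples with a call rate below `min_call_fraction` or a
#' heterozygous fraction (AB among non-missing calls) above
#' `max_het_fraction`. Thresholds are strict: a sample at exactly the
#' boundary is retained. Sample filtering is applied before marker
#' filtering; founder rows are filtered by the same rule.
#'
#' @param g a [nam_geno()] object.
#' @param min_call_fraction minimum fraction of genotyped (non-missing)
#'   markers; samples strictly below are removed (default 0.8).
#' @param max_het_fraction maximum heterozygous fraction among non-missing
#'   calls; samples strictly above are removed (default 0.2).
#' @return list with `geno` (filtered) and `removed` (data.frame of removed
#'   sample ids with their call and het rates).
#' @export
filter_samples <- function(g, min_call_fraction = 0.8,
                           max_het_fraction = 0.2) {
  stopifnot(inherits(g, "nam_geno"))
  obs <- !is.na(g$calls)
  call_rate <- rowMeans(obs)
  n_obs <- rowSums(obs)
  het_rate <- ifelse(n_obs > 0,
                     rowSums(g$calls == "AB", na.rm = TRUE) / n_obs, 0)
  drop <- call_rate < min_call_fraction | het_rate > max_het_fraction
  removed <- data.frame(sample = rownames(g$calls)[drop],
                        call_rate = call_rate[drop],
                        het_rate = het_rate[drop],
                        stringsAsFactors = FALSE)
  out <- g[!drop, ]
  if (nrow(out$calls) == 0L) {
    warning("all samples removed by the sample filter")
  }
  list(geno = out, removed = removed)
}

#' Marker-level genotype quality control
#'
#' Removes markers genotyped in fewer than `min_call_fraction` of samples or
#' heterozygous in more than `max_het_fraction` of samples. Applied after
#' [filter_samples()], so rates are computed on the retained samples.
#' Boundary values are retained, mirroring the strict sample thresholds.
#' The heterozygosity denominator is the number of non-missing calls, so
#' missingness is not conflated with heterozygosity.
#'
#' @inheritParams filter_samples
#' @return list with `geno` and `removed` (data.frame of markers).
#' @export
filter_markers <- function(g, min_call_fraction = 0.8,
                           max_het_fraction = 0.2) {
  stopifnot(inherits(g, "nam_geno"))
  obs <- !is.na(g$calls)
  call_rate <- colMeans(obs)
  n_obs <- colSums(obs)
  het_rate <- ifelse(n_obs > 0,
                     colSums(g$calls == "AB", na.rm = TRUE) / n_obs, 0)
  drop <- call_rate < min_call_fraction | het_rate > max_het_fraction
  removed <- data.frame(marker = colnames(g$calls)[drop],
                        call_rate = call_rate[drop],
                        het_rate = het_rate[drop],
                        stringsAsFactors = FALSE)
  out <- g[, !drop]
  if (ncol(out$calls) == 0L) {
    warning("all markers removed by the marker filter")
  }
  list(geno = out, removed = removed)
}

#' Full genotype QC: samples first, then markers
#'
#' @inheritParams filter_samples
#' @return list with `geno`, `removed_samples`, `removed_markers`.
#' @export
qc_filter <- function(g, min_call_fraction = 0.8, max_het_fraction = 0.2) {
  fs <- filter_samples(g, min_call_fraction, max_het_fraction)
  fm <- filter_markers(fs$geno, min_call_fraction, max_het_fraction)
  list(geno = fm$geno, removed_samples = fs$removed,
       removed_markers = fm$removed)
}

# is each marker polymorphic among these call rows?
# polymorphic = both homozygote classes observed, or one homozygote class
# plus the alternative allele (carried by a heterozygote)
marker_polymorphic <- function(calls) {
  has_aa <- colSums(calls == "AA", na.rm = TRUE) > 0
  has_bb <- colSums(calls == "BB", na.rm = TRUE) > 0
  has_ab <- colSums(calls == "AB", na.rm = TRUE) > 0
  (has_aa & has_bb) | (has_ab & (has_aa | has_bb))
}

#' Per-family marker statistics
#'
#' For each family (founder rows excluded): number of RILs, number of
#' polymorphic markers, mean per-sample heterozygosity (%) and mean
#' per-sample failure (missing) rate (%). A marker counts as polymorphic in
#' a family when both homozygote classes, or a homozygote class plus the
#' alternative allele, are observed among that family's RILs.
#'
#' @param g a [nam_geno()] object with family labels.
#' @return data.frame with one row per family: `family`, `n_rils`,
#'   `n_polymorphic`, `mean_het_pct`, `mean_failure_pct`; families with
#'   fewer than 2 RILs are flagged in the `flagged` column.
#' @export
family_stats <- function(g) {
  stopifnot(inherits(g, "nam_geno"))
  r <- ril_only(g)
  fams <- sort(unique(r$family))
  out <- lapply(fams, function(f) {
    calls <- r$calls[r$family == f, , drop = FALSE]
    obs <- !is.na(calls)
    n_obs <- rowSums(obs)
    het <- ifelse(n_obs > 0, rowSums(calls == "AB", na.rm = TRUE) / n_obs, 0)
    data.frame(
      family = f, n_rils = nrow(calls),
      n_polymorphic = sum(marker_polymorphic(calls)),
      mean_het_pct = 100 * mean(het),
      mean_failure_pct = 100 * mean(1 - rowMeans(obs)),
      flagged = nrow(calls) < 2L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Minor-allele-frequency spectrum
#'
#' Per-marker minor allele frequency from non-missing calls, heterozygotes
#' contributing half an allele count to each class; the minor frequency is
#' `min(f, 1 - f)` and therefore lies in \[0, 0.5\]. All-missing markers are
#' reported as `NA`.
#'
#' @param g a [nam_geno()] object.
#' @param scope `"population"` (all RILs) or `"family"` (one spectrum per
#'   family).
#' @return for `scope = "population"`, a named numeric vector; for
#'   `scope = "family"`, a marker x family matrix.
#' @export
maf_spectrum <- function(g, scope = c("population", "family")) {
  scope <- match.arg(scope)
  r <- ril_only(g)
  maf_of <- function(calls) {
    nb <- colSums(geno_dosage(calls), na.rm = TRUE)       # B-allele count
    nn <- 2 * colSums(!is.na(calls))                      # total alleles
    f <- ifelse(nn > 0, nb / nn, NA_real_)
    pmin(f, 1 - f)
  }
  if (scope == "population") {
    maf_of(r$calls)
  } else {
    fams <- sort(unique(r$family))
    vapply(fams, function(f) maf_of(r$calls[r$family == f, , drop = FALSE]),
           numeric(ncol(r$calls)))
  }
}

#' Exclusive intersections of per-family polymorphic marker sets
#'
#' For every non-empty subset of families, counts the markers polymorphic in
#' exactly that subset (UpSet semantics). Counts over all subsets sum to the
#' size of the union of the family sets.
#'
#' @param sets named list of character vectors (per-family polymorphic
#'   marker ids), e.g. built from [family_stats()] internals or directly via
#'   [polymorphic_sets()].
#' @return data.frame with columns `families` (comma-joined subset) ordered
#'   by decreasing `count`, plus `degree` (subset size).
#' @export
family_intersections <- function(sets) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  fams <- names(sets)
  all_mk <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_mk %in% s, logical(length(all_mk)))
  if (length(all_mk) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(NULL, fams))
  key <- apply(memb, 1L, function(z) paste(fams[z], collapse = ","))
  tab <- table(key)
  # enumerate all non-empty subsets so zero counts are reported too
  subsets <- unlist(lapply(seq_along(fams), function(k) {
    utils::combn(fams, k, paste, collapse = ",", simplify = FALSE)
  }))
  counts <- vapply(subsets, function(s) {
    if (s %in% names(tab)) as.integer(tab[[s]]) else 0L
  }, integer(1))
  out <- data.frame(families = unlist(subsets), count = counts,
                    degree = lengths(strsplit(unlist(subsets), ",")),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$degree, out$families), , drop = FALSE]
}

#' Per-family polymorphic marker sets
#'
#' @param g a [nam_geno()] object.
#' @return named list of character vectors of marker ids, one per family.
#' @export
polymorphic_sets <- function(g) {
  r <- ril_only(g)
  fams <- sort(unique(r$family))
  stats::setNames(lapply(fams, function(f) {
    colnames(r$calls)[marker_polymorphic(r$calls[r$family == f, ,
                                                 drop = FALSE])]
  }), fams)
}

#' SNP density in genomic bins
#'
#' Counts placed markers per half-open bin `[k*size, (k+1)*size)` along each
#' chromosome, reporting both all available markers and the subset flagged
#' polymorphic. Unplaced markers are excluded and their count logged as an
#' attribute.
#'
#' @param map physical map data.frame with columns `marker`, `chrom`,
#'   `pos_bp` (1-based), e.g. from [place_from_sam()] or
#'   [merge_placement_table()].
#' @param polymorphic character vector of marker ids counted as polymorphic
#'   (default none).
#' @param bin_size bin width in bp (default 10 Mb).
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   when given, trailing empty bins are reported as zero counts.
#' @return data.frame `chrom`, `bin_start`, `bin_end`, `n_markers`,
#'   `n_polymorphic`; attribute `n_unplaced` counts excluded markers.
#' @export
snp_density_bins <- function(map, polymorphic = character(0),
                             bin_size = 10e6, chrom_lengths = NULL) {
  stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(map)))
  unplaced <- is.na(map$chrom) | is.na(map$pos_bp)
  if (any(unplaced)) {
    message(sum(unplaced), " unplaced markers excluded from density bins")
  }
  map <- map[!unplaced, , drop = FALSE]
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    sort(unique(map$chrom))
  out <- lapply(chroms, function(cc) {
    pos <- map$pos_bp[map$chrom == cc]
    poly <- map$marker[map$chrom == cc] %in% polymorphic
    max_bin <- if (!is.null(chrom_lengths)) {
      ceiling(chrom_lengths[[cc]] / bin_size) - 1L
    } else if (length(pos)) max(pos %/% bin_size) else -1L
    if (max_bin < 0L) return(NULL)
    bins <- 0:max_bin
    idx <- pos %/% bin_size
    data.frame(
      chrom = cc, bin_start = bins * bin_size,
      bin_end = (bins + 1) * bin_size,
      n_markers = vapply(bins, function(b) sum(idx == b), integer(1)),
      n_polymorphic = vapply(bins, function(b) sum(idx == b & poly),
                             integer(1)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  attr(res, "n_unplaced") <- sum(unplaced)
  res
}
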