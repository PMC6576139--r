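#' Polarize a family's calls by founder origin
#'
#' Restricts a family to markers informative about founder origin: markers
#' where either founder call is missing or heterozygous are dropped (logged),
#' as are markers monomorphic between the founder pair. Remaining RIL calls
#' are recoded by origin — the RF homozygote class, the alternative-founder
#' homozygote class, or missing; heterozygous RIL calls are set to missing
#' ("set as failed").
#'
#' @param calls character matrix of one family's RIL calls (samples x
#'   markers, AA/AB/BB/NA).
#' @param rf_calls,alt_calls named call vectors of the recurrent and
#'   alternative founder over the same markers.
#' @param family_id label carried through to the output.
#' @return list of class `polarized_family`: `rf_dose` (RIL x marker matrix
#'   with 1 = RF homozygote, 0 = ALT homozygote, NA = missing/het),
#'   `markers`, `family_id`, `dropped` (data.frame marker/reason).
#' @export
polarize_family <- function(calls, rf_calls, alt_calls, family_id = "fam") {
  stopifnot(is.matrix(calls))
  mk <- colnames(calls)
  rf <- rf_calls[mk]
  alt <- alt_calls[mk]
  reason <- rep(NA_character_, length(mk))
  reason[is.na(rf) | is.na(alt)] <- "founder call missing"
  reason[is.na(reason) & (rf == "AB" | alt == "AB")] <- "founder heterozygous"
  reason[is.na(reason) & rf == alt] <- "monomorphic between founders"
  keep <- is.na(reason)
  dropped <- data.frame(marker = mk[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  kept <- which(keep)
  rf_dose <- matrix(NA_real_, nrow(calls), length(kept),
                    dimnames = list(rownames(calls), mk[kept]))
  for (j in seq_along(kept)) {
    cl <- calls[, kept[j]]
    rf_dose[cl == rf[kept[j]] & !is.na(cl), j] <- 1
    rf_dose[cl == alt[kept[j]] & !is.na(cl), j] <- 0
    # heterozygous RIL calls stay NA (set as failed)
  }
  structure(list(rf_dose = rf_dose, markers = mk[kept],
                 family_id = family_id, dropped = dropped),
            class = "polarized_family")
}

#' Goodness-of-fit test of 50:50 founder representation at one locus
#'
#' One-degree-of-freedom chi-squared test of the observed RF/ALT homozygote
#' counts against the Mendelian 50:50 expectation for an inbred family.
#'
#' @param n_rf,n_alt informative call counts for the RF and alternative
#'   founder classes; their sum must be >= 1.
#' @return list `chi2`, `p`, `direction` (`"RF"`, `"ALT"` or `NA` on a tie).
#' @examples
#' locus_gof(60, 40) # chi2 = 4, p ~ 0.0455, direction "RF"
#' @export
locus_gof <- function(n_rf, n_alt) {
  n <- n_rf + n_alt
  if (n < 1) stop("no informative calls at locus")
  e <- n / 2
  chi2 <- (n_rf - e)^2 / e + (n_alt - e)^2 / e
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  direction <- if (n_rf > n_alt) "RF" else if (n_alt > n_rf) "ALT"
  else NA_character_
  list(chi2 = chi2, p = p, direction = direction)
}

#' Signed, binned founder-contribution distortion scan
#'
#' Tests every informative marker of a polarized family against the 50:50
#' expectation, averages the per-marker p-values within half-open genomic
#' bins (default 5 Mb, anchored at 0), and log-transforms the bin mean. The
#' score is signed by the bin's majority direction (weighted by informative
#' calls): positive when the RF allele is over-represented, negative when
#' the alternative founder is. Bins with fewer than `min_markers`
#' informative markers are suppressed.
#'
#' @param pf a [polarize_family()] object.
#' @param map physical map data.frame (`marker`, `chrom`, `pos_bp`).
#' @param bin_size bin width in bp (default 5 Mb).
#' @param min_markers minimum markers per reported bin (default 3, i.e.
#'   "more than two").
#' @param log_base base of the log transform (default natural log).
#' @return data.frame `family`, `chrom`, `bin_start`, `bin_end`,
#'   `n_markers`, `mean_p`, `signed_score`, `direction`; attribute
#'   `n_unplaced` counts markers without a placement.
#' @export
binned_scan <- function(pf, map, bin_size = 5e6, min_markers = 3L,
                        log_base = exp(1)) {
  stopifnot(inherits(pf, "polarized_family"))
  idx <- match(pf$markers, map$marker)
  unplaced <- is.na(idx)
  if (any(unplaced)) {
    message(sum(unplaced), " markers without placement excluded from scan")
  }
  keep <- which(!unplaced)
  per_marker <- lapply(keep, function(j) {
    x <- pf$rf_dose[, j]
    n_rf <- sum(x == 1, na.rm = TRUE)
    n_alt <- sum(x == 0, na.rm = TRUE)
    if (n_rf + n_alt < 1) return(NULL)
    g <- locus_gof(n_rf, n_alt)
    data.frame(marker = pf$markers[j], chrom = map$chrom[idx[j]],
               pos_bp = map$pos_bp[idx[j]], p = g$p,
               n_rf = n_rf, n_alt = n_alt, stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, per_marker[!vapply(per_marker, is.null, logical(1))])
  if (is.null(pm) || nrow(pm) == 0L) {
    out <- data.frame(family = character(0), chrom = character(0),
                      bin_start = numeric(0), bin_end = numeric(0),
                      n_markers = integer(0), mean_p = numeric(0),
                      signed_score = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_unplaced") <- sum(unplaced)
    return(out)
  }
  pm$bin <- pm$pos_bp %/% bin_size
  keys <- unique(pm[, c("chrom", "bin")])
  keys <- keys[order(keys$chrom, keys$bin), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- pm[pm$chrom == keys$chrom[i] & pm$bin == keys$bin[i], ,
              drop = FALSE]
    if (nrow(sub) < min_markers) return(NULL)
    mean_p <- mean(sub$p)
    rf_w <- sum(sub$n_rf)
    alt_w <- sum(sub$n_alt)
    dir <- if (rf_w > alt_w) "RF" else if (alt_w > rf_w) "ALT"
    else NA_character_
    score <- -log(mean_p, base = log_base)
    signed <- if (is.na(dir)) score else if (dir == "RF") score else -score
    data.frame(family = pf$family_id, chrom = keys$chrom[i],
               bin_start = keys$bin[i] * bin_size,
               bin_end = (keys$bin[i] + 1) * bin_size,
               n_markers = nrow(sub), mean_p = mean_p,
               signed_score = signed, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(family = character(0), chrom = character(0),
                      bin_start = numeric(0), bin_end = numeric(0),
                      n_markers = integer(0), mean_p = numeric(0),
                      signed_score = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_unplaced") <- sum(unplaced)
  out
}

#' Bonferroni threshold for the distortion scan
#'
#' The significance threshold on the absolute signed score: the nominal
#' level divided by the number of markers in the population, log-transformed
#' in the configured base, i.e. `-log(alpha / n_markers)`.
#'
#' @param n_markers number of markers in the population (>= 1).
#' @param alpha nominal level (default 0.05).
#' @param log_base base of the log transform (default natural log, matching
#'   [binned_scan()]).
#' @return the threshold on `abs(signed_score)`.
#' @examples
#' scan_threshold(12114) # ~ 12.4
#' @export
scan_threshold <- function(n_markers, alpha = 0.05, log_base = exp(1)) {
  stopifnot(n_markers >= 1L, alpha > 0, alpha < 1)
  -log(alpha / n_markers, base = log_base)
}
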