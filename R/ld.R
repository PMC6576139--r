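#' Pairwise linkage disequilibrium on one chromosome
#'
#' Computes r-squared as the squared Pearson correlation of allele dosages
#' (AA = 0, AB = 1, BB = 2) over pairwise-complete samples, for all placed
#' markers of one chromosome. Pairs with fewer than `min_pairs` complete
#' samples, and pairs involving a monomorphic marker, are reported missing
#' (not zero). Near-inbred RILs make the genotype-based (composite) r2
#' essentially the haplotype r2.
#'
#' @param g a [nam_geno()] object (founder rows are excluded).
#' @param map physical map data.frame (`marker`, `chrom`, `pos_bp`).
#' @param chromosome chromosome name to analyse.
#' @param min_pairs minimum pairwise-complete samples per pair (default 10).
#' @return list of class `ld_matrix`: `chrom`, `markers`, `pos_bp`, `r2`
#'   (symmetric matrix), `n` (pairwise-complete counts).
#' @export
pairwise_r2 <- function(g, map, chromosome, min_pairs = 10L) {
  stopifnot(inherits(g, "nam_geno"))
  mk <- map$marker[map$chrom == chromosome]
  mk <- intersect(mk, colnames(g$calls))
  if (length(mk) < 2L) stop("need >= 2 placed markers on ", chromosome)
  pos <- map$pos_bp[match(mk, map$marker)]
  o <- order(pos)
  mk <- mk[o]
  pos <- pos[o]
  d <- geno_dosage(ril_only(g))[, mk, drop = FALSE]
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  obs <- !is.na(d)
  n <- crossprod(obs)
  r2[n < min_pairs] <- NA_real_
  diag(r2)[colSums(obs) >= min_pairs &
             apply(d, 2, function(x) stats::var(x, na.rm = TRUE) > 0)] <- 1
  structure(list(chrom = chromosome, markers = mk, pos_bp = pos,
                 r2 = r2, n = n),
            class = "ld_matrix")
}

#' Pull (distance, r2) pairs out of an LD matrix
#'
#' @param ldm an [pairwise_r2()] result.
#' @return data.frame `dist_bp`, `r2`, `n` for the upper triangle,
#'   missing pairs dropped.
#' @export
ld_pairs <- function(ldm) {
  stopifnot(inherits(ldm, "ld_matrix"))
  ut <- upper.tri(ldm$r2)
  i <- row(ldm$r2)[ut]
  j <- col(ldm$r2)[ut]
  keep <- !is.na(ldm$r2[ut])
  data.frame(dist_bp = abs(ldm$pos_bp[j] - ldm$pos_bp[i])[keep],
             r2 = ldm$r2[ut][keep], n = ldm$n[ut][keep])
}

#' Expected r2 under the Hill-Weir drift-recombination model
#'
#' The expectation of r-squared between two loci separated by recombination
#' scale `C` in a sample of `n` gametes:
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n (2 + C)(11 + C)}\right).}
#' At `C = 0` and large `n` this tends to 10/22.
#'
#' @param C recombination-scale parameter (vectorized).
#' @param n sample size.
#' @return expected r2.
#' @export
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir LD decay curve
#'
#' Nonlinear least squares of [hill_weir_expectation()] against observed
#' (distance, r2) pairs, with the recombination scale parameterized linearly
#' in distance, `C = a * d`, and the sample size `n` held fixed at the
#' number of lines genotyped. The single coefficient `a >= 0` is found by
#' golden-section search on `log10(a)` followed by a local refinement.
#'
#' @param dist_bp,r2 paired vectors of inter-marker distances and r2 values.
#' @param n sample size (number of lines) behind the r2 estimates.
#' @param a_range search range for `a` (per bp); the default spans
#'   organelle-to-outcrosser scales.
#' @return list of class `hill_weir_fit`: `a` (per unit distance), `n`,
#'   `rss`, `predict` (function of distance), `boundary` (TRUE when `a`
#'   hit the lower search bound).
#' @export
fit_hill_weir <- function(dist_bp, r2, n, a_range = c(1e-15, 10)) {
  keep <- is.finite(dist_bp) & is.finite(r2)
  dist_bp <- dist_bp[keep]
  r2 <- r2[keep]
  if (length(r2) < 10L || length(unique(dist_bp)) < 2L) {
    stop("need >= 10 pairs spanning more than one distance")
  }
  rss <- function(log_a) {
    a <- 10^log_a
    sum((r2 - hill_weir_expectation(a * dist_bp, n))^2)
  }
  bounds <- log10(a_range)
  opt <- stats::optimize(rss, bounds, tol = 1e-8)
  # refine around the optimum; optimize() can stall on wide intervals
  w <- 0.5
  lo <- max(bounds[1], opt$minimum - w)
  hi <- min(bounds[2], opt$minimum + w)
  opt2 <- stats::optimize(rss, c(lo, hi), tol = 1e-12)
  if (opt2$objective < opt$objective) opt <- opt2
  a <- 10^opt$minimum
  boundary <- opt$minimum <= bounds[1] + 1e-6
  if (boundary || rss(bounds[1]) <= opt$objective + 1e-15) {
    # data never fall below the C = 0 plateau: no decay signal
    if (rss(bounds[1]) <= opt$objective + 1e-15) {
      a <- 0
      boundary <- TRUE
    }
    if (boundary) warning("Hill-Weir fit at a = 0 boundary: no decay signal")
  }
  structure(list(
    a = a, n = n, rss = rss(log10(max(a, a_range[1]))),
    predict = function(d) hill_weir_expectation(a * d, n),
    boundary = boundary
  ), class = "hill_weir_fit")
}

#' @export
print.hill_weir_fit <- function(x, ...) {
  cat(sprintf("hill_weir_fit: a = %.4g per bp, n = %d, rss = %.4g%s\n",
              x$a, as.integer(x$n), x$rss,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Distance at which fitted LD decays below a threshold
#'
#' Smallest distance at which the fitted Hill-Weir curve drops to or below
#' the threshold (conventionally r2 = 0.2, taken as absence of LD), found by
#' monotone bisection to sub-bp precision. Returns 0 when the curve starts
#' at or below the threshold and `Inf` (with a warning) when it never
#' crosses it.
#'
#' @param fit a [fit_hill_weir()] result.
#' @param threshold r2 level in (0, 1) (default 0.2).
#' @return distance in the units the fit was made in (bp by default).
#' @export
decay_distance <- function(fit, threshold = 0.2) {
  stopifnot(inherits(fit, "hill_weir_fit"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  f <- function(d) fit$predict(d) - threshold
  if (f(0) <= 0) return(0)
  hi <- 1
  while (f(hi) > 0 && hi < 1e15) hi <- hi * 2
  if (f(hi) > 0) {
    warning("fitted curve never crosses the threshold")
    return(Inf)
  }
  lo <- if (hi > 1) hi / 2 else 0
  while (hi - lo > 0.5) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Smoothed LD profile along a chromosome
#'
#' Two-stage summary of how LD evolves along the physical map: first, each
#' marker is assigned the mean r2 to all other markers within `radius`
#' (two-sided, excluding itself); second, the per-marker values are smoothed
#' with a centered rolling mean over `window` consecutive markers in map
#' order, truncated at the chromosome ends. Markers with no neighbour inside
#' the radius get a missing stage-1 value and are excluded from stage 2.
#'
#' @param ldm a [pairwise_r2()] result.
#' @param radius stage-1 neighbourhood half-width in bp (default 0.5 Mb).
#' @param window stage-2 rolling-window size in markers (default 30).
#' @return data.frame `marker`, `pos_bp`, `ld_local` (stage 1), `ld_smooth`
#'   (stage 2; equal to `ld_local` with a warning when the chromosome has
#'   fewer markers than `window`).
#' @export
ld_evolution <- function(ldm, radius = 5e5, window = 30L) {
  stopifnot(inherits(ldm, "ld_matrix"))
  m <- length(ldm$markers)
  local <- vapply(seq_len(m), function(i) {
    nb <- which(abs(ldm$pos_bp - ldm$pos_bp[i]) <= radius)
    nb <- setdiff(nb, i)
    if (!length(nb)) return(NA_real_)
    v <- ldm$r2[i, nb]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(marker = ldm$markers, pos_bp = ldm$pos_bp,
                    ld_local = local, ld_smooth = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- which(!is.na(local))
  if (length(ok) < window) {
    warning("fewer markers than the window size: profile left unsmoothed")
    out$ld_smooth[ok] <- local[ok]
    return(out)
  }
  v <- local[ok]
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  sm <- vapply(seq_along(v), function(i) {
    mean(v[max(1L, i - half_lo):min(length(v), i + half_hi)])
  }, numeric(1))
  out$ld_smooth[ok] <- sm
  out
}
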