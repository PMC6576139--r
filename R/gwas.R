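#' Genomic kinship matrix
#'
#' Centered-dosage cross-product scaled by marker count (VanRaden-type):
#' missing dosages are imputed with the per-marker mean, columns are
#' centered, and `K = X X' / m`. A diagonal jitter of 1e-6 guarantees
#' positive semi-definiteness after rounding error.
#'
#' @param g a [nam_geno()] object (founder rows excluded) or dosage matrix.
#' @param jitter diagonal ridge (default 1e-6).
#' @return symmetric PSD matrix with sample dimnames.
#' @export
kinship <- function(g, jitter = 1e-6) {
  x <- if (inherits(g, "nam_geno")) geno_dosage(ril_only(g)) else g
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  xc <- sweep(x, 2L, colMeans(x))
  if (all(abs(xc) < 1e-12)) stop("degenerate genotypes: all markers constant")
  K <- tcrossprod(xc) / ncol(x)
  K <- (K + t(K)) / 2 + diag(jitter, nrow(K))
  dimnames(K) <- list(rownames(x), rownames(x))
  K
}

# REML log-likelihood of delta = sigma2_e / sigma2_g, profiled out,
# after rotation by the eigenvectors of K (EMMA-style)
reml_loglik_delta <- function(log_delta, lambda, ys, Xs) {
  delta <- exp(log_delta)
  w <- 1 / (lambda + delta)
  XtWX <- crossprod(Xs, Xs * w)
  XtWy <- crossprod(Xs, ys * w)
  beta <- solve(XtWX, XtWy)
  res <- ys - Xs %*% beta
  rss <- sum(w * res^2)
  n <- length(ys)
  q <- ncol(Xs)
  df <- n - q
  -0.5 * (df * log(2 * pi * rss / df) + df +
            sum(log(lambda + delta)) +
            determinant(XtWX, logarithm = TRUE)$modulus[1])
}

#' Kinship mixed-linear-model association scan (EMMA)
#'
#' Single-marker mixed-model GWAS: the variance components of
#' `y = Xb + u + e`, `u ~ N(0, sigma2_g K)`, are estimated once under the
#' null by maximizing the REML likelihood profiled over
#' `delta = sigma2_e / sigma2_g` on the spectral decomposition of K
#' (the EMMA device); each marker is then tested by generalized least
#' squares with an intercept and `n_pcs` principal-component covariates,
#' with Wald (t) p-values and the allele-substitution effect in trait
#' units. Markers with minor-allele frequency below `min_maf` are skipped
#' and logged. With `K = I` and no covariates the scan reduces exactly to
#' ordinary least squares.
#'
#' @param y named numeric vector of phenotypes (e.g. BLUPs from
#'   [fit_trial_model()]), names matching sample ids of `g`.
#' @param g a [nam_geno()] object or dosage matrix (samples x markers).
#' @param K kinship matrix from [kinship()] (defaults to computing it from
#'   `g`).
#' @param n_pcs number of principal-component covariates (default 3; the
#'   PCs are computed from the same genotype matrix as K).
#' @param min_maf minimum minor-allele frequency for a marker to be tested
#'   (default 0.01).
#' @return data.frame of class `mlm_scan`: `marker`, `effect`, `se`, `p`,
#'   `maf`; attributes `delta`, `sigma2_g`, `sigma2_e`, `skipped` (marker
#'   ids below the MAF floor).
#' @export
mlm_scan <- function(y, g, K = NULL, n_pcs = 3L, min_maf = 0.01) {
  x <- if (inherits(g, "nam_geno")) geno_dosage(ril_only(g)) else g
  ids <- intersect(names(y), rownames(x))
  if (length(ids) < 10L) stop("too few samples shared between y and g")
  x <- x[ids, , drop = FALSE]
  y <- y[ids]
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  if (is.null(K)) K <- kinship(x)
  K <- K[ids, ids]
  n <- length(ids)

  X0 <- matrix(1, n, 1)
  if (n_pcs > 0L) {
    pc <- geno_pca(x, n_pcs = n_pcs)
    X0 <- cbind(X0, pc$scores[, seq_len(min(n_pcs, ncol(pc$scores))),
                              drop = FALSE])
  }

  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  X0s <- crossprod(U, X0)

  opt <- stats::optimize(function(ld) -reml_loglik_delta(ld, lambda, ys, X0s),
                         c(-12, 12), tol = 1e-8)
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)
  # REML scale under the null
  XtWX <- crossprod(X0s, X0s * w)
  beta0 <- solve(XtWX, crossprod(X0s, ys * w))
  rss0 <- sum(w * (ys - X0s %*% beta0)^2)
  sigma2_g <- rss0 / (n - ncol(X0))
  sigma2_e <- delta * sigma2_g

  f <- colMeans(x) / 2
  maf <- pmin(f, 1 - f)
  test <- which(maf >= min_maf)
  skipped <- colnames(x)[maf < min_maf]

  Xs_all <- crossprod(U, x[, test, drop = FALSE])
  q1 <- ncol(X0) + 1L
  eff <- se <- pv <- rep(NA_real_, length(test))
  for (k in seq_along(test)) {
    Xs <- cbind(X0s, Xs_all[, k])
    XtWX <- crossprod(Xs, Xs * w)
    sol <- tryCatch(solve(XtWX, crossprod(Xs, ys * w)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    res <- ys - Xs %*% sol
    rss <- sum(w * res^2)
    s2 <- rss / (n - q1)
    vb <- s2 * solve(XtWX)[q1, q1]
    eff[k] <- sol[q1]
    se[k] <- sqrt(vb)
    pv[k] <- 2 * stats::pt(abs(eff[k] / se[k]), df = n - q1,
                           lower.tail = FALSE)
  }
  out <- data.frame(marker = colnames(x)[test], effect = eff, se = se,
                    p = pv, maf = maf[test], stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  attr(out, "sigma2_g") <- sigma2_g
  attr(out, "sigma2_e") <- sigma2_e
  attr(out, "skipped") <- skipped
  class(out) <- c("mlm_scan", "data.frame")
  out
}

#' Call QTNs at a Bonferroni threshold
#'
#' Markers with `p < alpha / n_markers` are significant. Markers significant
#' for several traits are reported once, with the traits comma-joined, so
#' the QTN count is over unique markers.
#'
#' @param scans data.frame stacking per-trait scan results, with columns
#'   `marker`, `trait`, `p`, `effect` (and optionally `chrom`, `pos_bp`).
#' @param n_markers Bonferroni denominator: number of markers tested.
#' @param alpha nominal familywise level (default 0.1).
#' @return data.frame `marker`, `traits`, `min_p`, `effects` (per-trait,
#'   comma-joined in trait order), plus position columns when present;
#'   attribute `cutoff` holds `alpha / n_markers`.
#' @export
call_qtns <- function(scans, n_markers, alpha = 0.1) {
  stopifnot(all(c("marker", "trait", "p", "effect") %in% names(scans)))
  cutoff <- alpha / n_markers
  sig <- scans[!is.na(scans$p) & scans$p < cutoff, , drop = FALSE]
  if (nrow(sig) == 0L) {
    out <- data.frame(marker = character(0), traits = character(0),
                      min_p = numeric(0), effects = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  sig <- sig[order(sig$trait), , drop = FALSE]
  mk <- unique(sig$marker)
  rows <- lapply(mk, function(m) {
    s <- sig[sig$marker == m, , drop = FALSE]
    r <- data.frame(marker = m,
                    traits = paste(unique(s$trait), collapse = ", "),
                    min_p = min(s$p),
                    effects = paste(signif(s$effect, 4), collapse = ", "),
                    stringsAsFactors = FALSE)
    for (col in c("chrom", "pos_bp")) {
      if (col %in% names(s)) r[[col]] <- s[[col]][1]
    }
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Gene models within a window of each QTN
#'
#' Looks up protein-coding gene models whose span intersects the closed
#' interval `[pos - window, pos + window]` around each QTN (default
#' +/- 500 kb), from a GFF3 annotation. Coordinates are 1-based inclusive
#' on both sides, matching the GFF3 convention.
#'
#' @param qtns data.frame with columns `marker`, `chrom`, `pos_bp`.
#' @param annotation path to a GFF3 file, or a `GRanges` of gene models
#'   (with `type == "gene"` rows; a `biotype`/`gene_biotype` column
#'   restricts to protein-coding when present).
#' @param window half-width in bp (default 500 kb).
#' @return list with `per_qtn` (data.frame `marker`, `gene_id`, `chrom`,
#'   `start`, `end`) and `unique_genes` (character vector over all QTNs).
#' @export
genes_near_qtns <- function(qtns, annotation, window = 5e5) {
  stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(qtns)))
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation)
  } else annotation
  if (!is.null(gr$type)) gr <- gr[gr$type == "gene"]
  bt <- gr$biotype %||% gr$gene_biotype
  if (!is.null(bt)) gr <- gr[!is.na(bt) & bt == "protein_coding"]
  gene_id <- gr$ID %||% gr$gene_id %||% gr$Name
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_along(gr))

  if (nrow(qtns) == 0L) {
    return(list(per_qtn = data.frame(marker = character(0),
                                     gene_id = character(0),
                                     chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     stringsAsFactors = FALSE),
                unique_genes = character(0)))
  }
  ann_chr <- as.character(GenomicRanges::seqnames(gr))
  missing_chr <- setdiff(unique(qtns$chrom), unique(ann_chr))
  if (length(missing_chr)) {
    stop("QTN chromosomes absent from the annotation: ",
         paste(missing_chr, collapse = ", "))
  }
  win <- GenomicRanges::GRanges(
    qtns$chrom,
    IRanges::IRanges(pmax(1, qtns$pos_bp - window), qtns$pos_bp + window)
  )
  hits <- GenomicRanges::findOverlaps(win, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  per_qtn <- data.frame(
    marker = qtns$marker[qh],
    gene_id = gene_id[sh],
    chrom = ann_chr[sh],
    start = GenomicRanges::start(gr)[sh],
    end = GenomicRanges::end(gr)[sh],
    stringsAsFactors = FALSE
  )
  list(per_qtn = per_qtn, unique_genes = unique(per_qtn$gene_id))
}
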