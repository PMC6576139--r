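#' Build a genome model for NAM simulation
#'
#' A genome model couples a physical coordinate frame (bp) with a genetic one
#' (cM) for a set of marker loci. Genetic positions may be supplied directly
#' or derived by piecewise-linear interpolation between anchor points; with
#' only the chromosome ends as anchors this reduces to proportional scaling.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `length_cm`; one row per chromosome.
#' @param markers data.frame with columns `marker`, `chrom`, `pos_bp` and
#'   optionally `pos_cm`. Positions must be strictly increasing within a
#'   chromosome. When `pos_cm` is absent it is interpolated from the anchors.
#' @param anchors optional data.frame with columns `chrom`, `pos_bp`,
#'   `pos_cm` giving intermediate interpolation anchors; the chromosome
#'   endpoints (0, 0) and (`length_bp`, `length_cm`) are always included.
#' @return object of class `genome_model`: list with elements `chromosomes`
#'   and `markers` (the latter with both `pos_bp` and `pos_cm` filled in).
#' @examples
#' gm <- genome_model(
#'   data.frame(chrom = "1A", length_bp = 1e8, length_cm = 150),
#'   data.frame(marker = c("m1", "m2"), chrom = "1A", pos_bp = c(1e6, 5e7))
#' )
#' gm$markers$pos_cm
#' @export
genome_model <- function(chromosomes, markers, anchors = NULL) {
  stopifnot(
    is.data.frame(chromosomes),
    all(c("chrom", "length_bp", "length_cm") %in% names(chromosomes)),
    is.data.frame(markers),
    all(c("marker", "chrom", "pos_bp") %in% names(markers))
  )
  if (nrow(chromosomes) < 1L) {
    stop("genome model needs at least one chromosome")
  }
  if (anyDuplicated(chromosomes$chrom)) {
    stop("duplicated chromosome names")
  }
  if (anyDuplicated(markers$marker)) {
    stop("duplicated marker ids")
  }
  bad <- setdiff(markers$chrom, chromosomes$chrom)
  if (length(bad)) {
    stop("markers on unknown chromosomes: ", paste(bad, collapse = ", "))
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  markers$marker <- as.character(markers$marker)
  # sort by chromosome (input order) then position
  ord <- order(match(markers$chrom, chromosomes$chrom), markers$pos_bp)
  markers <- markers[ord, , drop = FALSE]

  if (!"pos_cm" %in% names(markers)) {
    markers$pos_cm <- rep(NA_real_, nrow(markers))
  }
  for (i in seq_len(nrow(chromosomes))) {
    cc <- chromosomes$chrom[i]
    idx <- which(markers$chrom == cc)
    if (!length(idx)) next
    bp <- markers$pos_bp[idx]
    if (any(bp < 1) || any(bp > chromosomes$length_bp[i])) {
      stop("marker positions outside chromosome ", cc)
    }
    if (any(diff(bp) <= 0)) {
      stop("marker bp positions not strictly increasing on ", cc)
    }
    if (anyNA(markers$pos_cm[idx])) {
      abp <- c(0, chromosomes$length_bp[i])
      acm <- c(0, chromosomes$length_cm[i])
      if (!is.null(anchors)) {
        ai <- which(anchors$chrom == cc)
        abp <- c(abp, anchors$pos_bp[ai])
        acm <- c(acm, anchors$pos_cm[ai])
        o <- order(abp)
        abp <- abp[o]
        acm <- acm[o]
      }
      markers$pos_cm[idx] <- stats::approx(abp, acm, xout = bp)$y
    }
    cm <- markers$pos_cm[idx]
    if (any(cm < 0) || any(cm > chromosomes$length_cm[i])) {
      stop("marker cM positions outside the genetic map on ", cc)
    }
    if (any(diff(cm) < 0)) {
      stop("marker cM positions decreasing on ", cc)
    }
  }
  rownames(markers) <- NULL
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_model")
}

#' Wheat-like default genome for NAM simulation
#'
#' A tetraploid-wheat-like coordinate frame: 14 chromosomes (1A-7B) with
#' physical lengths of 580-850 Mb and genetic lengths of ~160 cM each, with
#' markers placed uniformly at random along the physical map. Marker counts
#' per chromosome are proportional to physical length.
#'
#' @param n_markers total number of marker loci (default 12000, the scale of
#'   a mid-density wheat genotyping array).
#' @param seed integer seed controlling marker placement.
#' @return a [genome_model()].
#' @export
wheat_genome <- function(n_markers = 12000, seed = 1L) {
  chrom <- paste0(rep(1:7, each = 2), rep(c("A", "B"), 7))
  len_mb <- c(594, 690, 781, 801, 750, 831, 744, 673,
              590, 707, 618, 721, 736, 750)
  chromosomes <- data.frame(
    chrom = chrom,
    length_bp = len_mb * 1e6,
    length_cm = round(110 + 70 * len_mb / max(len_mb)),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  n_per <- pmax(2L, round(n_markers * chromosomes$length_bp /
                            sum(chromosomes$length_bp)))
  mk <- do.call(rbind, lapply(seq_along(chrom), function(i) {
    pos <- sort(sample.int(chromosomes$length_bp[i] - 1L, n_per[i])) + 0
    data.frame(
      marker = sprintf("M_%s_%05d", chrom[i], seq_len(n_per[i])),
      chrom = chrom[i], pos_bp = pos, stringsAsFactors = FALSE
    )
  }))
  genome_model(chromosomes, mk)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %d markers, %.0f Mb / %.0f cM\n",
              nrow(x$chromosomes), nrow(x$markers),
              sum(x$chromosomes$length_bp) / 1e6,
              sum(x$chromosomes$length_cm)))
  invisible(x)
}

n_markers <- function(genome) nrow(genome$markers)

marker_index_by_chrom <- function(genome) {
  split(seq_len(nrow(genome$markers)), genome$markers$chrom)
}
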