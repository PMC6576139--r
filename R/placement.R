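#' Place array markers from alignments of their flanking sequences
#'
#' Reads a SAM/BAM file in which each read name is a marker id and derives
#' the physical map, applying the standard alignment filters: a marker is
#' kept iff its primary alignment is mapped with MAPQ >= `min_mapq`
#' (strictly, MAPQ < `min_mapq` is rejected), is not a secondary or
#' supplementary record, and carries no alternative-hit evidence. The latter
#' is operationalized as an XA or SA tag on the primary record, or more than
#' one non-secondary record sharing the read name. The position is the
#' 1-based leftmost mapping position of the primary alignment.
#'
#' @param path path to a SAM (or BAM) file.
#' @param min_mapq minimum mapping quality kept (default 10; MAPQ = 10 is
#'   kept).
#' @return list with `map` (data.frame `marker`, `chrom`, `pos_bp`,
#'   `strand`, `mapq`) and `rejected` (data.frame `marker`, `reason`). Every
#'   uniquely named input read appears in exactly one of the two.
#' @export
place_from_sam <- function(path, min_mapq = 10L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand"),
    tag = c("XA", "SA")
  )
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rec <- data.frame(
    marker = b$qname,
    flag = b$flag,
    chrom = as.character(b$rname),
    pos_bp = b$pos,
    mapq = b$mapq,
    strand = as.character(b$strand),
    has_alt = !is.na(b$tag$XA %||% rep(NA, length(b$qname))) |
      !is.na(b$tag$SA %||% rep(NA, length(b$qname))),
    stringsAsFactors = FALSE
  )
  rec$secondary <- bitwAnd(rec$flag, 256L) > 0L
  rec$supplementary <- bitwAnd(rec$flag, 2048L) > 0L
  rec$unmapped <- bitwAnd(rec$flag, 4L) > 0L

  markers <- unique(rec$marker)
  placed <- vector("list", length(markers))
  rejected <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    rr <- rec[rec$marker == mk, , drop = FALSE]
    prim <- rr[!rr$secondary & !rr$supplementary, , drop = FALSE]
    reason <- NULL
    if (nrow(prim) == 0L) {
      reason <- "no primary alignment"
    } else if (nrow(prim) > 1L) {
      reason <- "multiple hits (several non-secondary records)"
    } else if (prim$unmapped) {
      reason <- "unmapped"
    } else if (prim$has_alt) {
      reason <- "multiple hits (XA/SA tag)"
    } else if (nrow(rr) > nrow(prim)) {
      reason <- "secondary/supplementary alignments present"
    } else if (prim$mapq < min_mapq) {
      reason <- sprintf("MAPQ %d < %d", prim$mapq, min_mapq)
    }
    if (is.null(reason)) {
      placed[[i]] <- data.frame(marker = mk, chrom = prim$chrom,
                                pos_bp = prim$pos_bp, strand = prim$strand,
                                mapq = prim$mapq, stringsAsFactors = FALSE)
    } else {
      rejected[[i]] <- data.frame(marker = mk, reason = reason,
                                  stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, placed[!vapply(placed, is.null, logical(1))])
  rej <- do.call(rbind, rejected[!vapply(rejected, is.null, logical(1))])
  if (is.null(map)) {
    map <- data.frame(marker = character(0), chrom = character(0),
                      pos_bp = integer(0), strand = character(0),
                      mapq = integer(0), stringsAsFactors = FALSE)
  }
  if (is.null(rej)) {
    rej <- data.frame(marker = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  }
  map <- map[order(map$marker), , drop = FALSE]
  rownames(map) <- NULL
  list(map = map, rejected = rej)
}

#' Load a precomputed marker placement table
#'
#' @param path delimited text file (TSV/CSV autodetected by extension) with
#'   header columns `marker`, `chrom`, `pos_bp`.
#' @return data.frame physical map (`marker`, `chrom`, `pos_bp`).
#' @export
merge_placement_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty placement table")
    return(data.frame(marker = character(0), chrom = character(0),
                      pos_bp = numeric(0), stringsAsFactors = FALSE))
  }
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(df))) {
    stop("placement table must have columns: ", paste(need, collapse = ", "))
  }
  dup <- unique(df$marker[duplicated(df$marker)])
  if (length(dup)) {
    stop("duplicated marker ids in placement table: ",
         paste(utils::head(dup), collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(df$pos_bp))
  if (anyNA(pos)) stop("non-numeric positions in placement table")
  if (any(pos < 1)) stop("positions must be >= 1 (1-based)")
  data.frame(marker = as.character(df$marker),
             chrom = as.character(df$chrom), pos_bp = pos,
             stringsAsFactors = FALSE)
}

#' Physical map of a genome model
#'
#' @param genome a [genome_model()].
#' @return data.frame `marker`, `chrom`, `pos_bp` — the ground-truth
#'   placements of the simulated markers.
#' @export
genome_map <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  data.frame(marker = genome$markers$marker, chrom = genome$markers$chrom,
             pos_bp = genome$markers$pos_bp, stringsAsFactors = FALSE)
}

#' Write a synthetic SAM file of marker flanking-sequence alignments
#'
#' Emits one alignment per marker of the genome model at its true position
#' (MAPQ 60), then degrades a chosen fraction of markers into records that
#' the placement filters must reject: low MAPQ, an added secondary
#' alignment, an XA alternative-hit tag, or a duplicated non-secondary
#' record. The expected per-marker outcome is returned so placement can be
#' validated against known truth.
#'
#' @param genome a [genome_model()].
#' @param path output SAM path.
#' @param low_mapq_frac,secondary_frac,xa_frac,multihit_frac fractions of
#'   markers degraded by each mechanism (disjoint sets).
#' @param seed seed for choosing the degraded markers.
#' @return invisibly, a data.frame `marker`, `expected` with values
#'   `"placed"` or `"rejected"`.
#' @export
write_marker_sam <- function(genome, path, low_mapq_frac = 0.05,
                             secondary_frac = 0.05, xa_frac = 0.05,
                             multihit_frac = 0.05, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  set.seed(seed)
  mk <- genome$markers
  n <- nrow(mk)
  fracs <- c(low_mapq_frac, secondary_frac, xa_frac, multihit_frac)
  if (sum(fracs) > 1) stop("degradation fractions exceed 1")
  n_bad <- floor(fracs * n)
  bad <- sample.int(n, sum(n_bad))
  grp <- rep(c("low_mapq", "secondary", "xa", "multihit"), n_bad)
  kind <- rep("clean", n)
  kind[bad] <- grp

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chromosomes$chrom,
                   as.integer(genome$chromosomes$length_bp)))
  rec_line <- function(name, flag, chrom, pos, mapq, tag = NULL) {
    base <- sprintf("%s\t%d\t%s\t%d\t%d\t100M\t*\t0\t0\t*\t*",
                    name, flag, chrom, as.integer(pos), mapq)
    if (!is.null(tag)) base <- paste0(base, "\t", tag)
    base
  }
  lines <- character(0)
  for (i in seq_len(n)) {
    nm <- mk$marker[i]
    cc <- mk$chrom[i]
    pp <- mk$pos_bp[i]
    other <- sample(setdiff(genome$chromosomes$chrom, cc), 1L)
    lines <- c(lines, switch(
      kind[i],
      clean = rec_line(nm, 0L, cc, pp, 60L),
      low_mapq = rec_line(nm, 0L, cc, pp,
                          sample(0:9, 1L)),
      secondary = c(rec_line(nm, 0L, cc, pp, 60L),
                    rec_line(nm, 256L, other, max(1, pp %/% 2), 0L)),
      xa = rec_line(nm, 0L, cc, pp, 60L,
                    sprintf("XA:Z:%s,+%d,100M,2;", other, max(1, pp %/% 3))),
      multihit = c(rec_line(nm, 0L, cc, pp, 60L),
                   rec_line(nm, 0L, other, max(1, pp %/% 2), 60L))
    ))
  }
  writeLines(c(hdr, lines), path)
  invisible(data.frame(
    marker = mk$marker,
    expected = ifelse(kind == "clean", "placed", "rejected"),
    kind = kind, stringsAsFactors = FALSE
  ))
}
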