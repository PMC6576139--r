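#' Genotype matrix container
#'
#' The central object of the pipeline: a samples x markers table of biallelic
#' calls coded `"AA"`, `"AB"`, `"BB"` or `NA` (missing), with a family label
#' per sample and an optional flag marking founder rows. Founder rows carry
#' the parental lines themselves and are excluded from RIL-level statistics.
#'
#' @param calls character matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids); entries in
#'   `c("AA","AB","BB", NA)`.
#' @param family character vector of family labels, one per sample.
#' @param is_founder logical vector, one per sample; defaults to all FALSE.
#' @return object of class `nam_geno`.
#' @export
nam_geno <- function(calls, family, is_founder = NULL) {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must have sample rownames and marker colnames")
  }
  ok <- calls %in% c("AA", "AB", "BB") | is.na(calls)
  if (!all(ok)) {
    stop("invalid genotype codes: ",
         paste(utils::head(unique(calls[!ok])), collapse = ", "))
  }
  family <- as.character(family)
  if (length(family) != nrow(calls)) {
    stop("family labels must match the number of samples")
  }
  if (any(is.na(family) | family == "")) {
    stop("family labels must be non-empty")
  }
  if (is.null(is_founder)) is_founder <- rep(FALSE, nrow(calls))
  stopifnot(length(is_founder) == nrow(calls))
  structure(
    list(calls = calls, family = family, is_founder = is_founder),
    class = "nam_geno"
  )
}

#' @export
print.nam_geno <- function(x, ...) {
  cat(sprintf(
    "nam_geno: %d samples (%d founders) x %d markers, %d families, %.1f%% missing\n",
    nrow(x$calls), sum(x$is_founder), ncol(x$calls),
    length(unique(x$family[!x$is_founder])),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.nam_geno <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [nam_geno()] object.
#' @param i,j sample and marker indices (any standard matrix index).
#' @param ... ignored.
#' @export
`[.nam_geno` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, rownames(x$calls))
  ii <- seq_len(nrow(x$calls))[i]
  nam_geno(x$calls[i, j, drop = FALSE], x$family[ii], x$is_founder[ii])
}

#' Allele-dosage coding of a genotype matrix
#'
#' Codes each call as the count of the B allele: AA = 0, AB = 1, BB = 2,
#' missing = NA. Dosages are the working representation for LD, kinship,
#' PCA and association scans.
#'
#' @param g a [nam_geno()] object or a character matrix of calls.
#' @return numeric matrix of the same shape.
#' @export
geno_dosage <- function(g) {
  calls <- if (inherits(g, "nam_geno")) g$calls else g
  d <- matrix(NA_real_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  d[calls == "AA"] <- 0
  d[calls == "AB"] <- 1
  d[calls == "BB"] <- 2
  d
}

#' RIL-only view of a genotype matrix
#'
#' @param g a [nam_geno()] object.
#' @return the same object with founder rows dropped.
#' @export
ril_only <- function(g) {
  stopifnot(inherits(g, "nam_geno"))
  g[!g$is_founder, ]
}

#' Read / write genotype tables
#'
#' Tab-separated plain text: first three columns `sample`, `family`,
#' `is_founder`, then one column per marker with calls AA/AB/BB and missing
#' cells coded `NA`.
#'
#' @param g a [nam_geno()] object.
#' @param path file path.
#' @return `read_geno_tsv` returns a [nam_geno()]; `write_geno_tsv` returns
#'   `path` invisibly.
#' @export
write_geno_tsv <- function(g, path) {
  stopifnot(inherits(g, "nam_geno"))
  df <- data.frame(sample = rownames(g$calls), family = g$family,
                   is_founder = g$is_founder, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(g$calls, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  calls <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(calls) <- df$sample
  nam_geno(calls, df$family, as.logical(df$is_founder))
}
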