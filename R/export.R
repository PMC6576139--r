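#' Export a simulated NAM dataset as tab-separated tables
#'
#' Writes everything downstream stages consume, all plain text: the
#' genotype table (`genotypes.tsv`, see [write_geno_tsv()]), the true
#' marker placements (`placements.tsv`), the ground-truth founder-origin
#' mosaics per family (`truth_<family>.tsv`, one row per RIL with the
#' diploid RF-origin count at each marker), and optionally a phenotype
#' table (`phenotypes.tsv`) when trial records are supplied.
#'
#' @param nam result of [simulate_nam()].
#' @param dir output directory (created if missing).
#' @param phenotypes optional data.frame of trial records from
#'   [simulate_trial()].
#' @return invisibly, the vector of files written.
#' @export
export_nam_dataset <- function(nam, dir, phenotypes = NULL) {
  stopifnot(is.list(nam), !is.null(nam$geno), !is.null(nam$truth))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "genotypes.tsv")
  write_geno_tsv(nam$geno, f)
  files <- c(files, f)
  f <- file.path(dir, "placements.tsv")
  utils::write.table(genome_map(nam$truth$genome), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  for (fam in names(nam$truth$families)) {
    tf <- nam$truth$families[[fam]]
    tr <- as.data.frame(tf$origin1 + tf$origin2)
    tr <- cbind(sample = rownames(tf$origin1), tr)
    f <- file.path(dir, paste0("truth_", fam, ".tsv"))
    utils::write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(phenotypes)) {
    f <- file.path(dir, "phenotypes.tsv")
    utils::write.table(phenotypes, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
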