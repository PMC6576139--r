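# compact genomes and genotype fixtures used across the suite

small_genome <- function(n_chrom = 2L, markers_per = 40L,
                         length_bp = 50e6, length_cm = 100, seed = 1L) {
  chrom <- paste0(seq_len(n_chrom), "A")
  chromosomes <- data.frame(chrom = chrom, length_bp = length_bp,
                            length_cm = length_cm)
  set.seed(seed)
  mk <- do.call(rbind, lapply(chrom, function(cc) {
    data.frame(marker = sprintf("%s_m%03d", cc, seq_len(markers_per)),
               chrom = cc,
               pos_bp = sort(sample.int(length_bp - 1L, markers_per)))
  }))
  genome_model(chromosomes, mk)
}

# two markers on one chromosome separated by d cM
two_locus_genome <- function(d_cm, length_cm = max(100, d_cm)) {
  length_bp <- 1e8
  genome_model(
    data.frame(chrom = "1A", length_bp = length_bp, length_cm = length_cm),
    data.frame(marker = c("L1", "L2"), chrom = "1A",
               pos_bp = c(1, round(length_bp * d_cm / length_cm))),
    anchors = NULL
  )
}

# build a nam_geno from a character matrix given as rows of calls
make_geno <- function(rows, family = NULL, is_founder = NULL,
                      markers = NULL) {
  calls <- do.call(rbind, rows)
  if (is.null(markers)) markers <- sprintf("mk%02d", seq_len(ncol(calls)))
  dimnames(calls) <- list(names(rows) %||% sprintf("s%02d",
                                                   seq_len(nrow(calls))),
                          markers)
  if (is.null(family)) family <- rep("F1", nrow(calls))
  nam_geno(calls, family, is_founder)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# neutral simulated NAM used by several tests
neutral_nam <- function(n_families = 3L, rils = 50L, n_markers = 80L,
                        seed = 11L, clean = TRUE) {
  gm <- small_genome(2L, n_markers %/% 2L, seed = seed)
  pan <- simulate_founders(gm, n_families + 1L, divergence = 0.6,
                           seed = seed + 1L)
  sim <- sim_config(
    n_families = n_families, rils_per_family = rils,
    missing_rate = if (clean) 0 else 0.03,
    het_error_rate = if (clean) 0 else 0.01,
    ascertainment_fraction = 0, seed = seed + 2L
  )
  nam <- simulate_nam(gm, pan, sim)
  list(genome = gm, panel = pan, sim = sim, nam = nam)
}

# 3-state selfing-with-selection Markov oracle: expected genotype class
# frequencies (RF hom, het, ALT hom) after k selfing generations from F1.
# Viability weights w = c(w_rfhom, w_het, w_althom) act by rejection
# resampling WITHIN a line (sibling seeds share the parent), so the
# offspring distribution is renormalized per parent genotype (row-wise).
selfing_markov <- function(k, w = c(1, 1, 1)) {
  p <- c(0, 1, 0)  # start at F1: all heterozygous
  step <- matrix(c(1, 0, 0,
                   1 / 4, 1 / 2, 1 / 4,
                   0, 0, 1), 3, 3, byrow = TRUE)
  stepw <- step * matrix(w, 3, 3, byrow = TRUE)
  rs <- rowSums(stepw)
  stepw[rs > 0, ] <- stepw[rs > 0, ] / rs[rs > 0]
  for (i in seq_len(k)) p <- drop(p %*% stepw)
  p / sum(p)
}
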