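#' Simulation configuration
#'
#' Bundles the knobs of the NAM breeding simulator. Defaults emulate a
#' durum-wheat NAM characterized at F6: 12 families of 100 RILs each derived
#' by single-seed descent through 5 selfing generations from the F1, typed on
#' a mid-density array with light missingness and heterozygote-call error.
#'
#' @param n_families number of biparental families (crosses to the recurrent
#'   founder).
#' @param rils_per_family RILs advanced per family.
#' @param generations_of_selfing selfing generations from the F1 (5 gives F6).
#' @param missing_rate per-call probability of a missing genotype.
#' @param het_error_rate per-call probability that a true homozygote is read
#'   as heterozygous.
#' @param ascertainment_fraction fraction of FV-private polymorphic markers
#'   masked to monomorphic by the array (ascertainment bias).
#' @param retry_cap maximum sibling-seed resamplings per line per generation
#'   under viability selection before the line is declared dead.
#' @param seed master seed; all substreams derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 12L, rils_per_family = 100L,
                       generations_of_selfing = 5L,
                       missing_rate = 0.02, het_error_rate = 0.005,
                       ascertainment_fraction = 0.15,
                       retry_cap = 100L, seed = 1L) {
  rates <- c(missing_rate, het_error_rate, ascertainment_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  stopifnot(generations_of_selfing >= 1L, n_families >= 1L,
            rils_per_family >= 1L)
  structure(list(
    n_families = as.integer(n_families),
    rils_per_family = as.integer(rils_per_family),
    generations_of_selfing = as.integer(generations_of_selfing),
    missing_rate = missing_rate, het_error_rate = het_error_rate,
    ascertainment_fraction = ascertainment_fraction,
    retry_cap = as.integer(retry_cap), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Viability-selection specification
#'
#' Describes selection acting during single-seed descent: at each selfing
#' generation, an offspring whose genotype at `locus` falls in the targeted
#' class is rejected with probability `s` and a sibling seed is drawn
#' instead (up to the configured retry cap, after which the line dies).
#'
#' @param chrom,pos_bp physical locus under selection; it is mapped to the
#'   nearest marker locus of the genome model.
#' @param s selection coefficient in \[0, 1\]; 0 is neutral, 1 kills the
#'   targeted class outright.
#' @param mode targeted genotype class, one of `"against_alt_hom"`,
#'   `"against_rf_hom"`, `"against_het"` (classes defined by founder origin).
#' @return list of class `selection_spec`.
#' @export
selection_spec <- function(chrom, pos_bp,
                           s, mode = c("against_alt_hom", "against_rf_hom",
                                       "against_het")) {
  if (s < 0 || s > 1) stop("selection coefficient must be in [0, 1]")
  mode <- match.arg(mode)
  structure(list(chrom = as.character(chrom), pos_bp = pos_bp,
                 s = s, mode = mode),
            class = "selection_spec")
}

# deterministic substream seed derived from the master seed
substream_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + k) %% 2147483629
  }
  as.integer(s) + 1L
}

#' Simulate a founder panel
#'
#' Founders are fully homozygous lines, so one haplotype per founder
#' suffices. The recurrent founder (RF) draws allele B with probability 1/2
#' per marker; every other founder differs from the RF at a marker with
#' probability given by `divergence`, independently across markers. The RF
#' and optionally the first `n_mv_alt` alternative founders are flagged as
#' modern varieties (MV); the rest are farmer varieties (FV), the
#' distinction that drives ascertainment masking.
#'
#' @param genome a [genome_model()].
#' @param n_founders number of founders including the RF (>= 2).
#' @param divergence probability (scalar or per-marker vector) that a
#'   non-RF founder carries the allele opposite to the RF at a marker.
#' @param n_mv_alt how many non-RF founders are MVs (default 1).
#' @param seed integer seed.
#' @return list of class `founder_panel` with elements `founder_ids`,
#'   `haplotypes` (founder x marker character matrix in \{"A","B"\}),
#'   `rf_id`, `type` (named "MV"/"FV").
#' @export
simulate_founders <- function(genome, n_founders, divergence = 0.6,
                              n_mv_alt = 1L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  m <- n_markers(genome)
  if (m == 0L) stop("degenerate genome: no marker loci")
  if (n_founders < 2L) stop("need at least two founders")
  if (any(divergence < 0 | divergence > 1)) {
    stop("divergence must be in [0, 1]")
  }
  div <- rep_len(divergence, m)
  set.seed(substream_seed(seed, 101L))
  ids <- c("RF", sprintf("ALT%02d", seq_len(n_founders - 1L)))
  rf <- ifelse(stats::runif(m) < 0.5, "B", "A")
  hap <- matrix("", n_founders, m, dimnames = list(ids, genome$markers$marker))
  hap[1L, ] <- rf
  flip <- c(A = "B", B = "A")
  for (i in seq_len(n_founders - 1L)) {
    differs <- stats::runif(m) < div
    hap[i + 1L, ] <- ifelse(differs, flip[rf], rf)
  }
  type <- c("MV", rep("FV", n_founders - 1L))
  if (n_mv_alt > 0L && n_founders > 1L) {
    type[1L + seq_len(min(n_mv_alt, n_founders - 1L))] <- "MV"
  }
  names(type) <- ids
  structure(list(founder_ids = ids, haplotypes = hap, rf_id = "RF",
                 type = type),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d founders (%d MV), RF = %s, %d markers\n",
              length(x$founder_ids), sum(x$type == "MV"), x$rf_id,
              ncol(x$haplotypes)))
  invisible(x)
}

# One meiosis over one chromosome for n lines at once.
# H1c, H2c: n x m matrices (phased haplotypes, any atomic type);
# cm: marker cM positions; len_cm: chromosome genetic length.
# Haldane model: crossover count ~ Poisson(len/100), breakpoints uniform
# on the genetic map, no interference.
meiosis_chrom <- function(H1c, H2c, cm, len_cm) {
  n <- nrow(H1c)
  out <- H1c
  k <- stats::rpois(n, len_cm / 100)
  start <- sample.int(2L, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (k[i] == 0L) {
      if (start[i] == 2L) out[i, ] <- H2c[i, ]
    } else {
      breaks <- sort(stats::runif(k[i], 0, len_cm))
      seg <- findInterval(cm, breaks)
      use2 <- xor(start[i] == 2L, seg %% 2L == 1L)
      out[i, use2] <- H2c[i, use2]
      out[i, !use2] <- H1c[i, !use2]
    }
  }
  out
}

#' Simulate one meiosis
#'
#' Draws a single gamete from a phased parental haplotype pair under the
#' Haldane model: per chromosome the crossover count is Poisson with mean
#' equal to the genetic length in Morgans, breakpoints fall uniformly on the
#' genetic map, and there is no interference. The gamete is a mosaic of the
#' two parental haplotypes.
#'
#' @param haplotypes 2 x m matrix (two phased haplotypes over the genome's
#'   markers, in map order).
#' @param genome a [genome_model()].
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return vector of length m, the gamete haplotype.
#' @examples
#' gm <- genome_model(
#'   data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
#'   data.frame(marker = c("m1", "m2"), chrom = "1A", pos_bp = c(1, 1e8))
#' )
#' meiosis(rbind(c("A", "A"), c("B", "B")), gm, seed = 1)
#' @export
meiosis <- function(haplotypes, genome, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            is.matrix(haplotypes), nrow(haplotypes) == 2L,
            ncol(haplotypes) == n_markers(genome))
  if (!is.null(seed)) set.seed(seed)
  out <- stats::setNames(haplotypes[1L, ], genome$markers$marker)
  idx <- marker_index_by_chrom(genome)
  for (cc in names(idx)) {
    j <- idx[[cc]]
    len <- genome$chromosomes$length_cm[genome$chromosomes$chrom == cc]
    g <- meiosis_chrom(haplotypes[1L, j, drop = FALSE],
                       haplotypes[2L, j, drop = FALSE],
                       genome$markers$pos_cm[j], len)
    out[j] <- g[1L, ]
  }
  out
}

# classify founder-origin genotype at one locus: 2 = RF hom, 1 = het,
# 0 = alt hom, given logical origin haplotypes (TRUE = RF origin)
origin_class <- function(o1, o2) as.integer(o1) + as.integer(o2)

targeted_class <- function(mode) {
  switch(mode, against_alt_hom = 0L, against_het = 1L, against_rf_hom = 2L)
}

#' Simulate one NAM family by single-seed descent
#'
#' Crosses the recurrent founder to an alternative founder, then advances
#' each RIL line independently through `generations_of_selfing` selfing
#' generations, keeping one offspring per line per generation (the one-seed
#' bottleneck is literal, so drift and residual heterozygosity are emergent).
#' Viability selection, if supplied, is applied by rejection sampling within
#' each line: a targeted offspring is discarded with probability `s` and a
#' sibling seed drawn instead, up to the retry cap; lines that exhaust the
#' cap die, and the family errors out if no line survives.
#'
#' @param panel a [simulate_founders()] panel.
#' @param alt_id id of the alternative founder crossed to the RF.
#' @param genome a [genome_model()].
#' @param sim a [sim_config()].
#' @param selection list of [selection_spec()] objects (possibly empty).
#' @param family_id label for the family (default the alt founder id).
#' @param seed seed for this family (default derived from `sim$seed`).
#' @return list with `calls` (RIL x marker character matrix), `origin1` and
#'   `origin2` (logical RIL x marker ground-truth mosaics, TRUE = RF origin),
#'   `family_id`, `alt_id`, `died` (ids of lines lost to selection).
#' @export
simulate_family <- function(panel, alt_id, genome, sim,
                            selection = list(), family_id = alt_id,
                            seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"), inherits(sim, "sim_config"))
  if (!alt_id %in% panel$founder_ids) stop("unknown founder: ", alt_id)
  if (inherits(selection, "selection_spec")) selection <- list(selection)
  m <- n_markers(genome)
  n <- sim$rils_per_family
  if (is.null(seed)) {
    seed <- substream_seed(sim$seed, match(alt_id, panel$founder_ids))
  }
  set.seed(seed)

  # map each selection locus to its nearest marker
  sel_idx <- vapply(selection, function(sp) {
    j <- which(genome$markers$chrom == sp$chrom)
    if (!length(j)) stop("selection locus on unknown chromosome ", sp$chrom)
    j[which.min(abs(genome$markers$pos_bp[j] - sp$pos_bp))]
  }, integer(1))

  # origin haplotypes: TRUE = RF origin; F1 is RF/ALT at every locus
  O1 <- matrix(TRUE, n, m)
  O2 <- matrix(FALSE, n, m)
  alive <- rep(TRUE, n)
  idx <- marker_index_by_chrom(genome)
  len_cm <- stats::setNames(genome$chromosomes$length_cm,
                            genome$chromosomes$chrom)

  self_once <- function(O1, O2, rows) {
    N1 <- O1[rows, , drop = FALSE]
    N2 <- O2[rows, , drop = FALSE]
    for (cc in names(idx)) {
      j <- idx[[cc]]
      N1[, j] <- meiosis_chrom(O1[rows, j, drop = FALSE],
                               O2[rows, j, drop = FALSE],
                               genome$markers$pos_cm[j], len_cm[[cc]])
      N2[, j] <- meiosis_chrom(O1[rows, j, drop = FALSE],
                               O2[rows, j, drop = FALSE],
                               genome$markers$pos_cm[j], len_cm[[cc]])
    }
    list(N1, N2)
  }

  for (gen in seq_len(sim$generations_of_selfing)) {
    rows <- which(alive)
    off <- self_once(O1, O2, rows)
    if (length(selection)) {
      # each line's offspring is tested once; a rejected line resamples a
      # sibling seed (new meiosis) and is re-tested, up to the retry cap
      tries <- rep(0L, length(rows))
      pending <- seq_along(rows)
      while (length(pending)) {
        rej <- rep(FALSE, length(pending))
        for (si in seq_along(selection)) {
          sp <- selection[[si]]
          cls <- origin_class(off[[1]][pending, sel_idx[si]],
                              off[[2]][pending, sel_idx[si]])
          hit <- cls == targeted_class(sp$mode)
          rej <- rej | (hit & stats::runif(length(pending)) < sp$s)
        }
        died <- rej & tries[pending] >= sim$retry_cap
        alive[rows[pending[died]]] <- FALSE
        resample <- pending[rej & !died]
        if (length(resample)) {
          redo <- self_once(O1, O2, rows[resample])
          off[[1]][resample, ] <- redo[[1]]
          off[[2]][resample, ] <- redo[[2]]
          tries[resample] <- tries[resample] + 1L
        }
        pending <- resample
      }
      rows_keep <- alive[rows]
      O1[rows[rows_keep], ] <- off[[1]][rows_keep, , drop = FALSE]
      O2[rows[rows_keep], ] <- off[[2]][rows_keep, , drop = FALSE]
    } else {
      O1[rows, ] <- off[[1]]
      O2[rows, ] <- off[[2]]
    }
    if (!any(alive)) {
      sp <- selection[[1]]
      stop(sprintf(
        "selection at %s:%d wiped out family %s: no RIL survived",
        sp$chrom, as.integer(sp$pos_bp), family_id))
    }
  }

  keep <- which(alive)
  O1 <- O1[keep, , drop = FALSE]
  O2 <- O2[keep, , drop = FALSE]
  rf_al <- panel$haplotypes[panel$rf_id, ]
  alt_al <- panel$haplotypes[alt_id, ]
  n_out <- length(keep)
  RF <- matrix(rf_al, n_out, m, byrow = TRUE)
  AL <- matrix(alt_al, n_out, m, byrow = TRUE)
  A1 <- ifelse(O1, RF, AL)
  A2 <- ifelse(O2, RF, AL)
  calls <- matrix(paste0(pmin(A1, A2), pmax(A1, A2)), n_out, m)
  ids <- sprintf("%s_%03d", family_id, keep)
  dimnames(calls) <- list(ids, genome$markers$marker)
  dimnames(O1) <- dimnames(O2) <- dimnames(calls)
  list(calls = calls, origin1 = O1, origin2 = O2,
       family_id = family_id, alt_id = alt_id,
       died = sprintf("%s_%03d", family_id, setdiff(seq_len(n), keep)))
}

#' Simulate a full NAM population
#'
#' Runs [simulate_family()] for the first `n_families` alternative founders
#' of the panel and assembles RILs plus founder rows into one [nam_geno()]
#' object. Founder rows carry the family label of their cross (the RF row is
#' labelled `"RF"`) and are flagged via `is_founder`.
#'
#' @param genome a [genome_model()].
#' @param panel a [simulate_founders()] panel with at least
#'   `sim$n_families + 1` founders.
#' @param sim a [sim_config()].
#' @param selection either a single list of [selection_spec()]s applied to
#'   every family, or a named list (by family id) of such lists.
#' @return list with `geno` (a [nam_geno()]) and `truth` (per-family output
#'   of [simulate_family()], plus `panel` and `genome`).
#' @export
simulate_nam <- function(genome, panel, sim, selection = list()) {
  alt_ids <- setdiff(panel$founder_ids, panel$rf_id)
  if (length(alt_ids) < sim$n_families) {
    stop("panel has fewer alternative founders than n_families")
  }
  alt_ids <- alt_ids[seq_len(sim$n_families)]
  fam_ids <- sprintf("Fam%02d", seq_along(alt_ids))
  per_family <- !is.null(names(selection))
  fams <- vector("list", length(alt_ids))
  for (i in seq_along(alt_ids)) {
    sel <- if (per_family) {
      selection[[fam_ids[i]]] %||% list()
    } else selection
    fams[[i]] <- simulate_family(panel, alt_ids[i], genome, sim,
                                 selection = sel, family_id = fam_ids[i])
  }
  calls <- do.call(rbind, lapply(fams, `[[`, "calls"))
  family <- rep(fam_ids, vapply(fams, function(f) nrow(f$calls), integer(1)))
  # founder rows: RF once, plus each family's alternative founder
  f_ids <- c(panel$rf_id, alt_ids)
  f_calls <- t(vapply(f_ids, function(id) {
    al <- panel$haplotypes[id, ]
    paste0(al, al)
  }, character(n_markers(genome))))
  dimnames(f_calls) <- list(c("RF", fam_ids), colnames(calls))
  rownames(f_calls) <- paste0("founder_", c("RF", fam_ids))
  all_calls <- rbind(f_calls, calls)
  geno <- nam_geno(
    all_calls,
    family = c("RF", fam_ids, family),
    is_founder = c(rep(TRUE, length(f_ids)), rep(FALSE, nrow(calls)))
  )
  names(fams) <- fam_ids
  list(geno = geno,
       truth = list(families = fams, panel = panel, genome = genome,
                    alt_of = stats::setNames(alt_ids, fam_ids)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Founder calls for one family
#'
#' Convenience accessor: the homozygous call vectors of the RF and of a
#' family's alternative founder, as stored in a founder panel.
#'
#' @param panel a [simulate_founders()] panel.
#' @param alt_id alternative founder id.
#' @return list with `rf` and `alt` call vectors (e.g. "AA"/"BB").
#' @export
founder_calls <- function(panel, alt_id) {
  rf <- panel$haplotypes[panel$rf_id, ]
  al <- panel$haplotypes[alt_id, ]
  list(rf = stats::setNames(paste0(rf, rf), names(rf)),
       alt = stats::setNames(paste0(al, al), names(al)))
}

#' Overlay array-genotyping artifacts on clean simulated calls
#'
#' Emulates what a genotyping array does to the truth, in three layers:
#' ascertainment masking (a fraction of FV-private polymorphic markers is
#' collapsed to the RF homozygote everywhere, as if the probe never saw the
#' exotic allele), heterozygote miscalls (true homozygotes flipped to AB),
#' and missingness. A marker is FV-private when every founder carrying its
#' non-RF allele is a farmer variety. All changes are logged.
#'
#' @param g a [nam_geno()] with clean calls.
#' @param sim a [sim_config()] supplying `missing_rate`, `het_error_rate`
#'   and `ascertainment_fraction`.
#' @param panel the [simulate_founders()] panel (needed to identify
#'   FV-private markers; may be `NULL` if `ascertainment_fraction` is 0).
#' @param seed seed (default derived from `sim$seed`).
#' @return list with `geno` (the perturbed [nam_geno()]) and `log` (counts
#'   and marker ids of each change class).
#' @export
inject_array_artifacts <- function(g, sim, panel = NULL, seed = NULL) {
  stopifnot(inherits(g, "nam_geno"), inherits(sim, "sim_config"))
  if (is.null(seed)) seed <- substream_seed(sim$seed, 777L)
  set.seed(seed)
  calls <- g$calls
  log <- list(masked_markers = character(0), n_het_flips = 0L,
              n_set_missing = 0L)

  if (sim$ascertainment_fraction > 0) {
    if (is.null(panel)) {
      stop("ascertainment masking needs the founder panel")
    }
    rf_al <- panel$haplotypes[panel$rf_id, ]
    others <- setdiff(panel$founder_ids, panel$rf_id)
    diff_mat <- panel$haplotypes[others, , drop = FALSE] !=
      matrix(rf_al, length(others), length(rf_al), byrow = TRUE)
    carriers_fv <- colSums(diff_mat & (panel$type[others] == "FV")) > 0
    carriers_mv <- colSums(diff_mat & (panel$type[others] == "MV")) > 0
    private_fv <- carriers_fv & !carriers_mv
    cand <- colnames(calls)[private_fv[colnames(calls)]]
    n_mask <- round(sim$ascertainment_fraction * length(cand))
    masked <- if (n_mask > 0) sample(cand, n_mask) else character(0)
    for (mk in masked) calls[, mk] <- paste0(rf_al[mk], rf_al[mk])
    log$masked_markers <- masked
  }

  if (sim$het_error_rate > 0) {
    hom <- which(calls %in% c("AA", "BB"))
    flip <- hom[stats::runif(length(hom)) < sim$het_error_rate]
    calls[flip] <- "AB"
    log$n_het_flips <- length(flip)
  }

  if (sim$missing_rate > 0) {
    obs <- which(!is.na(calls))
    drop <- obs[stats::runif(length(obs)) < sim$missing_rate]
    calls[drop] <- NA_character_
    log$n_set_missing <- length(drop)
  }

  list(geno = nam_geno(calls, g$family, g$is_founder), log = log)
}

#' Simulate a multi-environment alpha-lattice trial
#'
#' Generates plot observations under the generative model
#' \deqn{Y = \mu + G_a + L_b + GL_{ab} + b_i + c_j + r_k + \epsilon,}
#' where genotype effects and location effects are supplied, the
#' genotype-by-location terms, replications, columns within replication,
#' rows within replication and residuals are independent Gaussian draws
#' with the stated variances. Each location x replication holds every
#' genotype once, assigned at random to a rows x columns grid.
#'
#' @param genotype_effects named numeric vector, one effect per genotype.
#' @param locations character vector of location names.
#' @param n_reps replications per location.
#' @param varcomp named list/vector of variances: `gl` (genotype x
#'   location), `rep`, `col`, `row`, `resid`; missing entries default to 0.
#' @param location_effects named numeric vector (default all 0).
#' @param mu grand intercept.
#' @param n_rows,n_cols grid dimensions per replication; default the most
#'   square grid holding all genotypes.
#' @param trait trait name attached to the records.
#' @param seed integer seed.
#' @return data.frame of trial records: `genotype`, `location`, `rep`,
#'   `row`, `col`, `trait`, `value`.
#' @export
simulate_trial <- function(genotype_effects, locations = c("L1", "L2", "L3"),
                           n_reps = 2L,
                           varcomp = list(gl = 0, rep = 0, col = 0, row = 0,
                                          resid = 1),
                           location_effects = NULL, mu = 100,
                           n_rows = NULL, n_cols = NULL,
                           trait = "trait", seed = 1L) {
  vc <- list(gl = 0, rep = 0, col = 0, row = 0, resid = 0)
  vc[names(varcomp)] <- varcomp
  if (any(!is.finite(unlist(vc))) || any(unlist(vc) < 0)) {
    stop("variance components must be finite and non-negative")
  }
  gen <- names(genotype_effects)
  if (is.null(gen)) stop("genotype_effects must be named")
  ng <- length(gen)
  if (is.null(n_cols)) n_cols <- ceiling(sqrt(ng))
  if (is.null(n_rows)) n_rows <- ceiling(ng / n_cols)
  if (n_rows * n_cols < ng) stop("grid too small for the genotypes")
  if (is.null(location_effects)) {
    location_effects <- stats::setNames(rep(0, length(locations)), locations)
  }
  set.seed(seed)
  gl <- matrix(stats::rnorm(ng * length(locations), 0, sqrt(vc$gl)),
               ng, length(locations), dimnames = list(gen, locations))
  out <- vector("list", length(locations) * n_reps)
  k <- 0L
  for (loc in locations) {
    for (r in seq_len(n_reps)) {
      b <- stats::rnorm(1, 0, sqrt(vc$rep))
      ce <- stats::rnorm(n_cols, 0, sqrt(vc$col))
      re <- stats::rnorm(n_rows, 0, sqrt(vc$row))
      cells <- sample.int(n_rows * n_cols, ng)
      row_i <- ((cells - 1L) %% n_rows) + 1L
      col_i <- ((cells - 1L) %/% n_rows) + 1L
      y <- mu + genotype_effects + location_effects[[loc]] + gl[, loc] +
        b + ce[col_i] + re[row_i] +
        stats::rnorm(ng, 0, sqrt(vc$resid))
      k <- k + 1L
      out[[k]] <- data.frame(
        genotype = gen, location = loc, rep = r,
        row = row_i, col = col_i, trait = trait, value = unname(y),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
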