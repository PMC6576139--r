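test_that("genome model validates coordinates and interpolates linearly", {
  gm <- genome_model(
    data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
    data.frame(marker = c("a", "b", "c"), chrom = "1A",
               pos_bp = c(1e6, 5e7, 9e7))
  )
  expect_equal(gm$markers$pos_cm, c(1, 50, 90))
  expect_error(genome_model(
    data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
    data.frame(marker = c("a", "b"), chrom = "1A", pos_bp = c(5e7, 5e7))
  ), "strictly increasing")
  expect_error(genome_model(
    data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
    data.frame(marker = "a", chrom = "2B", pos_bp = 1)
  ), "unknown chromosome")
  expect_error(simulate_founders(genome_model(
    data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
    data.frame(marker = character(0), chrom = character(0),
               pos_bp = numeric(0))
  ), 2), "no marker loci")
})

test_that("founder panels respect the divergence specification", {
  gm <- small_genome(1L, 200L)
  # divergence 0: all founders identical, no polymorphism in any cross
  p0 <- simulate_founders(gm, 5L, divergence = 0, seed = 3)
  expect_true(all(p0$haplotypes == matrix(p0$haplotypes[1, ], 5, 200,
                                          byrow = TRUE)))
  # divergence 1: every marker polymorphic in every cross
  p1 <- simulate_founders(gm, 2L, divergence = 1, seed = 3)
  expect_true(all(p1$haplotypes[1, ] != p1$haplotypes[2, ]))
  # divergence 0.5: fraction differing from RF ~ Binomial(m, 0.5)
  p5 <- simulate_founders(gm, 51L, divergence = 0.5, seed = 4)
  frac <- mean(p5$haplotypes["ALT07", ] != p5$haplotypes["RF", ])
  se <- sqrt(0.25 / 200)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_true(all(p5$haplotypes %in% c("A", "B")))  # homozygous by design
  expect_identical(p5$rf_id, "RF")
})

test_that("meiosis follows the Haldane map function", {
  # homozygous parent: gamete equals either haplotype
  gm <- two_locus_genome(50)
  hp <- rbind(c("A", "B"), c("A", "B"))
  expect_identical(meiosis(hp, gm, seed = 1), c(L1 = "A", L2 = "B"))
  # zero map distance: no recombinants
  gm0 <- genome_model(
    data.frame(chrom = "1A", length_bp = 1e8, length_cm = 100),
    data.frame(marker = c("L1", "L2"), chrom = "1A", pos_bp = c(1, 2),
               pos_cm = c(0, 0))
  )
  set.seed(2)
  g0 <- replicate(500, {
    g <- meiosis(rbind(c("A", "A"), c("B", "B")), gm0)
    g[1] != g[2]
  })
  expect_equal(sum(g0), 0)
  # recombinant fraction r = 0.5 (1 - exp(-2d)) across distances
  set.seed(3)
  for (d in c(1, 10, 50, 100)) {
    gmd <- two_locus_genome(d)
    n <- 4000
    rec <- mean(replicate(n, {
      g <- meiosis(rbind(c("A", "A"), c("B", "B")), gmd)
      g[1] != g[2]
    }))
    r_exp <- 0.5 * (1 - exp(-2 * d / 100))
    se <- sqrt(r_exp * (1 - r_exp) / n)
    expect_lt(abs(rec - r_exp), max(4 * se, 0.004))
  }
})

test_that("single-seed descent leaves (1/2)^k residual heterozygosity", {
  gm <- small_genome(1L, 10L)
  pan <- simulate_founders(gm, 2L, divergence = 1, seed = 5)
  for (k in c(1L, 3L, 5L)) {
    sim <- sim_config(n_families = 1L, rils_per_family = 400L,
                      generations_of_selfing = k,
                      missing_rate = 0, het_error_rate = 0,
                      ascertainment_fraction = 0, seed = 20L + k)
    fam <- simulate_family(pan, "ALT01", gm, sim)
    het <- mean(fam$calls == "AB")
    p <- 0.5^k
    se <- sqrt(p * (1 - p) / length(fam$calls))
    # markers within a line are correlated, so allow a generous band
    expect_lt(abs(het - p), 6 * se + 0.01)
  }
})

test_that("neutral families segregate 50:50 for the founder alleles", {
  gm <- small_genome(1L, 5L)
  pan <- simulate_founders(gm, 2L, divergence = 1, seed = 6)
  sim <- sim_config(n_families = 1L, rils_per_family = 1000L,
                    missing_rate = 0, het_error_rate = 0,
                    ascertainment_fraction = 0, seed = 7L)
  fam <- simulate_family(pan, "ALT01", gm, sim)
  rf_freq <- colMeans((fam$origin1 + fam$origin2) / 2)
  se <- sqrt(0.25 / 1000)
  expect_true(all(abs(rf_freq - 0.5) < 4 * se))
})

test_that("viability selection matches the selfing Markov-chain oracle", {
  gm <- small_genome(1L, 5L)
  pan <- simulate_founders(gm, 2L, divergence = 1, seed = 8)
  locus <- gm$markers[3, ]
  n <- 800L
  for (cfg in list(
    list(mode = "against_alt_hom", s = 1, w = c(1, 1, 0)),
    list(mode = "against_het", s = 1, w = c(1, 0, 1)),
    list(mode = "against_alt_hom", s = 0.5, w = c(1, 1, 0.5))
  )) {
    sim <- sim_config(n_families = 1L, rils_per_family = n,
                      missing_rate = 0, het_error_rate = 0,
                      ascertainment_fraction = 0, seed = 31L)
    sel <- selection_spec(locus$chrom, locus$pos_bp, s = cfg$s,
                          mode = cfg$mode)
    fam <- simulate_family(pan, "ALT01", gm, sim, selection = list(sel))
    j <- which(colnames(fam$calls) == locus$marker)
    cls <- fam$origin1[, j] + fam$origin2[, j]  # 2 RF hom, 1 het, 0 ALT hom
    obs <- c(mean(cls == 2), mean(cls == 1), mean(cls == 0))
    expected <- selfing_markov(5L, cfg$w)
    for (z in 1:3) {
      se <- sqrt(max(expected[z] * (1 - expected[z]), 1e-4) / n)
      expect_lt(abs(obs[z] - expected[z]), 4 * se)
    }
    # s = 1: RF allele frequency significantly above 0.5
    if (cfg$mode == "against_alt_hom" && cfg$s == 1) {
      expect_gt(mean(cls) / 2, 0.5 + 4 * sqrt(0.25 / n))
    }
  }
})

test_that("lethal selection on every genotype class kills the family", {
  gm <- small_genome(1L, 5L)
  pan <- simulate_founders(gm, 2L, divergence = 1, seed = 8)
  locus <- gm$markers[3, ]
  sim <- sim_config(n_families = 1L, rils_per_family = 20L,
                    missing_rate = 0, het_error_rate = 0,
                    ascertainment_fraction = 0, retry_cap = 5L, seed = 9L)
  sel <- lapply(c("against_alt_hom", "against_rf_hom", "against_het"),
                function(m) selection_spec(locus$chrom, locus$pos_bp,
                                           s = 1, mode = m))
  expect_error(simulate_family(pan, "ALT01", gm, sim, selection = sel),
               "no RIL survived")
})

test_that("a fixed seed reproduces the simulation byte for byte", {
  fx1 <- neutral_nam(seed = 42L)
  fx2 <- neutral_nam(seed = 42L)
  expect_identical(fx1$nam$geno$calls, fx2$nam$geno$calls)
  expect_identical(fx1$nam$truth$families$Fam01$origin1,
                   fx2$nam$truth$families$Fam01$origin1)
  a1 <- inject_array_artifacts(fx1$nam$geno, fx1$sim, fx1$panel)
  a2 <- inject_array_artifacts(fx2$nam$geno, fx2$sim, fx2$panel)
  expect_identical(a1$geno$calls, a2$geno$calls)
})

test_that("array artifacts behave as specified", {
  fx <- neutral_nam(seed = 13L)
  g <- fx$nam$geno
  # all rates zero: identity
  sim0 <- sim_config(missing_rate = 0, het_error_rate = 0,
                     ascertainment_fraction = 0, seed = 1L)
  expect_identical(inject_array_artifacts(g, sim0, fx$panel)$geno$calls,
                   g$calls)
  # missingness ~ Binomial(n_calls, rate)
  simm <- sim_config(missing_rate = 0.2, het_error_rate = 0,
                     ascertainment_fraction = 0, seed = 2L)
  am <- inject_array_artifacts(g, simm, fx$panel)
  n_calls <- sum(!is.na(g$calls))
  n_miss <- sum(is.na(am$geno$calls)) - sum(is.na(g$calls))
  se <- sqrt(n_calls * 0.2 * 0.8)
  expect_lt(abs(n_miss - 0.2 * n_calls), 3 * se)
  # full ascertainment: every FV-private marker collapses to monomorphic
  sima <- sim_config(missing_rate = 0, het_error_rate = 0,
                     ascertainment_fraction = 1, seed = 3L)
  aa <- inject_array_artifacts(g, sima, fx$panel)
  pan <- fx$panel
  rf <- pan$haplotypes["RF", ]
  others <- setdiff(pan$founder_ids, "RF")
  carriers <- lapply(colnames(g$calls), function(mk) {
    others[pan$haplotypes[others, mk] != rf[mk]]
  })
  private <- vapply(carriers, function(cs) {
    length(cs) > 0 && all(pan$type[cs] == "FV")
  }, logical(1))
  expect_identical(sort(aa$log$masked_markers),
                   sort(colnames(g$calls)[private]))
  for (mk in aa$log$masked_markers) {
    expect_equal(unique(aa$geno$calls[, mk]), paste0(rf[mk], rf[mk]))
  }
  # rates outside [0, 1] rejected at configuration time
  expect_error(sim_config(missing_rate = 1.2), "rates")
})

test_that("trial simulation mirrors its generative model", {
  eff <- stats::setNames(c(-2, 0, 3), c("g1", "g2", "g3"))
  # all random variances zero, one location: phenotype = mu + effect
  tr <- simulate_trial(eff, locations = "L1", n_reps = 1,
                       varcomp = list(resid = 0), mu = 10, seed = 1)
  expect_equal(tr$value[match(c("g1", "g2", "g3"), tr$genotype)],
               c(8, 10, 13))
  # residual variance moment check
  eff2 <- stats::setNames(rep(0, 200), sprintf("g%03d", 1:200))
  tr2 <- simulate_trial(eff2, locations = c("A", "B", "C"), n_reps = 2,
                        varcomp = list(resid = 2.5), seed = 2)
  expect_lt(abs(stats::var(tr2$value) - 2.5) / 2.5, 0.15)
  # zero genotype variance: one-way ANOVA F close to 1
  fstat <- summary(stats::aov(value ~ genotype,
                              data = tr2))[[1]]$`F value`[1]
  expect_lt(abs(fstat - 1), 0.35)
  expect_error(simulate_trial(eff, varcomp = list(resid = NA)), "finite")
})
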