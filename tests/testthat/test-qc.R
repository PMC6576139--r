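test_that("sample filter applies strict call-rate and heterozygosity rules", {
  # 100 markers: easy percentages
  mk <- sprintf("mk%03d", 1:100)
  good <- rep("AA", 100)
  low_call <- c(rep("AA", 79), rep(NA, 21))          # 79% genotyped
  boundary_call <- c(rep("AA", 80), rep(NA, 20))     # exactly 80%
  high_het <- c(rep("AB", 21), rep("AA", 79))        # 21% heterozygous
  boundary_het <- c(rep("AB", 20), rep("AA", 80))    # exactly 20%
  g <- make_geno(list(s_good = good, s_low = low_call,
                      s_bcall = boundary_call, s_het = high_het,
                      s_bhet = boundary_het), markers = mk)
  fs <- filter_samples(g)
  expect_setequal(fs$removed$sample, c("s_low", "s_het"))
  expect_setequal(rownames(fs$geno$calls), c("s_good", "s_bcall", "s_bhet"))
  # brute-force tally agrees with the reported rates
  expect_equal(fs$removed$het_rate[fs$removed$sample == "s_het"],
               sum(high_het == "AB") / sum(!is.na(high_het)))
})

test_that("marker filter mirrors the sample rules column-wise", {
  rows <- c(rep(list(rep("AA", 4)), 79), rep(list(rep(NA_character_, 4)), 21))
  calls <- do.call(rbind, rows)
  # marker 1: genotyped in 79/100 samples -> removed
  # marker 2: boundary 80/100 -> retained; marker 3: clean; marker 4: all het
  calls[, 2] <- c(rep("AA", 80), rep(NA, 20))
  calls[, 3] <- "BB"
  calls[, 4] <- "AB"
  dimnames(calls) <- list(sprintf("s%03d", 1:100), sprintf("mk%d", 1:4))
  g <- nam_geno(calls, rep("F1", 100))
  fm <- filter_markers(g)
  expect_setequal(fm$removed$marker, c("mk1", "mk4"))
  expect_setequal(colnames(fm$geno$calls), c("mk2", "mk3"))
})

test_that("qc filtering is idempotent", {
  fx <- neutral_nam(seed = 21L, clean = FALSE)
  art <- inject_array_artifacts(fx$nam$geno,
                                sim_config(ascertainment_fraction = 0,
                                           seed = 4L), fx$panel)
  q1 <- qc_filter(art$geno)
  q2 <- qc_filter(q1$geno)
  expect_identical(q1$geno$calls, q2$geno$calls)
  expect_equal(nrow(q2$removed_samples), 0L)
  expect_equal(nrow(q2$removed_markers), 0L)
})

test_that("family statistics count polymorphism and het as defined", {
  # all RILs identical homozygotes: zero polymorphic
  g0 <- make_geno(rep(list(rep("AA", 10)), 5))
  expect_equal(family_stats(g0)$n_polymorphic, 0L)
  # AA, BB, missing at one marker: polymorphic
  g1 <- make_geno(list(c("AA", "AA"), c("BB", "AA"), c(NA, "AA")))
  expect_equal(family_stats(g1)$n_polymorphic, 1L)
  # AA + AB (hom class plus alternative allele): polymorphic
  g2 <- make_geno(list(c("AA", "AA"), c("AB", "AA")))
  expect_equal(family_stats(g2)$n_polymorphic, 1L)
  # singleton family flagged
  g3 <- make_geno(list(c("AA", "AA")), family = "solo")
  expect_true(family_stats(g3)$flagged)
})

test_that("family polymorphism matches the simulator truth tables", {
  fx <- neutral_nam(n_families = 2L, rils = 60L, seed = 31L)
  st <- family_stats(fx$nam$geno)
  pan <- fx$panel
  for (i in seq_len(nrow(st))) {
    alt <- fx$nam$truth$alt_of[[st$family[i]]]
    truth_poly <- sum(pan$haplotypes["RF", ] != pan$haplotypes[alt, ])
    # with 60 RILs essentially every founder-polymorphic marker segregates
    expect_lte(st$n_polymorphic[i], truth_poly)
    expect_gte(st$n_polymorphic[i], truth_poly - 2L)
  }
  # residual heterozygosity near (1/2)^5 of the polymorphic fraction
  poly_frac <- mean(pan$haplotypes["RF", ] != pan$haplotypes["ALT01", ])
  expect_lt(abs(st$mean_het_pct[1] / 100 - 0.5^5 * poly_frac), 0.02)
})

test_that("minor allele frequencies are frequencies of the rarer allele", {
  # monomorphic marker: MAF 0
  g0 <- make_geno(rep(list(c("AA", "BB")), 4))
  expect_equal(unname(maf_spectrum(g0)), c(0, 0))
  # AB contributes half to each allele
  g1 <- make_geno(list(c("AA"), c("AB")), markers = "m1")
  expect_equal(unname(maf_spectrum(g1)), 0.25)
  # all-missing marker undefined
  g2 <- make_geno(list(c("AA", NA), c("AA", NA)))
  expect_true(is.na(maf_spectrum(g2)[2]))
  # marker private to one of 12 equal families, fixed alternate there
  calls <- matrix("AA", 120, 1, dimnames = list(sprintf("s%03d", 1:120), "m"))
  fam <- rep(sprintf("F%02d", 1:12), each = 10)
  calls[fam == "F05", ] <- "BB"
  gp <- nam_geno(calls, fam)
  expect_equal(unname(maf_spectrum(gp)), 10 / 120 * 2 / 2)  # 0.0833
  # invariant: MAF in [0, 0.5] and unchanged under allele-label swap
  fx <- neutral_nam(seed = 41L)
  m1 <- maf_spectrum(fx$nam$geno)
  expect_true(all(m1 >= 0 & m1 <= 0.5, na.rm = TRUE))
  swapped <- fx$nam$geno$calls
  swapped[] <- c(AA = "BB", AB = "AB", BB = "AA")[swapped]
  m2 <- maf_spectrum(nam_geno(swapped, fx$nam$geno$family,
                              fx$nam$geno$is_founder))
  expect_equal(m1, m2)
})

test_that("family intersections follow UpSet exclusive semantics", {
  # single family
  one <- family_intersections(list(F1 = c("a", "b", "c")))
  expect_equal(one$count, 3L)
  # disjoint sets
  two <- family_intersections(list(F1 = c("a", "b"), F2 = "c"))
  expect_equal(two$count[two$families == "F1"], 2L)
  expect_equal(two$count[two$families == "F2"], 1L)
  expect_equal(two$count[two$families == "F1,F2"], 0L)
  # random 3-family fixture vs brute-force enumeration
  set.seed(5)
  mk <- sprintf("m%02d", 1:40)
  sets <- list(A = sample(mk, 25), B = sample(mk, 18), C = sample(mk, 30))
  it <- family_intersections(sets)
  u <- unique(unlist(sets))
  brute <- table(vapply(u, function(m) {
    paste(names(sets)[vapply(sets, function(s) m %in% s, logical(1))],
          collapse = ",")
  }, character(1)))
  for (i in seq_len(nrow(it))) {
    exp_n <- if (it$families[i] %in% names(brute)) {
      as.integer(brute[[it$families[i]]])
    } else 0L
    expect_equal(it$count[i], exp_n)
  }
  # counts over subsets sum to the union size
  expect_equal(sum(it$count), length(u))
})

test_that("snp density bins are half-open and complete", {
  map <- data.frame(marker = c("a", "b", "c"), chrom = "1A",
                    pos_bp = c(1, 10e6, 10e6 - 1))
  db <- snp_density_bins(map, bin_size = 10e6)
  # position 10 Mb falls in the second bin (half-open convention)
  expect_equal(db$n_markers, c(2L, 1L))
  expect_equal(db$bin_start, c(0, 10e6))
  # empty chromosome: all-zero bins when lengths are declared
  db2 <- snp_density_bins(map[0, ], bin_size = 10e6,
                          chrom_lengths = c(`2B` = 25e6))
  expect_equal(db2$n_markers, c(0L, 0L, 0L))
  # uniform fixture: 100 markers on 100 Mb, 10 bins, counts match a tally
  set.seed(9)
  pos <- sample.int(100e6, 100)
  map3 <- data.frame(marker = sprintf("m%03d", 1:100), chrom = "3A",
                     pos_bp = pos)
  poly <- map3$marker[1:40]
  db3 <- snp_density_bins(map3, polymorphic = poly, bin_size = 10e6,
                          chrom_lengths = c(`3A` = 100e6))
  expect_equal(nrow(db3), 10L)
  expect_equal(sum(db3$n_markers), 100L)
  tally <- table(factor(pos %/% 10e6, levels = 0:9))
  expect_equal(db3$n_markers, as.integer(tally))
  expect_equal(sum(db3$n_polymorphic), 40L)
})
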