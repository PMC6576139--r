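test_that("allele-sharing distance reproduces its defining cases", {
  g <- make_geno(list(
    a = c("AA", "BB", "AA"),
    b = c("AA", "BB", "AA"),   # identical: d = 0
    c = c("BB", "AA", "BB"),   # fully opposite: d = 1
    d = c("AB", "AB", "AB")    # half shared with homozygotes: d = 0.5
  ))
  D <- allele_sharing_distance(g)$d
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  expect_equal(D["a", "d"], 0.5)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # low shared-call pairs flagged; zero shared calls -> missing entry
  g2 <- make_geno(list(x = c("AA", NA), y = c(NA, "BB")))
  D2 <- allele_sharing_distance(g2)
  expect_true(is.na(D2$d["x", "y"]))
  expect_true(D2$low_confidence["x", "y"])
  # invariant to marker order and allele-label swap
  fx <- neutral_nam(seed = 81L)
  d1 <- allele_sharing_distance(fx$nam$geno)$d
  perm <- sample(ncol(fx$nam$geno$calls))
  d2 <- allele_sharing_distance(fx$nam$geno[, perm])$d
  expect_equal(d1, d2)
  swapped <- fx$nam$geno$calls
  swapped[] <- c(AA = "BB", AB = "AB", BB = "AA")[swapped]
  d3 <- allele_sharing_distance(nam_geno(swapped, fx$nam$geno$family,
                                         fx$nam$geno$is_founder))$d
  expect_equal(d1, d3)
})

test_that("neighbour joining recovers additive trees exactly", {
  # 4-taxon additive matrix from a known tree: topology and branch lengths
  tr <- ape::read.tree(text = "((a:1,b:2):1.5,c:3,d:0.5);")
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  mine <- nj_tree(D)
  expect_equal(phangorn::RF.dist(mine, ape::unroot(tr)), 0)
  # additivity round-trip: path distances reproduce the input matrix
  back <- ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-10)
  # 3 taxa: closed-form three-point star
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  star <- nj_tree(D3)
  len <- stats::setNames(star$edge.length,
                         star$tip.label[star$edge[, 2]])
  expect_equal(len[c("x", "y", "z")], c(x = 1, y = 2, z = 3))
  expect_error(nj_tree(D3[1:2, 1:2]), ">= 3 samples")
  Dna <- D3
  Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(nj_tree(Dna), "incomplete")
})

test_that("neighbour joining matches the reference implementation", {
  set.seed(17)
  for (i in 1:20) {
    n_tip <- sample(5:12, 1)
    rt <- ape::rtree(n_tip)
    D <- ape::cophenetic.phylo(rt)
    o <- sample(n_tip)
    D <- D[o, o]
    mine <- nj_tree(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("RIL families form monophyletic clusters in the NJ tree", {
  # family separation needs many independently segregating segments, so a
  # multi-chromosome genome; monophyly on an unrooted tree is assessed
  # after rooting with an out-of-family tip
  ok <- 0L
  for (rep in 1:3) {
    gm <- small_genome(10L, 30L, seed = 200L + rep)
    pan <- simulate_founders(gm, 4L, divergence = 0.6, seed = 201L + rep)
    sim <- sim_config(n_families = 3L, rils_per_family = 12L,
                      missing_rate = 0, het_error_rate = 0,
                      ascertainment_fraction = 0, seed = 202L + rep)
    r <- ril_only(simulate_nam(gm, pan, sim)$geno)
    tr <- nj_tree(allele_sharing_distance(r)$d)
    mono <- vapply(unique(r$family), function(f) {
      tips <- rownames(r$calls)[r$family == f]
      out <- rownames(r$calls)[r$family != f][1]
      ape::is.monophyletic(ape::root(tr, outgroup = out,
                                     resolve.root = TRUE), tips)
    }, logical(1))
    ok <- ok + all(mono)
  }
  expect_gte(ok, 2L)
})

test_that("PCA explains variance like its eigendecomposition oracle", {
  # identical rows: zero variance, no scores
  g0 <- make_geno(rep(list(c("AA", "BB", "AA")), 4))
  expect_warning(p0 <- geno_pca(g0), "zero variance")
  expect_equal(length(p0$explained), 0L)
  # well-separated families split on PC1 (multi-chromosome genome so the
  # between-family axis dominates within-family segregation noise)
  gm <- small_genome(10L, 30L, seed = 95L)
  pan <- simulate_founders(gm, 3L, divergence = 0.6, seed = 96L)
  simc <- sim_config(n_families = 2L, rils_per_family = 30L,
                     missing_rate = 0, het_error_rate = 0,
                     ascertainment_fraction = 0, seed = 97L)
  r <- ril_only(simulate_nam(gm, pan, simc)$geno)
  pc <- geno_pca(r)
  s1 <- pc$scores[r$family == "Fam01", 1]
  s2 <- pc$scores[r$family == "Fam02", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # explained fractions: non-increasing, sum <= 1, equal eigenvalue ratios
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  x <- geno_dosage(r)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pc$explained[1:5], (ev / sum(ev))[1:5], tolerance = 1e-8)
  # scores invariant (up to sign) to sample order
  perm <- sample(nrow(r$calls))
  pc2 <- geno_pca(r[perm, ])
  for (k in 1:3) {
    a <- pc$scores[rownames(pc2$scores), k]
    expect_true(isTRUE(all.equal(a, pc2$scores[, k], tolerance = 1e-6)) ||
                  isTRUE(all.equal(a, -pc2$scores[, k], tolerance = 1e-6)))
  }
})

test_that("misassigned samples are flagged against the simulator truth", {
  fx <- neutral_nam(n_families = 3L, rils = 25L, n_markers = 120L,
                    seed = 99L)
  g <- ril_only(fx$nam$geno)
  # clean labels: no flags
  expect_equal(nrow(flag_misassigned(g)), 0L)
  # relabel one Fam01 RIL into Fam02: flagged, with Fam01 nearest
  fam <- g$family
  victim <- which(fam == "Fam01")[1]
  fam[victim] <- "Fam02"
  g_bad <- nam_geno(g$calls, fam)
  fl <- flag_misassigned(g_bad)
  expect_true(rownames(g$calls)[victim] %in% fl$sample)
  expect_equal(fl$nearest_family[fl$sample == rownames(g$calls)[victim]],
               "Fam01")
  # an impossible margin flags nothing
  expect_equal(nrow(flag_misassigned(g_bad, margin = 1)), 0L)
  # singleton families are skipped with a warning
  fam2 <- g$family
  fam2[1] <- "Solo"
  expect_warning(flag_misassigned(nam_geno(g$calls, fam2)), "singleton")
})
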