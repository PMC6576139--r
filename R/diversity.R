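#' Allele-sharing genetic distance
#'
#' Pairwise dissimilarity d(i,j) = 1 - mean shared-allele fraction over
#' pairwise-complete markers, where identical homozygotes share 1, a
#' homozygote and a heterozygote share 0.5, and opposite homozygotes share
#' 0. In dosage terms the shared fraction at a marker is `1 - |x - y| / 2`.
#'
#' @param g a [nam_geno()] object or a dosage matrix.
#' @param min_shared pairs with fewer shared (pairwise-complete) calls are
#'   flagged low-confidence (default 50).
#' @return list of class `dist_matrix`: `d` (symmetric dissimilarity matrix
#'   with zero diagonal; `NA` where a pair shares no calls), `n_shared`
#'   (pairwise-complete counts), `low_confidence` (logical matrix).
#' @export
allele_sharing_distance <- function(g, min_shared = 50L) {
  x <- if (inherits(g, "nam_geno")) geno_dosage(g) else g
  if (nrow(x) < 2L) stop("need at least two samples")
  obs <- !is.na(x)
  A <- list(
    (x == 0 & obs) + 0,
    (x == 1 & obs) + 0,
    (x == 2 & obs) + 0
  )
  # total |dosage difference| summed over shared markers
  tot <- 2 * (A[[1]] %*% t(A[[3]]) + A[[3]] %*% t(A[[1]])) +
    (A[[1]] %*% t(A[[2]]) + A[[2]] %*% t(A[[1]]) +
       A[[2]] %*% t(A[[3]]) + A[[3]] %*% t(A[[2]]))
  n_shared <- (obs + 0) %*% t(obs + 0)
  d <- ifelse(n_shared > 0, tot / (2 * n_shared), NA_real_)
  diag(d) <- 0
  dimnames(d) <- dimnames(n_shared) <- list(rownames(x), rownames(x))
  structure(list(d = d, n_shared = n_shared,
                 low_confidence = n_shared < min_shared),
            class = "dist_matrix")
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a complete distance matrix, with
#' deterministic tie-breaking: among minimal-Q pairs the one whose clusters
#' carry the lexicographically smallest leaf labels is joined first.
#' Negative branch lengths are clamped to zero (logged via a message).
#' Returns an `ape::phylo` object (serializable with [ape::write.tree()]).
#'
#' @param D a [allele_sharing_distance()] result or a complete symmetric
#'   numeric matrix with dimnames.
#' @return an unrooted `phylo` tree whose tips are the input samples.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "dist_matrix")) D$d else as.matrix(D)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs >= 3 samples")
  if (anyNA(d)) stop("incomplete distance matrix")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))

  active <- seq_len(n)            # phylo node ids of active clusters
  rep_lab <- labs                 # smallest leaf label per active cluster
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  clamped <- 0L

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    if (len < 0) {
      clamped <<- clamped + 1L
      len <- 0
    }
    elen <<- c(elen, len)
  }

  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1]]
    j <- pick[[2]]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    v <- next_node
    next_node <- next_node + 1L
    add_edge(v, active[i], li)
    add_edge(v, active[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], v)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
  }
  # final three-way join: closed-form three-point branch lengths
  v <- next_node
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  add_edge(v, active[1], la)
  add_edge(v, active[2], lb)
  add_edge(v, active[3], lc)
  if (clamped > 0L) {
    message(clamped, " negative branch lengths clamped to 0")
  }
  # ape convention: the root carries number n + 1; the final join node is
  # created last, so rotate the internal numbering
  root <- next_node
  remap <- function(z) ifelse(z == root, n + 1L,
                              ifelse(z > n, z + 1L, z))
  edges <- matrix(as.integer(remap(edges)), ncol = 2L)
  tr <- structure(list(edge = edges, edge.length = elen,
                       tip.label = labs, Nnode = n - 2L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Principal component analysis of genotypes
#'
#' Centered-dosage PCA by singular value decomposition. Missing dosages are
#' imputed with the per-marker mean (a deterministic, standard choice), so
#' imputed cells contribute nothing after centering.
#'
#' @param g a [nam_geno()] object (founder rows excluded) or dosage matrix.
#' @param n_pcs number of components to return (default all).
#' @return list of class `geno_pca`: `scores` (samples x PCs), `explained`
#'   (variance fractions, non-increasing, summing to <= 1), `sdev`.
#' @export
geno_pca <- function(g, n_pcs = NULL) {
  x <- if (inherits(g, "nam_geno")) geno_dosage(ril_only(g)) else g
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 markers")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mu[j]
  }
  xc <- sweep(x, 2L, colMeans(x))
  total_var <- sum(xc^2)
  if (total_var == 0) {
    warning("all-constant genotype matrix: zero variance, no scores")
    return(structure(list(scores = matrix(0, nrow(x), 0),
                          explained = numeric(0), sdev = numeric(0)),
                     class = "geno_pca"))
  }
  k <- min(nrow(x) - 1L, ncol(x))
  if (!is.null(n_pcs)) k <- min(k, n_pcs)
  sv <- svd(xc, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained = sv$d[seq_len(k)]^2 / total_var,
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1L))),
            class = "geno_pca")
}

#' Flag samples whose genotypes disagree with their family label
#'
#' A reproducible stand-in for visual inspection of family clusters: a
#' sample is flagged when its mean allele-sharing distance to its own
#' family's members exceeds its mean distance to some other family's
#' members by more than `margin`. Singleton families are skipped with a
#' warning.
#'
#' @param g a [nam_geno()] object with family labels (founders excluded).
#' @param margin required distance advantage of the nearest foreign family
#'   (default 0.05).
#' @return data.frame `sample`, `family`, `nearest_family`, `own_mean`,
#'   `nearest_mean` for flagged samples (zero rows when none).
#' @export
flag_misassigned <- function(g, margin = 0.05) {
  stopifnot(inherits(g, "nam_geno"))
  r <- ril_only(g)
  D <- allele_sharing_distance(r)$d
  fams <- unique(r$family)
  singles <- fams[tabulate(factor(r$family, fams)) < 2L]
  if (length(singles)) {
    warning("singleton families skipped: ", paste(singles, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(D))) {
    f <- r$family[i]
    own <- which(r$family == f)
    own <- setdiff(own, i)
    if (!length(own)) next
    own_mean <- mean(D[i, own], na.rm = TRUE)
    others <- setdiff(fams, c(f, singles))
    if (!length(others)) next
    other_means <- vapply(others, function(of) {
      mean(D[i, r$family == of], na.rm = TRUE)
    }, numeric(1))
    b <- which.min(other_means)
    if (own_mean > other_means[b] + margin) {
      out[[length(out) + 1L]] <- data.frame(
        sample = rownames(D)[i], family = f,
        nearest_family = others[b], own_mean = own_mean,
        nearest_mean = other_means[b], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(0), family = character(0),
                      nearest_family = character(0), own_mean = numeric(0),
                      nearest_mean = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
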