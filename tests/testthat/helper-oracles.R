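# Independent oracles and small fixtures used across the tests. Each oracle
# is written as a direct, naive transcription of the defining formula so it
# stays independent of the package's implementation paths.

# mutual information by an explicit double loop over the joint histogram
brute_force_mi <- function(a, b, n_bins) {
  scale01 <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(NULL)
    (x - r[1]) / (r[2] - r[1])
  }
  sa <- scale01(a); sb <- scale01(b)
  if (is.null(sa) || is.null(sb)) return(0)
  ia <- pmin(floor(sa * n_bins) + 1, n_bins)
  ib <- pmin(floor(sb * n_bins) + 1, n_bins)
  n <- length(ia)
  joint <- matrix(0, n_bins, n_bins)
  for (k in seq_len(n)) joint[ia[k], ib[k]] <- joint[ia[k], ib[k]] + 1
  joint <- joint / n
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
  }
  mi
}

# exhaustive nearest-centroid assignment
nearest_centroid <- function(x, centroids) {
  apply(x, 1, function(p) {
    which.min(colSums((t(centroids) - p)^2))
  })
}

# Friedman chi-square p-value by exhaustive enumeration of within-block
# permutations (tie-corrected statistic recomputed from scratch)
perm_friedman_p <- function(values) {
  b <- nrow(values); k <- ncol(values)
  stat <- function(x) {
    r <- t(apply(x, 1, rank))
    Rj <- colSums(r)
    A <- sum(r^2)
    den <- A - b * k * (k + 1)^2 / 4
    if (den <= 0) return(0)
    (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / den
  }
  perms <- gtools_perms(k)
  obs <- stat(values)
  grid <- expand.grid(rep(list(seq_len(nrow(perms))), b))
  count <- 0
  for (g in seq_len(nrow(grid))) {
    x <- values
    for (bl in seq_len(b)) x[bl, ] <- values[bl, perms[grid[g, bl], ]]
    if (stat(x) >= obs - 1e-12) count <- count + 1
  }
  count / nrow(grid)
}

# all permutations of 1..k, plain recursion
gtools_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
}

# Conover post-hoc p-values transcribed directly from the textbook formulas
textbook_conover_p <- function(values) {
  b <- nrow(values); k <- ncol(values)
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  A1 <- sum(r^2)
  C1 <- b * k * (k + 1)^2 / 4
  T1 <- (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / (A1 - C1)
  dof <- (b - 1) * (k - 1)
  se <- sqrt(2 * b * (A1 - C1) * (1 - T1 / (b * (k - 1))) / dof)
  p <- matrix(1, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) p[i, j] <- 2 * pt(abs(Rj[i] - Rj[j]) / se, dof, lower.tail = FALSE)
  }
  p
}

# small, fast phantom for unit tests (full-size defaults are exercised in
# the acceptance tests)
small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(48L, 48L, 12L),
                 gland_length_mm = 38,
                 cross_section_mm = rbind(head = c(8, 7), body = c(6, 6),
                                          tail = c(6, 6)),
                 ...)
}

# three well-separated spheres as a binary map
three_spheres_mask <- function(dim = c(30L, 12L, 12L), spacing = c(1, 1, 1),
                               radius = 3) {
  coords <- lapply(1:3, function(a) (seq_len(dim[a]) - 1) * spacing[a] + spacing[a] / 2)
  centers <- list(c(5, 6, 6), c(15, 6, 6), c(25, 6, 6))
  m <- array(FALSE, dim)
  memb <- list()
  for (s in 1:3) {
    d2 <- outer(outer((coords[[1]] - centers[[s]][1])^2,
                      (coords[[2]] - centers[[s]][2])^2, `+`),
                (coords[[3]] - centers[[s]][3])^2, `+`)
    memb[[s]] <- d2 <= radius^2
    m <- m | memb[[s]]
  }
  list(mask = m, membership = memb, centers = centers, spacing = spacing)
}
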