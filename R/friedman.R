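# Nonparametric comparison of patient setups: the Friedman rank test over
# complete blocks, and Conover's Fisher-LSD-style post-hoc pairwise
# comparisons with homogeneous-group symbols.

#' Friedman rank test over a complete block design
#'
#' Values are mid-ranked within each block; the tie-corrected chi-square
#' statistic is
#' `T = (k - 1) * sum((Rj - b(k+1)/2)^2) / (A - b k (k+1)^2 / 4)`
#' with `A` the sum of all squared ranks, which reduces to the classical
#' `12/(bk(k+1)) sum(Rj^2) - 3b(k+1)` without ties. `dof = k - 1`; the
#' p-value comes from the chi-square upper tail, or, with
#' `p_method = "permutation"`, from exhaustive enumeration of all `(k!)^b`
#' within-block permutations (only feasible for tiny designs).
#'
#' If every block is fully tied the statistic is defined as 0 and p = 1.
#'
#' @param values blocks x treatments numeric matrix (no missing cells)
#' @param p_method `"chisq"` (default) or `"permutation"`
#' @return list: `statistic`, `dof`, `p_value`, `rank_sums`, `method`,
#'   `n_blocks`, `n_treatments`
#' @export
friedman_block_test <- function(values, p_method = c("chisq", "permutation")) {
  p_method <- match.arg(p_method)
  values <- as.matrix(values)
  b <- nrow(values); k <- ncol(values)
  if (b < 2 || k < 2) stop("need at least 2 blocks and 2 treatments")
  if (anyNA(values)) stop("incomplete blocks must be dropped before testing")
  stat_of <- function(x) {
    r <- t(apply(x, 1, rank))
    Rj <- colSums(r)
    A <- sum(r^2)
    denom <- A - b * k * (k + 1)^2 / 4
    if (denom <= .Machine$double.eps * A) return(0)
    (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / denom
  }
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  stat <- stat_of(values)
  dof <- k - 1
  if (p_method == "chisq") {
    p <- if (stat == 0) 1 else stats::pchisq(stat, dof, lower.tail = FALSE)
  } else {
    perms <- permutations_k(k)
    n_perm <- nrow(perms)
    if (n_perm^b > 2e6) stop("permutation enumeration too large; use chisq")
    # enumerate all within-block permutations of the observed block values
    idx <- rep(1L, b)
    count <- 0L; total <- 0L
    x <- values
    repeat {
      for (bl in seq_len(b)) x[bl, ] <- values[bl, perms[idx[bl], ]]
      total <- total + 1L
      if (stat_of(x) >= stat - 1e-12) count <- count + 1L
      j <- b
      while (j >= 1) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= n_perm) break
        idx[j] <- 1L; j <- j - 1
      }
      if (j < 1) break
    }
    p <- count / total
  }
  list(statistic = stat, dof = dof, p_value = p,
       rank_sums = setNames(Rj, colnames(values)),
       method = p_method, n_blocks = b, n_treatments = k)
}

permutations_k <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_k(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1, length.out = k - pos), drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Conover post-hoc pairwise comparisons for the Friedman design
#'
#' The nonparametric analogue of Fisher's least-significant-difference
#' method: treatments i and j differ when
#' `|Ri - Rj| / SE > t(1 - alpha/2, (b-1)(k-1))`, with
#' `SE = sqrt(2b (A - C)(1 - T1/(b(k-1))) / ((b-1)(k-1)))`, where `A` is
#' the sum of squared within-block mid-ranks, `C = b k (k+1)^2 / 4` and
#' `T1` the tie-corrected Friedman statistic. Two-sided p-values use the t
#' distribution with `(b-1)(k-1)` dof. No multiplicity adjustment beyond
#' the LSD protection of a significant omnibus test is applied.
#'
#' Homogeneous groups are the maximal cliques of the non-significance graph
#' at `alpha`: treatments sharing a group symbol are pairwise
#' non-significant and every significant pair shares no symbol.
#'
#' Degenerate designs (zero rank variance) yield a single all-treatment
#' group with all pairwise p = 1 and a warning. Perfectly separated
#' designs (T1 at its maximum) have SE = 0; unequal rank sums then get
#' p = 0.
#'
#' @param values blocks x treatments numeric matrix
#' @param alpha significance level for grouping
#' @return list: `friedman` (omnibus result), `pairwise_p` (symmetric
#'   matrix, unit diagonal), `rank_sums`, `groups` (list of treatment-index
#'   vectors), `symbols` (character per treatment), `alpha`
#' @export
conover_posthoc <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  b <- nrow(values); k <- ncol(values)
  fr <- friedman_block_test(values)
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- b * k * (k + 1)^2 / 4
  dof <- (b - 1) * (k - 1)
  pw <- matrix(1, k, k)
  degenerate <- (A - C) <= .Machine$double.eps * A
  if (degenerate) {
    warning("zero rank variance: all treatments tied in every block")
  } else {
    fac <- max(0, 1 - fr$statistic / (b * (k - 1)))
    se <- sqrt(2 * b * (A - C) * fac / dof)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (se == 0) {
        p <- if (abs(Rj[i] - Rj[j]) > 1e-9) 0 else 1
      } else {
        p <- 2 * stats::pt(abs(Rj[i] - Rj[j]) / se, dof, lower.tail = FALSE)
      }
      pw[i, j] <- pw[j, i] <- p
    }
  }
  tn <- colnames(values)
  if (is.null(tn)) tn <- paste0("T", seq_len(k))
  dimnames(pw) <- list(tn, tn)

  groups <- homogeneous_groups(pw >= alpha)
  symbols <- rep("", k)
  if (length(groups) > 1 || any(pw < alpha)) {
    syms <- c(letters, LETTERS)
    for (g in seq_along(groups))
      for (t in groups[[g]])
        symbols[t] <- paste0(symbols[t], syms[g])
  }
  list(friedman = fr, pairwise_p = pw, rank_sums = setNames(Rj, tn),
       groups = groups, symbols = setNames(symbols, tn), alpha = alpha)
}

# maximal cliques of a small non-significance adjacency matrix (k <= ~12)
homogeneous_groups <- function(adj) {
  k <- nrow(adj)
  diag(adj) <- TRUE
  cliques <- list()
  for (s in seq_len(2^k) - 1L) {
    members <- which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0)
    if (length(members) == 0) next
    if (all(adj[members, members])) cliques[[length(cliques) + 1]] <- members
  }
  # keep maximal cliques only
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j)
      i != j && all(cliques[[i]] %in% cliques[[j]]), logical(1)))
  }, logical(1))
  cliques <- cliques[keep]
  # order by the smallest member for deterministic lettering
  cliques[order(vapply(cliques, min, numeric(1)))]
}
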