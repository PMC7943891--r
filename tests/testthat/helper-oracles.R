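# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: the hypergeometric oracle works in exact
# integer arithmetic, and the Ward.D2 oracle recomputes the clustering
# objective from scratch at every agglomeration step.

# ---- exact integer arithmetic on 3 limbs, base 2^20 -------------------
# Integers below 2^60 are stored as rows (l0, l1, l2) with
# value = l0 + l1*B + l2*B^2.  Binomial coefficients up to C(60, 30)
# (~1.2e17 < 2^57) and single hypergeometric terms (bounded by C(n, k))
# stay below 2^57, and every limb product stays below 2^53, so all
# arithmetic here is exact; doubles enter only at the final conversion.

.limb_base <- 2^20

limb_carry <- function(z) {
  for (j in seq_len(ncol(z) - 1L)) {
    carry <- floor(z[, j] / .limb_base)
    z[, j] <- z[, j] - carry * .limb_base
    z[, j + 1L] <- z[, j + 1L] + carry
  }
  stopifnot(all(z[, ncol(z)] < .limb_base))
  z
}

limb_add <- function(x, y) limb_carry(x + y)

limb_mul <- function(x, y) {
  z <- matrix(0, nrow(x), 6L)
  z[, 1] <- x[, 1] * y[, 1]
  z[, 2] <- x[, 1] * y[, 2] + x[, 2] * y[, 1]
  z[, 3] <- x[, 1] * y[, 3] + x[, 2] * y[, 2] + x[, 3] * y[, 1]
  z[, 4] <- x[, 2] * y[, 3] + x[, 3] * y[, 2]
  z[, 5] <- x[, 3] * y[, 3]
  z <- limb_carry(z)
  stopifnot(all(z[, 4:6] == 0))  # results must fit in 3 limbs
  z[, 1:3, drop = FALSE]
}

limb_to_double <- function(z) {
  z[, 1] + z[, 2] * .limb_base + z[, 3] * .limb_base^2
}

# Pascal's triangle in exact limbs: pascal_limbs(N)[[a + 1]] holds
# C(a, 0..a) as rows.
pascal_limbs <- function(N) {
  out <- vector("list", N + 1L)
  out[[1]] <- matrix(c(1, 0, 0), 1L, 3L)
  for (a in seq_len(N)) {
    prev <- out[[a]]
    zero <- matrix(0, 1L, 3L)
    out[[a + 1L]] <- limb_add(rbind(zero, prev), rbind(prev, zero))
  }
  out
}

# Upper-tail hypergeometric probabilities for all x in the support of
# (n, m, k), by brute-force summation of exactly computed terms
# C(m, i) * C(n - m, k - i); division by C(n, k) is the only floating
# operation.
hyper_upper_oracle <- function(n, m, k, pascal) {
  imin <- max(0L, m + k - n)
  imax <- min(m, k)
  i <- imin:imax
  t_a <- pascal[[m + 1L]][i + 1L, , drop = FALSE]
  t_b <- pascal[[n - m + 1L]][k - i + 1L, , drop = FALSE]
  terms <- limb_to_double(limb_mul(t_a, t_b))
  denom <- limb_to_double(pascal[[n + 1L]][k + 1L, , drop = FALSE])
  p <- rev(cumsum(rev(terms))) / denom
  list(x = i, p = pmin(p, 1))
}

# ---- naive Ward.D2 agglomeration --------------------------------------
# At every step the inter-cluster distance is recomputed from the raw
# data: d(A, B) = sqrt(2 |A||B| / (|A|+|B|)) * ||mean_A - mean_B||, the
# square root of twice the increase in within-cluster sum of squares
# caused by merging A and B.  Returns the merge sequence as member-index
# sets plus the merge heights.
ward_d2_naive <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq(a + 1L, length(clusters))) {
        na <- length(clusters[[a]])
        nb <- length(clusters[[b]])
        ma <- colMeans(X[clusters[[a]], , drop = FALSE])
        mb <- colMeans(X[clusters[[b]], , drop = FALSE])
        d <- sqrt(2 * na * nb / (na + nb) * sum((ma - mb)^2))
        if (is.null(best) || d < best$d) {
          best <- list(a = a, b = b, d = d)
        }
      }
    }
    merges[[length(merges) + 1L]] <- list(
      left = sort(clusters[[best$a]]), right = sort(clusters[[best$b]]))
    heights <- c(heights, best$d)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# Member-index sets merged at each step of an hclust tree, for comparison
# with ward_d2_naive (each step as an unordered pair of sorted sets).
hclust_merge_sets <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  resolve <- function(id, step) {
    if (id < 0) -id else members[[id]]
  }
  out <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    left <- sort(resolve(hc$merge[s, 1], s))
    right <- sort(resolve(hc$merge[s, 2], s))
    members[[s]] <- sort(c(left, right))
    out[[s]] <- list(left = left, right = right)
  }
  out
}

# TRUE when two merge steps join the same unordered pair of member sets.
same_merge <- function(a, b) {
  (identical(a$left, b$left) && identical(a$right, b$right)) ||
    (identical(a$left, b$right) && identical(a$right, b$left))
}
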