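# Alpha diversity (Hill profiles, Shannon), phylogenetic beta diversity
# (weighted UniFrac, DPCoA), and Spearman monotonicity of estimates
# against truth.

check_abundances <- function(p, tol = 1e-6) {
  if (length(p) == 0L) stop("empty abundance vector")
  if (any(p < 0)) stop("negative abundance")
  s <- sum(p)
  if (abs(s - 1) > tol) stop("abundances sum to ", format(s), ", not 1")
  p / s
}

#' Hill number of order q
#'
#' `qD = (sum_i p_i^q)^(1/(1-q))` over the positive abundances; at q = 1
#' the limit `exp(-sum p_i log p_i)` (the exponential of Shannon) is used.
#' q = 0 gives richness S; increasing q shifts emphasis from rare to
#' dominant organisms. qD is non-increasing in q.
#'
#' @param p Relative abundances, summing to 1 (zeros allowed; excluded).
#' @param q Order of the Hill number; `|q| <= 50` (overflow guard).
#' @return The diversity number, >= 1.
#' @examples
#' hill_number(rep(1 / 8, 8), 2)  # 8: uniform community of 8
#' @export
hill_number <- function(p, q) {
  stopifnot(abs(q) <= 50)
  p <- check_abundances(p)
  p <- p[p > 0]
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Shannon index
#'
#' `-sum p_i log p_i` (natural log) over positive abundances;
#' `exp(shannon(p))` equals `hill_number(p, 1)`.
#'
#' @inheritParams hill_number
#' @export
shannon <- function(p) {
  p <- check_abundances(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Hill diversity profile with bootstrap confidence band
#'
#' Mean Hill diversity across communities on a grid of orders (default -1
#' to 5 in 0.5 steps), with a percentile bootstrap confidence interval
#' obtained by resampling communities with replacement.
#'
#' @param communities List of relative-abundance vectors (one per
#'   community), each summing to 1.
#' @param q_grid Orders at which to evaluate; default `seq(-1, 5, 0.5)`.
#' @param n_boot Bootstrap iterations, default 5000.
#' @param seed Optional integer seed.
#' @param conf Confidence level, default 0.95.
#' @return Data frame: `q`, `mean_qD`, `ci_low`, `ci_high`.
#' @export
diversity_profile <- function(communities, q_grid = seq(-1, 5, by = 0.5),
                              n_boot = 5000, seed = NULL, conf = 0.95) {
  stopifnot(length(communities) >= 2)
  qd <- vapply(communities, function(p) {
    vapply(q_grid, function(q) hill_number(p, q), numeric(1))
  }, numeric(length(q_grid)))          # q x communities
  qd <- t(qd)                           # communities x q
  m <- colMeans(qd)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    nc <- nrow(qd)
    boots <- matrix(NA_real_, n_boot, length(q_grid))
    for (b in seq_len(n_boot)) {
      boots[b, ] <- colMeans(qd[sample.int(nc, nc, replace = TRUE), ,
                                drop = FALSE])
    }
    ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
  })
  data.frame(q = q_grid, mean_qD = m, ci_low = ci[1, ], ci_high = ci[2, ])
}

# Per-branch descendant abundance mass for each edge of a rooted tree:
# postorder accumulation of tip abundances.
branch_masses <- function(tree, p) {
  missing <- setdiff(names(p), tree$tip.label)
  if (length(missing)) {
    stop("taxon absent from tree: ", missing[1])
  }
  ntip <- length(tree$tip.label)
  acc <- numeric(ntip + tree$Nnode)
  acc[seq_len(ntip)] <- p[match(tree$tip.label, names(p))]
  acc[is.na(acc)] <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    acc[ord$edge[i, 1]] <- acc[ord$edge[i, 1]] + acc[ord$edge[i, 2]]
  }
  # mass flowing through each edge = mass under its child node, in the
  # edge order of the original tree
  acc[tree$edge[, 2]]
}

#' Weighted UniFrac distance between two communities
#'
#' Raw weighted UniFrac is `sum_branches len_b * |A_b - B_b|`, where `A_b`
#' is the fraction of community `a` descending through branch `b`. The
#' normalized variant divides by `sum_branches len_b * (A_b + B_b)`, so it
#' lies in \[0, 1\]. Reports should state which variant was used.
#'
#' @param tree A rooted `phylo` tree with branch lengths; every taxon of
#'   `a` and `b` must be a tip.
#' @param a,b Named relative-abundance vectors (names are tip labels).
#' @param normalized Use the normalized variant? Default `FALSE` (raw).
#' @return Non-negative distance; 0 for identical communities.
#' @export
weighted_unifrac <- function(tree, a, b, normalized = FALSE) {
  a <- stats::setNames(check_abundances(a), names(a))
  b <- stats::setNames(check_abundances(b), names(b))
  A <- branch_masses(tree, a)
  B <- branch_masses(tree, b)
  len <- tree$edge.length
  raw <- sum(len * abs(A - B))
  if (!normalized) return(raw)
  denom <- sum(len * (A + B))
  if (denom == 0) 0 else raw / denom
}

#' Pairwise weighted UniFrac matrix
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param communities Named list of named relative-abundance vectors.
#' @inheritParams weighted_unifrac
#' @return Symmetric distance matrix with zero diagonal.
#' @export
weighted_unifrac_matrix <- function(tree, communities, normalized = FALSE) {
  n <- length(communities)
  d <- matrix(0, n, n, dimnames = list(names(communities), names(communities)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- weighted_unifrac(tree, communities[[i]],
                                             communities[[j]], normalized)
    }
  }
  d
}

#' DPCoA distances between communities
#'
#' Double principal coordinate analysis, computed operationally: species
#' dissimilarities are the square roots of patristic distances; species
#' are embedded by classical metric scaling of those dissimilarities
#' (negative eigenvalues below `-tol * max_eigenvalue` trigger a warning
#' and are truncated at zero); each community is placed at the
#' abundance-weighted centroid of its species' coordinates; community
#' distances are Euclidean distances between centroids. Because the
#' embedding is Euclidean, the result satisfies the triangle inequality.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param communities Named list of named relative-abundance vectors, or a
#'   communities-by-taxa abundance matrix with dimnames.
#' @param tol Relative tolerance for negative eigenvalues, default 1e-8.
#' @return Symmetric distance matrix between communities.
#' @export
dpcoa_distances <- function(tree, communities, tol = 1e-8) {
  if (is.list(communities)) {
    taxa <- sort(unique(unlist(lapply(communities, names))))
    X <- t(vapply(communities, function(p) {
      p <- check_abundances(p)
      out <- stats::setNames(numeric(length(taxa)), taxa)
      out[names(p)] <- p
      out
    }, numeric(length(taxa))))
  } else {
    X <- as.matrix(communities)
    X <- X / rowSums(X)
    taxa <- colnames(X)
  }
  stopifnot(nrow(X) >= 2)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) stop("taxon absent from tree: ", missing[1])
  delta <- sqrt(stats::cophenetic(tree)[taxa, taxa, drop = FALSE])
  n <- length(taxa)
  # classical metric scaling (Gower double-centering)
  D2 <- delta^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (any(lam < -tol * max(lam))) {
    warning("non-Euclidean residual after sqrt transform; negative ",
            "eigenvalues truncated at 0")
  }
  lam[lam < 0] <- 0
  keep <- lam > 0
  coords <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]),
                                                      nrow = sum(keep))
  centroids <- X %*% coords
  as.matrix(stats::dist(centroids))
}

#' Spearman monotonicity of estimates against truth
#'
#' Spearman rank correlation (average ranks for ties) between true and
#' estimated values, its square, and percentile bootstrap confidence
#' intervals for both, obtained by resampling index pairs with
#' replacement. Whether one inspects rho or rho^2 is a reporting choice;
#' both are returned.
#'
#' @param true_values,estimated_values Equal-length numeric vectors
#'   (length >= 3), e.g. true vs estimated Shannon per community, or the
#'   lower triangles of true vs estimated distance matrices.
#' @param n_boot Bootstrap iterations, default 1000.
#' @param seed Optional integer seed.
#' @param conf Confidence level, default 0.95.
#' @return A list: `rho`, `rho_sq`, `ci_rho`, `ci_rho_sq`, `n`, `n_boot`.
#' @export
monotonicity_report <- function(true_values, estimated_values, n_boot = 1000,
                                seed = NULL, conf = 0.95) {
  x <- as.numeric(true_values); y <- as.numeric(estimated_values)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Spearman correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    n <- length(x)
    boots <- vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(x[ix], y[ix], method = "spearman"))
    }, numeric(1))
    boots <- boots[!is.na(boots)]
    ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    ci_sq <- stats::quantile(boots^2, c(alpha, 1 - alpha), names = FALSE)
  })
  list(rho = rho, rho_sq = rho^2, ci_rho = ci, ci_rho_sq = ci_sq,
       n = length(x), n_boot = n_boot)
}

#' Shannon diversity per community
#'
#' Convenience wrappers returning named vectors of Shannon indices, from
#' the truth (target fractions) or from an OTU table (summed weights per
#' OTU, normalized).
#'
#' @param targets A community-target data frame.
#' @return Named numeric vector keyed by community.
#' @export
shannon_from_targets <- function(targets) {
  vapply(abundances_from_targets(targets), shannon, numeric(1))
}

#' @rdname shannon_from_targets
#' @param otu An OTU-table data frame.
#' @export
shannon_from_otu <- function(otu) {
  vapply(abundances_from_otu(otu), shannon, numeric(1))
}
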