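#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all pairs of
#' non-negative feature vectors (0 = identical, 1 = disjoint support). A
#' pair of all-zero vectors has an undefined distance and raises an error
#' naming the offending individuals.
#'
#' @param features a numeric matrix (rows = individuals) from
#'   [feature_matrix], or a list of `spectral_features`.
#' @return A list of class `dissimilarity_matrix`: `labels`, `values`
#'   (symmetric matrix with zero diagonal, entries in \[0, 1\]).
#' @export
bray_curtis_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features) && !is.matrix(features))
    features <- feature_matrix(features)
  m <- as.matrix(features)
  if (nrow(m) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative features", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis distance undefined between all-zero individuals: ",
         paste(labels[zero], collapse = ", "), call. = FALSE)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, values = d), class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix: %d individuals, Bray-Curtis range %.3f - %.3f\n",
              length(x$labels), min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

as_dissimilarity <- function(dist) {
  if (inherits(dist, "dissimilarity_matrix")) return(dist)
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (is.matrix(dist)) {
    labels <- rownames(dist)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(dist)))
    return(structure(list(labels = labels, values = dist),
                     class = "dissimilarity_matrix"))
  }
  stop("expected a dissimilarity_matrix, dist, or square matrix", call. = FALSE)
}

# number of distinct partitions of n items into unordered-within-size labeled
# groups of the given sizes (groups of equal size are exchangeable)
n_distinct_partitions <- function(sizes) {
  n <- sum(sizes)
  lg <- lgamma(n + 1) - sum(lgamma(sizes + 1)) -
    sum(lgamma(table(sizes) + 1))
  exp(lg)
}

# enumerate every distinct set partition of `elements` into groups of the
# given sizes; `emit(groups)` is called once per partition with a list of
# integer vectors. The lowest remaining element always leads the next group
# of each distinct size, so partitions that differ only by exchanging
# equal-size groups appear once.
enum_partitions <- function(elements, sizes, emit, acc = list()) {
  if (!length(sizes)) { emit(acc); return(invisible()) }
  e <- elements[1]
  rest <- elements[-1]
  for (s in unique(sizes)) {
    i <- match(s, sizes)
    combos <- if (s == 1L) list(integer(0)) else combn(rest, s - 1L, simplify = FALSE)
    for (cmb in combos) {
      grp <- c(e, cmb)
      enum_partitions(setdiff(elements, grp), sizes[-i], emit,
                      c(acc, list(grp)))
    }
  }
  invisible()
}

# ANOSIM R from the rank vector of the n(n-1)/2 pairwise dissimilarities and
# a logical within-group indicator per pair
anosim_R <- function(ranks, within) {
  M <- length(ranks)
  (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
}

#' ANOSIM permutation test
#'
#' Analysis of Similarities: ranks all pairwise dissimilarities (mid-ranks
#' for ties) and contrasts mean between-group and within-group ranks,
#' `R = (rbar_between - rbar_within) / (M/2)` with `M = n(n-1)/2`, so
#' `R` lies in \[-1, 1\] and is invariant to monotone transforms of the
#' dissimilarities. If the number of distinct group assignments (set
#' partitions into the observed group sizes) is at most `exhaustive_limit`
#' they are enumerated and the p-value is exact,
#' `p = #\{R_perm >= R_obs\} / n_partitions` (the observed assignment is one
#' of them); otherwise `n_permutations` random label shuffles are drawn from
#' the seeded generator and `p = (#\{R_perm >= R_obs\} + 1) /
#' (n_permutations + 1)`.
#'
#' @param dist a `dissimilarity_matrix` (or square matrix / `dist`).
#' @param groups group label per individual (>= 2 groups, each >= 2
#'   members).
#' @param n_permutations Monte-Carlo permutation count (default 9999).
#' @param seed integer seed for the Monte-Carlo shuffles.
#' @param exhaustive_limit enumerate exactly when the number of distinct
#'   assignments is at most this (default 200000); set to 0 to force
#'   Monte-Carlo.
#' @return A list of class `anosim_result`: `R`, `p_value`,
#'   `n_permutations` (permutations actually examined), `exact`, `seed`,
#'   `group_sizes`.
#' @export
anosim <- function(dist, groups, n_permutations = 9999L, seed = NULL,
                   exhaustive_limit = 200000) {
  dist <- as_dissimilarity(dist)
  d <- dist$values
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("need one group label per individual (", n, "), got ",
         length(groups), call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("ANOSIM needs at least 2 groups", call. = FALSE)
  if (any(sizes < 2L))
    stop("every group needs at least 2 members; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)

  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)),
                   use.names = FALSE)
  # pair (i, j) with i < j, column-free flat indexing of the lower triangle
  dvec <- d[cbind(pair_j, pair_i)]
  ranks <- rank(dvec)  # mid-ranks for ties
  within_obs <- groups[pair_i] == groups[pair_j]
  if (all(within_obs) || !any(within_obs))
    stop("degenerate design: no between-group or no within-group pairs", call. = FALSE)
  R_obs <- anosim_R(ranks, within_obs)

  n_exact <- n_distinct_partitions(as.integer(sizes))
  tol <- 1e-12
  if (n_exact <= exhaustive_limit && n_exact >= 1) {
    count <- 0L
    total <- 0L
    member <- integer(n)
    emit <- function(grps) {
      for (g in seq_along(grps)) member[grps[[g]]] <<- g
      within <- member[pair_i] == member[pair_j]
      if (anosim_R(ranks, within) >= R_obs - tol) count <<- count + 1L
      total <<- total + 1L
    }
    enum_partitions(seq_len(n), as.integer(sort(sizes, decreasing = TRUE)),
                    emit)
    res <- list(R = R_obs, p_value = count / total, n_permutations = total,
                exact = TRUE, seed = seed, group_sizes = sizes)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_permutations)) {
      gp <- sample(groups)
      within <- gp[pair_i] == gp[pair_j]
      if (anosim_R(ranks, within) >= R_obs - tol) count <- count + 1L
    }
    res <- list(R = R_obs, p_value = (count + 1) / (n_permutations + 1),
                n_permutations = as.integer(n_permutations), exact = FALSE,
                seed = seed, group_sizes = sizes)
  }
  structure(res, class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations) %s\n",
              x$R, x$p_value,
              if (x$exact) "exact" else "Monte-Carlo", x$n_permutations,
              significance_code(x$p_value)))
  invisible(x)
}

#' Significance codes for permutation p-values
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise.
#'
#' @param p numeric p-value(s).
#' @return Character vector of codes.
#' @export
significance_code <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}

#' Pairwise ANOSIM between all group pairs
#'
#' Runs [anosim] on the sub-matrix of each unordered pair of groups and
#' reports R, the p-value and its significance code. No multiplicity
#' adjustment is applied by default, mirroring the usual presentation of
#' pairwise ANOSIM tables; set `bonferroni = TRUE` to multiply p-values by
#' the number of pairs (capped at 1).
#'
#' @inheritParams anosim
#' @param bonferroni apply a Bonferroni correction across pairs.
#' @return A data.frame of class `pairwise_anosim`: `group_a`, `group_b`,
#'   `R`, `p_value`, `significance`.
#' @export
pairwise_anosim <- function(dist, groups, n_permutations = 9999L, seed = NULL,
                            exhaustive_limit = 200000, bonferroni = FALSE) {
  dist <- as_dissimilarity(dist)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- combn(lev, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    keep <- groups %in% pr
    sub <- dist$values[keep, keep, drop = FALSE]
    res <- anosim(sub, groups[keep], n_permutations = n_permutations,
                  seed = seed, exhaustive_limit = exhaustive_limit)
    data.frame(group_a = pr[1], group_b = pr[2], R = res$R,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * length(pairs))
  out$significance <- significance_code(out$p_value)
  class(out) <- c("pairwise_anosim", "data.frame")
  out
}

#' Non-metric multidimensional scaling
#'
#' Embeds individuals in `n_dims` dimensions preserving the rank order of
#' their dissimilarities, minimizing Kruskal stress-1 by iterative
#' configuration updates alternated with monotone (isotonic) regression
#' (via `vegan::monoMDS`, global model). `n_restarts` random starting
#' configurations are drawn from the seeded generator and the lowest-stress
#' solution is returned.
#'
#' @param dist a `dissimilarity_matrix` (or square matrix / `dist`).
#' @param n_dims embedding dimension (default 2).
#' @param n_restarts random restarts (default 20).
#' @param max_iter iteration cap per restart.
#' @param tol convergence tolerance on the stress gradient.
#' @param seed integer seed for the random starts.
#' @return A list of class `mds_embedding`: `coordinates` (n x n_dims matrix
#'   with individual rownames), `stress` (Kruskal stress-1), `n_restarts`,
#'   `seed`, `converged`.
#' @export
nmds <- function(dist, n_dims = 2L, n_restarts = 20L, max_iter = 300L,
                 tol = 1e-7, seed = NULL) {
  dist <- as_dissimilarity(dist)
  n <- nrow(dist$values)
  if (n < n_dims + 1L)
    stop("nMDS needs at least n_dims + 1 individuals", call. = FALSE)
  dd <- stats::as.dist(dist$values)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- matrix(rnorm(n * n_dims), n, n_dims)
    fit <- vegan::monoMDS(dd, y = init, k = n_dims, model = "global",
                          maxit = max_iter, smin = tol, sfgrmin = tol,
                          sratmax = 1 - max(1e-6, tol))
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  converged <- isTRUE(best$icause != 4L)  # 4 = iteration cap reached
  if (!converged)
    warning("nMDS did not converge within max_iter; returning best solution",
            call. = FALSE)
  coords <- best$points
  rownames(coords) <- dist$labels
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  structure(list(coordinates = coords, stress = best$stress,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 converged = converged),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("nMDS embedding: %d points in %d-D, stress-1 = %.4g (%d restarts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress, x$n_restarts))
  invisible(x)
}

#' Plot an nMDS ordination
#'
#' Scatter of the 2-D embedding with one plotting symbol per group, the
#' conventional ordination view of a Bray-Curtis matrix.
#'
#' @param x an `mds_embedding`.
#' @param groups optional group label per individual (controls symbols).
#' @param ... passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.mds_embedding <- function(x, groups = NULL, ...) {
  co <- x$coordinates
  if (is.null(groups)) {
    graphics::plot(co[, 1], co[, 2], xlab = "MDS1", ylab = "MDS2",
                   main = sprintf("nMDS (stress = %.3f)", x$stress), ...)
  } else {
    g <- as.factor(groups)
    graphics::plot(co[, 1], co[, 2], pch = as.integer(g), col = as.integer(g),
                   xlab = "MDS1", ylab = "MDS2",
                   main = sprintf("nMDS (stress = %.3f)", x$stress), ...)
    graphics::legend("topright", legend = levels(g), pch = seq_along(levels(g)),
                     col = seq_along(levels(g)), bty = "n")
  }
  invisible(x)
}
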