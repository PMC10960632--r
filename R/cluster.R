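#' Voxelwise t statistics
#'
#' Dependent design: one-sample t test on the per-subject condition
#' differences (`maps_a - maps_b`, or `maps_a` alone if it already holds
#' differences). Independent design: pooled-variance two-sample t test
#' comparing the columns of `maps_a` (group 1) against `maps_b`
#' (group 2). Voxels with a missing value in any required subject, or
#' with zero variance, are invalidated (NA) and counted.
#'
#' @param maps_a numeric matrix, voxels x subjects.
#' @param maps_b matrix for the second condition/group, or NULL for a
#'   one-sample test on `maps_a`.
#' @param design `"dependent"` or `"independent"`.
#' @return a `stat_map` list: `t`, `p` (two-sided parametric), `df`,
#'   `design`, `n_invalid`.
#' @export
voxelwise_t <- function(maps_a, maps_b = NULL,
                        design = c("dependent", "independent")) {
  design <- match.arg(design)
  if (design == "dependent") {
    d <- if (is.null(maps_b)) maps_a else maps_a - maps_b
    n <- ncol(d)
    if (n < 2) stop("voxelwise_t: need at least 2 subjects", call. = FALSE)
    ok <- rowSums(is.na(d)) == 0
    m <- rowMeans(d)
    s2 <- rowSums((d - m)^2) / (n - 1)
    tt <- m / sqrt(s2 / n)
    df <- n - 1
  } else {
    if (is.null(maps_b))
      stop("voxelwise_t: independent design needs two groups", call. = FALSE)
    n1 <- ncol(maps_a); n2 <- ncol(maps_b)
    if (n1 < 2 || n2 < 2)
      stop("voxelwise_t: need n >= 2 per group", call. = FALSE)
    ok <- rowSums(is.na(maps_a)) == 0 & rowSums(is.na(maps_b)) == 0
    m1 <- rowMeans(maps_a); m2 <- rowMeans(maps_b)
    s2p <- (rowSums((maps_a - m1)^2) + rowSums((maps_b - m2)^2)) /
      (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(s2p * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tt[!ok | !is.finite(tt)] <- NA_real_
  p <- 2 * stats::pt(-abs(tt), df)
  structure(list(t = tt, p = p, df = df, design = design,
                 n_invalid = sum(is.na(tt))),
            class = "stat_map")
}

# 3-D connected-component labelling of a set of voxels (linear indices)
# under 6- or 26-connectivity, by breadth-first search. Returns an integer
# label per input voxel.
label_components <- function(idx, dim3, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  if (length(idx) == 0) return(integer(0))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6"  = off[nz == 1, , drop = FALSE],
                "18" = off[nz >= 1 & rowSums(off != 0) <= 2, , drop = FALSE],
                "26" = off[nz >= 1, , drop = FALSE])
  member <- logical(prod(dim3))
  member[idx] <- TRUE
  pos_of <- integer(prod(dim3))
  pos_of[idx] <- seq_along(idx)
  labels <- integer(length(idx))
  coords <- arrayInd(idx, dim3)
  lab <- 0L
  for (start in seq_along(idx)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    frontier <- coords[start, , drop = FALSE]
    labels[start] <- lab
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        cbind(frontier[, 1] + off[k, 1], frontier[, 2] + off[k, 2],
              frontier[, 3] + off[k, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dim3[1] +
        (nb[, 3] - 1L) * dim3[1] * dim3[2]
      lin <- unique(lin[member[lin]])
      lin <- lin[labels[pos_of[lin]] == 0L]
      if (length(lin) == 0) break
      labels[pos_of[lin]] <- lab
      frontier <- arrayInd(lin, dim3)
    }
  }
  labels
}

#' Form supra-threshold clusters
#'
#' Thresholds a voxelwise t map at a cluster-forming alpha (two-sided
#' parametric p) and groups adjacent supra-threshold voxels of the same
#' sign into connected components. The cluster statistic is the mass: the
#' sum of the member t values. The minimum-size rule is not applied here
#' but at the reporting stage ([cluster_p()]).
#'
#' @param stat a `stat_map` from [voxelwise_t()].
#' @param dim3 grid dimensions.
#' @param alpha cluster-forming threshold on the voxelwise p.
#' @param connectivity 6, 18 or 26 (3-D adjacency).
#' @return list of clusters, each with `voxels` (linear indices), `size`,
#'   `mass`, `sign`.
#' @export
form_clusters <- function(stat, dim3, alpha = 0.005, connectivity = 26L) {
  tcrit <- stats::qt(1 - alpha / 2, stat$df)
  clusters_from_t(stat$t, dim3, tcrit, connectivity)
}

# Shared fast path: clusters of |t| > tcrit split by sign.
clusters_from_t <- function(tt, dim3, tcrit, connectivity) {
  out <- list()
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(tt) & sgn * tt > tcrit)
    if (length(idx) == 0) next
    labels <- label_components(idx, dim3, connectivity)
    for (l in seq_len(max(labels))) {
      v <- idx[labels == l]
      out[[length(out) + 1L]] <- list(voxels = v, size = length(v),
                                      mass = sum(tt[v]), sign = sgn)
    }
  }
  out
}

# Recompute the max |mass| over clusters for a t vector (0 if none).
max_cluster_mass <- function(tt, dim3, tcrit, connectivity) {
  cl <- clusters_from_t(tt, dim3, tcrit, connectivity)
  if (length(cl) == 0) return(0)
  max(vapply(cl, function(c) abs(c$mass), numeric(1)))
}

# t statistics for the dependent (one-sample on differences) design,
# vectorised over voxels; d is voxels x subjects with no NA rows assumed
# pre-filtered to NA-safe values.
t_one_sample <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / (n - 1)
  tt <- m / sqrt(s2 / n)
  tt[!is.finite(tt)] <- NA_real_
  tt
}

t_two_sample <- function(Y, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  A <- Y[, g1, drop = FALSE]; B <- Y[, g2, drop = FALSE]
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  s2p <- (rowSums((A - m1)^2) + rowSums((B - m2)^2)) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(s2p * (1 / n1 + 1 / n2))
  tt[!is.finite(tt)] <- NA_real_
  tt
}

#' Monte-Carlo null distribution of the maximum cluster mass
#'
#' Dependent design: per permutation the two conditions are swapped
#' independently per subject (a sign flip of the difference map).
#' Independent design: group labels are reshuffled preserving group
#' sizes. For each permutation the voxelwise t map and its supra-threshold
#' clusters are recomputed with identical threshold and connectivity, and
#' the largest absolute cluster mass (over both signs) is recorded; the
#' maximum-statistic convention controls the family-wise error across
#' clusters.
#'
#' @param maps_a,maps_b voxels x subjects matrices (conditions for the
#'   dependent design — `maps_b = NULL` treats `maps_a` as differences;
#'   groups for the independent design).
#' @param dim3 grid dimensions.
#' @param design `"dependent"` or `"independent"`.
#' @param alpha cluster-forming threshold.
#' @param connectivity adjacency (6, 18, 26).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exhaustive if TRUE and the design is dependent with at most 20
#'   subjects, enumerate all `2^n` sign-flip patterns instead of sampling.
#' @return numeric vector of max |mass| values, one per permutation.
#' @export
monte_carlo_null <- function(maps_a, maps_b = NULL, dim3,
                             design = c("dependent", "independent"),
                             alpha = 0.005, connectivity = 26L,
                             n_perm = 1000L, seed = 1L,
                             exhaustive = FALSE) {
  design <- match.arg(design)
  if (n_perm < 1 && !exhaustive)
    stop("monte_carlo_null: n_perm must be >= 1", call. = FALSE)
  set.seed(seed)
  if (design == "dependent") {
    d <- if (is.null(maps_b)) maps_a else maps_a - maps_b
    ok <- rowSums(is.na(d)) == 0
    d <- d[ok, , drop = FALSE]
    n <- ncol(d)
    tcrit <- stats::qt(1 - alpha / 2, n - 1)
    if (exhaustive) {
      if (n > 20)
        stop("monte_carlo_null: exhaustive enumeration limited to n <= 20",
             call. = FALSE)
      signs <- t(as.matrix(expand.grid(rep(list(c(1, -1)), n))))
    } else {
      signs <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), n)
    }
    # sign flips leave the per-voxel sum of squares unchanged, so the
    # one-sample t of every permutation follows from one matrix multiply
    D2 <- rowSums(d * d)
    masses <- numeric(ncol(signs))
    batch <- 256L
    full <- rep(NA_real_, prod(dim3))
    for (start in seq(1L, ncol(signs), by = batch)) {
      cols <- start:min(start + batch - 1L, ncol(signs))
      M <- (d %*% signs[, cols, drop = FALSE]) / n
      s2 <- (D2 - n * M * M) / (n - 1)
      Tm <- M / sqrt(s2 / n)
      for (k in seq_along(cols)) {
        full[ok] <- Tm[, k]
        masses[cols[k]] <- max_cluster_mass(full, dim3, tcrit, connectivity)
      }
    }
    masses
  } else {
    if (is.null(maps_b))
      stop("monte_carlo_null: independent design needs two groups",
           call. = FALSE)
    Y <- cbind(maps_a, maps_b)
    ok <- rowSums(is.na(Y)) == 0
    Y <- Y[ok, , drop = FALSE]
    n1 <- ncol(maps_a); n <- ncol(Y)
    n2 <- n - n1
    tcrit <- stats::qt(1 - alpha / 2, n - 2)
    # per-voxel total sum and sum of squares are permutation-invariant;
    # group-1 sums for all permutations come from one matrix multiply
    # with the 0/1 membership matrix
    G1 <- matrix(0, n, n_perm)
    for (k in seq_len(n_perm)) G1[sample.int(n, n1), k] <- 1
    Stot <- rowSums(Y)
    SStot <- rowSums(Y * Y)
    masses <- numeric(n_perm)
    batch <- 256L
    full <- rep(NA_real_, prod(dim3))
    for (start in seq(1L, n_perm, by = batch)) {
      cols <- start:min(start + batch - 1L, n_perm)
      S1 <- Y %*% G1[, cols, drop = FALSE]
      M1 <- S1 / n1
      M2 <- (Stot - S1) / n2
      s2p <- (SStot - n1 * M1 * M1 - n2 * M2 * M2) / (n - 2)
      Tm <- (M1 - M2) / sqrt(s2p * (1 / n1 + 1 / n2))
      for (k in seq_along(cols)) {
        full[ok] <- Tm[, k]
        masses[cols[k]] <- max_cluster_mass(full, dim3, tcrit, connectivity)
      }
    }
    masses
  }
}

#' Monte-Carlo cluster p values
#'
#' For each observed cluster, `p_mc = (1 + #{null >= |mass|}) /
#' (n_null + 1)` (the add-one convention avoids zero p values). A cluster
#' is flagged significant when `p_mc < p_threshold` and its size reaches
#' `min_size` voxels.
#'
#' @param clusters list from [form_clusters()].
#' @param null numeric vector of permutation max |mass| values.
#' @param min_size minimum cluster extent for significance.
#' @param p_threshold significance level on the Monte-Carlo p.
#' @return a `cluster_result` list: `clusters` (each gaining `p_mc` and
#'   `significant`), `null_distribution`, `n_significant`.
#' @export
cluster_p <- function(clusters, null, min_size = 10L, p_threshold = 0.05) {
  if (length(null) == 0)
    stop("cluster_p: empty null distribution", call. = FALSE)
  clusters <- lapply(clusters, function(cl) {
    cl$p_mc <- (1 + sum(null >= abs(cl$mass))) / (length(null) + 1)
    cl$significant <- cl$p_mc < p_threshold && cl$size >= min_size
    cl
  })
  structure(list(clusters = clusters, null_distribution = null,
                 n_significant = sum(vapply(clusters, `[[`, logical(1),
                                            "significant"))),
            class = "cluster_result")
}

#' Cluster-mass permutation test
#'
#' Convenience wrapper running [voxelwise_t()], [form_clusters()],
#' [monte_carlo_null()] and [cluster_p()] in sequence.
#'
#' @inheritParams monte_carlo_null
#' @param min_size minimum cluster extent for significance.
#' @return a `cluster_result` with the observed `stat_map` attached as
#'   `stat`.
#' @export
cluster_permutation_test <- function(maps_a, maps_b = NULL, dim3,
                                     design = c("dependent", "independent"),
                                     alpha = 0.005, min_size = 10L,
                                     connectivity = 26L, n_perm = 1000L,
                                     seed = 1L) {
  design <- match.arg(design)
  stat <- voxelwise_t(maps_a, maps_b, design)
  obs <- form_clusters(stat, dim3, alpha, connectivity)
  null <- monte_carlo_null(maps_a, maps_b, dim3, design, alpha,
                           connectivity, n_perm, seed)
  res <- cluster_p(obs, null, min_size)
  res$stat <- stat
  res
}

#' Cluster table
#'
#' @param result a `cluster_result`.
#' @param dim3 grid dimensions (for peak coordinates).
#' @return data.frame with one row per cluster: size, mass, sign, peak
#'   voxel coordinates, Monte-Carlo p and significance flag.
#' @export
cluster_table <- function(result, dim3) {
  if (length(result$clusters) == 0)
    return(data.frame(size = integer(0), mass = numeric(0),
                      sign = numeric(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0),
                      p_mc = numeric(0), significant = logical(0)))
  rows <- lapply(result$clusters, function(cl) {
    tvals <- if (!is.null(result$stat)) result$stat$t[cl$voxels] else
      rep(NA_real_, cl$size)
    peak <- cl$voxels[which.max(abs(tvals))]
    pc <- arrayInd(peak, dim3)
    data.frame(size = cl$size, mass = cl$mass, sign = cl$sign,
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
               p_mc = cl$p_mc, significant = cl$significant)
  })
  do.call(rbind, rows)
}
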