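# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately slow and literal: nested loops over searchlight centres and
# trial pairs, so package results can be checked against an implementation
# that shares no code with the fast path.

toy_spec <- function(n_objects = 6L, n_targets = 0L, n_scenes = 3L,
                     seed = 1L) {
  n_paired <- n_objects - n_targets - 1L
  design_spec(n_objects = n_objects, n_object_targets = n_targets,
              n_paired = n_paired, n_baseline = 1L,
              n_scenes = n_scenes, n_scene_targets = 0L,
              retrieval_counts = list(
                old_match = n_paired - 2L, old_mismatch = 1L,
                old_new_scene = 1L, new_objects = 2L),
              seed = seed)
}

toy_betas <- function(design, dim3 = c(4L, 4L, 3L), a_cat = 0.2,
                      b_item = 0.3, seed = 2L) {
  generate_betas(design, signal_params(a_cat, b_item, dim3), seed = seed)
}

# Brute-force neighbourhood of a centre voxel: every in-bounds, in-mask
# voxel whose mm distance from the centre is within the radius.
brute_sphere <- function(center, dim3, mask, spec) {
  r_vox <- spec$radius_mm / spec$voxel_size_mm
  out <- integer(0)
  for (x in 1:dim3[1]) for (y in 1:dim3[2]) for (z in 1:dim3[3]) {
    if (sum((c(x, y, z) - center)^2) <= r_vox^2 + 1e-12) {
      lin <- x + (y - 1) * dim3[1] + (z - 1) * dim3[1] * dim3[2]
      if (mask[lin]) out <- c(out, lin)
    }
  }
  out
}

brute_mean_z <- function(X, pairs) {
  zs <- apply(pairs, 1, function(p) {
    r <- cor(X[, p[1]], X[, p[2]])
    atanh(min(max(r, -(1 - 1e-7)), 1 - 1e-7))
  })
  mean(zs)
}

# Full brute-force item-level maps: loops over every centre voxel.
brute_item_maps <- function(betas, design, spec) {
  td1 <- design[design$phase == "TD1" & design$category == "object" &
                  !design$is_target, ]
  td2 <- design[design$phase == "TD2" & design$category == "object" &
                  !design$is_target, ]
  stim <- intersect(td1$stimulus_id, td2$stimulus_id)
  c1 <- match(td1$trial_id[match(stim, td1$stimulus_id)], betas$trial_id)
  c2 <- match(td2$trial_id[match(stim, td2$stimulus_id)], betas$trial_id)
  n <- length(stim)
  V <- prod(betas$dim3)
  within <- between <- rep(NA_real_, V)
  wpairs <- cbind(c1, c2)
  bp <- expand.grid(i = seq_len(n), j = seq_len(n))
  bp <- bp[bp$i != bp$j, ]
  bpairs <- cbind(c1[bp$i], c2[bp$j])
  for (v in which(betas$mask)) {
    cen <- arrayInd(v, betas$dim3)
    sph <- brute_sphere(cen, betas$dim3, betas$mask, spec)
    if (length(sph) < spec$min_voxels) next
    X <- betas$data[sph, , drop = FALSE]
    within[v] <- brute_mean_z(X, wpairs)
    between[v] <- brute_mean_z(X, bpairs)
  }
  list(within = within, between = between, diff = within - between)
}

brute_category_maps <- function(betas, design, spec) {
  td1 <- design[design$phase == "TD1" & !design$is_target, ]
  obj <- td1[td1$category == "object", ]
  sc <- td1[td1$category == "scene", ]
  co <- match(obj$trial_id, betas$trial_id)
  cs <- match(sc$trial_id, betas$trial_id)
  pr <- t(combn(nrow(obj), 2))
  pr <- pr[obj$run[pr[, 1]] != obj$run[pr[, 2]], , drop = FALSE]
  wpairs <- cbind(co[pr[, 1]], co[pr[, 2]])
  bp <- expand.grid(i = seq_along(co), j = seq_along(cs))
  bpairs <- cbind(co[bp$i], cs[bp$j])
  V <- prod(betas$dim3)
  within <- between <- rep(NA_real_, V)
  for (v in which(betas$mask)) {
    cen <- arrayInd(v, betas$dim3)
    sph <- brute_sphere(cen, betas$dim3, betas$mask, spec)
    if (length(sph) < spec$min_voxels) next
    X <- betas$data[sph, , drop = FALSE]
    within[v] <- brute_mean_z(X, wpairs)
    between[v] <- brute_mean_z(X, bpairs)
  }
  list(within = within, between = between, diff = within - between)
}

# Exhaustive sign-flip null for the dependent design, clustering via
# igraph connected components (independent of the package's BFS labeller).
oracle_signflip_null <- function(d, dim3, alpha, connectivity = 26L) {
  n <- ncol(d)
  tcrit <- qt(1 - alpha / 2, n - 1)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  apply(signs, 1, function(s) {
    ds <- sweep(d, 2, s, `*`)
    m <- rowMeans(ds)
    sdv <- apply(ds, 1, sd)
    tt <- m / (sdv / sqrt(n))
    tt[!is.finite(tt)] <- NA
    best <- 0
    for (sgn in c(1, -1)) {
      idx <- which(!is.na(tt) & sgn * tt > tcrit)
      if (length(idx) == 0) next
      co <- arrayInd(idx, dim3)
      adj <- matrix(FALSE, length(idx), length(idx))
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        dd <- abs(co[a, ] - co[b, ])
        adj[a, b] <- a != b && all(dd <= 1) &&
          (connectivity == 26L || sum(dd) == 1)
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)$membership
      for (k in unique(comp)) best <- max(best, abs(sum(tt[idx[comp == k]])))
    }
    best
  })
}
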