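#' Searchlight specification
#'
#' A spherical searchlight defined in millimetres on an isotropic voxel
#' lattice. The offset set contains every integer voxel displacement whose
#' Euclidean norm in mm is at most `radius_mm`; the centre voxel is always
#' included. With the default 4 mm radius and 2 mm voxels the sphere holds
#' 33 voxels.
#'
#' @param radius_mm searchlight radius in mm.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param min_voxels centres whose (mask-truncated) neighbourhood holds
#'   fewer valid voxels than this are marked invalid.
#' @return an object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius_mm = 4, voxel_size_mm = 2,
                             min_voxels = 5L) {
  stopifnot(radius_mm >= 0, voxel_size_mm > 0)
  structure(list(radius_mm = radius_mm, voxel_size_mm = voxel_size_mm,
                 min_voxels = as.integer(min_voxels)),
            class = "searchlight_spec")
}

#' Lattice offsets of a spherical searchlight
#'
#' @param spec a [searchlight_spec()].
#' @return integer matrix (one row per offset, columns dx, dy, dz in voxel
#'   units) of all lattice points with `||d * voxel_size|| <= radius_mm`.
#' @export
sphere_offsets <- function(spec = searchlight_spec()) {
  r_vox <- spec$radius_mm / spec$voxel_size_mm
  m <- floor(r_vox)
  g <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= r_vox^2 + 1e-12
  as.matrix(g[keep, , drop = FALSE])
}

#' Fisher z transform of a Pearson correlation
#'
#' `atanh` of the correlation after clipping at `1 - 1e-7` in absolute
#' value, keeping the transform finite for identical patterns.
#'
#' @param r correlation(s) in `[-1, 1]` (values beyond by more than 1e-6
#'   raise a domain error).
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-6, na.rm = TRUE))
    stop("fisher_z: |r| > 1", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

# Sparse centre x voxel incidence matrix of the searchlight: N[c, v] = 1
# iff in-mask voxel v lies in the sphere around in-mask centre c. Rows and
# columns are indexed by position within which(mask).
neighbor_matrix <- function(dim3, mask, spec = searchlight_spec()) {
  offsets <- sphere_offsets(spec)
  vox <- which(mask)
  coords <- arrayInd(vox, dim3)
  row_of <- integer(prod(dim3))
  row_of[vox] <- seq_along(vox)
  ii <- jj <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    nb <- cbind(coords[, 1] + offsets[k, 1],
                coords[, 2] + offsets[k, 2],
                coords[, 3] + offsets[k, 3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
      nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
      nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dim3[1] +
      (nb[ok, 3] - 1L) * dim3[1] * dim3[2]
    inm <- mask[lin]
    ii[[k]] <- which(ok)[inm]
    jj[[k]] <- row_of[lin[inm]]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                       dims = c(length(vox), length(vox)))
}

# Core engine: per searchlight centre, the mean Fisher-z Pearson
# correlation over each requested set of trial pairs. Works from sliding
# sufficient statistics (sums, sums of squares and cross-products
# aggregated over the sphere by one sparse multiply), so the cost is a few
# dense matrix operations per chunk of pairs rather than a loop over
# centres.
#
# X: voxels-in-mask x trials matrix; N: output of neighbor_matrix();
# pair_sets: named list of 2-column index matrices into columns of X.
# Returns a named list of per-centre mean-z vectors (length nrow(N)), with
# NA at centres having fewer than min_voxels neighbours.
searchlight_pair_means <- function(X, N, pair_sets, min_voxels = 5L,
                                   chunk = 4000L) {
  n_c <- Matrix::rowSums(N)
  S1 <- as.matrix(N %*% X)
  S2 <- as.matrix(N %*% (X * X))
  invalid <- n_c < min_voxels
  lapply(pair_sets, function(P) {
    P <- as.matrix(P)
    if (nrow(P) == 0) return(rep(NA_real_, nrow(N)))
    acc <- numeric(nrow(N))
    cnt <- numeric(nrow(N))
    for (start in seq(1L, nrow(P), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(P))
      i <- P[idx, 1]; j <- P[idx, 2]
      Sxy <- as.matrix(N %*% (X[, i, drop = FALSE] * X[, j, drop = FALSE]))
      num <- Sxy - S1[, i, drop = FALSE] * S1[, j, drop = FALSE] / n_c
      vi <- pmax(S2[, i, drop = FALSE] - S1[, i, drop = FALSE]^2 / n_c, 0)
      vj <- pmax(S2[, j, drop = FALSE] - S1[, j, drop = FALSE]^2 / n_c, 0)
      r <- num / sqrt(vi * vj)
      r[!is.finite(r)] <- NA
      z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
      acc <- acc + rowSums(z, na.rm = TRUE)
      cnt <- cnt + rowSums(!is.na(z))
    }
    v <- acc / cnt
    v[invalid] <- NA_real_
    v
  })
}

# Expand a vector defined on which(mask) to full grid length with NA.
expand_to_grid <- function(values, mask) {
  full <- rep(NA_real_, length(mask))
  full[mask] <- values
  full
}

new_distinctiveness_maps <- function(maps, dim3, valid_mask,
                                     subject_id = NA_integer_) {
  structure(c(maps, list(dim3 = dim3, valid_mask = valid_mask,
                         subject_id = subject_id)),
            class = "distinctiveness_maps")
}

# Column indices in the beta series for a set of trial ids.
beta_cols <- function(betas, trial_ids) {
  idx <- match(trial_ids, betas$trial_id)
  if (anyNA(idx))
    stop("trials absent from beta series", call. = FALSE)
  idx
}

#' Item-level distinctiveness searchlight maps
#'
#' For every searchlight centre, within-item similarity is the mean
#' Fisher-z Pearson correlation between each object's TD1 pattern and the
#' same object's TD2 pattern; between-item similarity is the mean over all
#' TD1-object x TD2-object pairs excluding the same-object pairs. Their
#' difference is item-level distinctiveness. Target-detection targets are
#' excluded; all pairs are cross-phase and therefore cross-run.
#'
#' @param betas a [beta_series()].
#' @param design trial table.
#' @param spec a [searchlight_spec()].
#' @param stimuli optional vector of object stimulus ids to restrict the
#'   analysis to (used for subsequent-memory splits); default all
#'   non-target objects present in both phases.
#' @return a `distinctiveness_maps` object with full-grid vectors
#'   `within_item`, `between_item`, `item_diff` and a `valid_mask`.
#' @export
item_distinctiveness <- function(betas, design, spec = searchlight_spec(),
                                 stimuli = NULL) {
  td1 <- design[design$phase == "TD1" & design$category == "object" &
                  !design$is_target, ]
  td2 <- design[design$phase == "TD2" & design$category == "object" &
                  !design$is_target, ]
  stim <- intersect(td1$stimulus_id, td2$stimulus_id)
  if (!is.null(stimuli)) stim <- intersect(stim, stimuli)
  if (length(stim) < 2)
    stop("item_distinctiveness: need at least 2 objects present in both ",
         "phases", call. = FALSE)
  t1 <- td1$trial_id[match(stim, td1$stimulus_id)]
  t2 <- td2$trial_id[match(stim, td2$stimulus_id)]
  c1 <- beta_cols(betas, t1)
  c2 <- beta_cols(betas, t2)

  n <- length(stim)
  all_pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  between <- all_pairs[all_pairs$i != all_pairs$j, ]

  mask <- betas$mask
  N <- neighbor_matrix(betas$dim3, mask, spec)
  X <- betas$data[mask, , drop = FALSE]
  res <- searchlight_pair_means(
    X, N,
    list(within = cbind(c1, c2),
         between = cbind(c1[between$i], c2[between$j])),
    min_voxels = spec$min_voxels)

  within <- expand_to_grid(res$within, mask)
  betw <- expand_to_grid(res$between, mask)
  valid <- !is.na(within) & !is.na(betw)
  new_distinctiveness_maps(
    list(within_item = within, between_item = betw,
         item_diff = within - betw),
    betas$dim3, valid)
}

#' Category-level distinctiveness searchlight maps
#'
#' Within-category similarity is the mean Fisher-z correlation over all
#' TD1 object-object pairs from different runs (same-run pairs are
#' excluded to avoid time-dependent correlation of the haemodynamic
#' responses); between-category similarity is the mean over all TD1
#' object-scene pairs (cross-run by design, scenes occupying their own
#' run). Their difference is category-level distinctiveness.
#'
#' @inheritParams item_distinctiveness
#' @param stimuli optional object stimulus ids restricting the anchor set
#'   of objects (pairs are formed within the restricted set; scenes are
#'   never restricted).
#' @return a `distinctiveness_maps` object with `within_category`,
#'   `between_category`, `category_diff` and `valid_mask`.
#' @export
category_distinctiveness <- function(betas, design,
                                     spec = searchlight_spec(),
                                     stimuli = NULL) {
  td1 <- design[design$phase == "TD1" & !design$is_target, ]
  obj <- td1[td1$category == "object", ]
  sc <- td1[td1$category == "scene", ]
  if (!is.null(stimuli)) obj <- obj[obj$stimulus_id %in% stimuli, ]
  if (nrow(sc) == 0)
    stop("category_distinctiveness: no scene trials in TD1", call. = FALSE)
  if (length(unique(obj$run)) < 2)
    stop("category_distinctiveness: all objects in one run, no cross-run ",
         "object pairs", call. = FALSE)
  co <- beta_cols(betas, obj$trial_id)
  cs <- beta_cols(betas, sc$trial_id)

  no <- nrow(obj)
  pr <- t(utils::combn(no, 2))
  pr <- pr[obj$run[pr[, 1]] != obj$run[pr[, 2]], , drop = FALSE]
  osp <- expand.grid(i = seq_len(no), j = seq_len(nrow(sc)))

  mask <- betas$mask
  N <- neighbor_matrix(betas$dim3, mask, spec)
  X <- betas$data[mask, , drop = FALSE]
  res <- searchlight_pair_means(
    X, N,
    list(within = cbind(co[pr[, 1]], co[pr[, 2]]),
         between = cbind(co[osp$i], cs[osp$j])),
    min_voxels = spec$min_voxels)

  within <- expand_to_grid(res$within, mask)
  betw <- expand_to_grid(res$between, mask)
  valid <- !is.na(within) & !is.na(betw)
  new_distinctiveness_maps(
    list(within_category = within, between_category = betw,
         category_diff = within - betw),
    betas$dim3, valid)
}

#' Scene-pairing control contrasts
#'
#' Tests whether the object-scene association phase left a scene trace in
#' the object patterns: per phase, the similarity of objects paired with
#' the same scene (within-scene) minus the similarity of objects paired
#' with different scenes (between-scene), both restricted to cross-run
#' pairs; the reported contrast is the TD2 minus TD1 difference of these
#' session-internal contrasts.
#'
#' @inheritParams item_distinctiveness
#' @param variant `"all"` uses every paired non-target object;
#'   `"pair_correct_only"` keeps objects with a correct subsequent pair
#'   response; `"strong_memory_scenes"` keeps objects belonging to scenes
#'   for which between `strong_range[1]` and `strong_range[2]` of the
#'   paired objects were correctly remembered.
#' @param strong_range integer 2-vector defining a strong-memory scene.
#' @return list with full-grid vectors `contrast`, `td1`, `td2`, the
#'   `valid_mask`, and `empty = TRUE` (with all-NA maps) when no objects
#'   qualify under the variant.
#' @export
scene_pairing_controls <- function(betas, design,
                                   spec = searchlight_spec(),
                                   variant = c("all", "pair_correct_only",
                                               "strong_memory_scenes"),
                                   strong_range = c(3L, 5L)) {
  variant <- match.arg(variant)
  keep <- design[design$phase == "TD1" & design$category == "object" &
                   !design$is_target & !is.na(design$paired_scene_id), ]
  eligible <- unique(keep$stimulus_id)
  ret <- design[design$phase == "RETRIEVAL" & design$condition != "new", ]
  if (variant == "pair_correct_only") {
    eligible <- intersect(eligible,
                          ret$stimulus_id[ret$pair_outcome == "correct"])
  } else if (variant == "strong_memory_scenes") {
    scene_of <- keep$paired_scene_id[match(ret$stimulus_id, keep$stimulus_id)]
    ncorr <- tapply(ret$pair_outcome == "correct", scene_of, sum)
    strong <- as.integer(names(ncorr)[ncorr >= strong_range[1] &
                                        ncorr <= strong_range[2]])
    eligible <- intersect(
      eligible, keep$stimulus_id[keep$paired_scene_id %in% strong])
  }
  if (length(eligible) < 2)
    return(list(contrast = rep(NA_real_, prod(betas$dim3)),
                td1 = NULL, td2 = NULL,
                valid_mask = rep(FALSE, prod(betas$dim3)), empty = TRUE))

  mask <- betas$mask
  N <- neighbor_matrix(betas$dim3, mask, spec)
  X <- betas$data[mask, , drop = FALSE]

  phase_contrast <- function(phase) {
    ph <- design[design$phase == phase & design$category == "object" &
                   !design$is_target & design$stimulus_id %in% eligible, ]
    scene_id <- keep$paired_scene_id[match(ph$stimulus_id, keep$stimulus_id)]
    cols <- beta_cols(betas, ph$trial_id)
    pr <- t(utils::combn(nrow(ph), 2))
    pr <- pr[ph$run[pr[, 1]] != ph$run[pr[, 2]], , drop = FALSE]
    same <- scene_id[pr[, 1]] == scene_id[pr[, 2]]
    if (!any(same) || all(same)) return(NULL)
    res <- searchlight_pair_means(
      X, N,
      list(within = cbind(cols[pr[same, 1]], cols[pr[same, 2]]),
           between = cbind(cols[pr[!same, 1]], cols[pr[!same, 2]])),
      min_voxels = spec$min_voxels)
    expand_to_grid(res$within - res$between, mask)
  }

  td1 <- phase_contrast("TD1")
  td2 <- phase_contrast("TD2")
  if (is.null(td1) || is.null(td2))
    return(list(contrast = rep(NA_real_, prod(betas$dim3)),
                td1 = td1, td2 = td2,
                valid_mask = rep(FALSE, prod(betas$dim3)), empty = TRUE))
  contrast <- td2 - td1
  list(contrast = contrast, td1 = td1, td2 = td2,
       valid_mask = !is.na(contrast), empty = FALSE)
}

#' Trial-wise distinctiveness within a mask
#'
#' Computes one distinctiveness value per object using the mask-restricted
#' voxel pattern as a single vector (no searchlight). At the item level
#' the value is the Fisher-z correlation of the object's TD1 and TD2
#' patterns minus the mean Fisher-z correlation of its TD1 pattern with
#' all other objects' TD2 patterns. At the category level it is the mean
#' correlation with all other TD1 objects from different runs minus the
#' mean correlation with all TD1 scenes.
#'
#' @param betas a [beta_series()].
#' @param design trial table.
#' @param mask logical vector over the grid (or vector of voxel indices);
#'   typically a back-projected cluster mask.
#' @param level `"item"` or `"category"`.
#' @return data.frame with `trial_id` (the object's TD1 trial),
#'   `stimulus_id` and `value`; objects with no eligible partner get NA.
#' @export
trialwise_distinctiveness <- function(betas, design, mask,
                                      level = c("item", "category")) {
  level <- match.arg(level)
  if (!is.logical(mask)) {
    m <- logical(prod(betas$dim3)); m[mask] <- TRUE; mask <- m
  }
  mask <- mask & betas$mask
  if (!any(mask)) stop("trialwise_distinctiveness: empty mask",
                       call. = FALSE)
  td1 <- design[design$phase == "TD1" & design$category == "object" &
                  !design$is_target, ]
  X <- betas$data[mask, , drop = FALSE]
  if (level == "item") {
    td2 <- design[design$phase == "TD2" & design$category == "object" &
                    !design$is_target, ]
    stim <- intersect(td1$stimulus_id, td2$stimulus_id)
    t1 <- td1$trial_id[match(stim, td1$stimulus_id)]
    t2 <- td2$trial_id[match(stim, td2$stimulus_id)]
    Z <- fisher_z(stats::cor(X[, beta_cols(betas, t1), drop = FALSE],
                             X[, beta_cols(betas, t2), drop = FALSE]))
    n <- length(stim)
    value <- vapply(seq_len(n), function(i) {
      others <- Z[i, -i]
      if (length(others) == 0) return(NA_real_)
      Z[i, i] - mean(others)
    }, numeric(1))
    data.frame(trial_id = t1, stimulus_id = stim, value = value)
  } else {
    sc <- design[design$phase == "TD1" & design$category == "scene" &
                   !design$is_target, ]
    if (nrow(sc) == 0)
      stop("trialwise_distinctiveness: no scenes for category level",
           call. = FALSE)
    co <- beta_cols(betas, td1$trial_id)
    cs <- beta_cols(betas, sc$trial_id)
    Zoo <- fisher_z(stats::cor(X[, co, drop = FALSE]))
    Zos <- fisher_z(stats::cor(X[, co, drop = FALSE],
                               X[, cs, drop = FALSE]))
    n <- nrow(td1)
    value <- vapply(seq_len(n), function(i) {
      elig <- td1$run != td1$run[i]
      if (!any(elig)) return(NA_real_)
      mean(Zoo[i, elig]) - mean(Zos[i, ])
    }, numeric(1))
    data.frame(trial_id = td1$trial_id, stimulus_id = td1$stimulus_id,
               value = value)
  }
}

#' Group valid-voxel mask
#'
#' Intersection of the per-subject valid masks: only voxels for which the
#' searchlight metric is available in every subject enter group analyses.
#'
#' @param maps list of `distinctiveness_maps` (or any objects with a
#'   logical `valid_mask` element).
#' @return logical vector.
#' @export
group_valid_mask <- function(maps) {
  Reduce(`&`, lapply(maps, `[[`, "valid_mask"))
}
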