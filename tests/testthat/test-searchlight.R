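test_that("sphere offsets enumerate the exact lattice ball", {
  expect_equal(nrow(sphere_offsets(searchlight_spec(4, 2))), 33L)
  expect_equal(nrow(sphere_offsets(searchlight_spec(2, 2))), 7L)
  expect_equal(nrow(sphere_offsets(searchlight_spec(0, 2))), 1L)
  # brute-force recount at radius 4 mm / 2 mm voxels
  cnt <- 0L
  for (x in -2:2) for (y in -2:2) for (z in -2:2)
    if (x^2 + y^2 + z^2 <= 4) cnt <- cnt + 1L
  expect_equal(nrow(sphere_offsets(searchlight_spec(4, 2))), cnt)
})

test_that("fisher_z is the clipped atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "\\|r\\| > 1")
})

test_that("item searchlight maps equal the brute-force oracle", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d)
  spec <- searchlight_spec(2, 2, min_voxels = 1)
  m <- item_distinctiveness(b, d, spec)
  o <- brute_item_maps(b, d, spec)
  expect_equal(m$within_item, o$within, tolerance = 1e-12)
  expect_equal(m$between_item, o$between, tolerance = 1e-12)
  expect_equal(m$item_diff, m$within_item - m$between_item)
})

test_that("category searchlight maps equal the brute-force oracle", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d)
  spec <- searchlight_spec(2, 2, min_voxels = 1)
  m <- category_distinctiveness(b, d, spec)
  o <- brute_category_maps(b, d, spec)
  expect_equal(m$within_category, o$within, tolerance = 1e-12)
  expect_equal(m$between_category, o$between, tolerance = 1e-12)

  # all objects in one run: no valid cross-run pairs
  d1 <- d
  d1$run[d1$phase == "TD1" & d1$category == "object"] <- 1L
  expect_error(category_distinctiveness(b, d1, spec), "one run")
})

test_that("identical TD2 patterns produce large within-item similarity", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d, a_cat = 0, b_item = 0, seed = 9)
  # copy each TD1 object pattern into its TD2 trial
  td1 <- d[d$phase == "TD1" & d$category == "object", ]
  td2 <- d[d$phase == "TD2", ]
  for (s in td1$stimulus_id) {
    i1 <- match(td1$trial_id[td1$stimulus_id == s], b$trial_id)
    i2 <- match(td2$trial_id[td2$stimulus_id == s], b$trial_id)
    b$data[, i2] <- b$data[, i1]
  }
  spec <- searchlight_spec(2, 2, min_voxels = 1)
  m <- item_distinctiveness(b, d, spec)
  v <- which(m$valid_mask)
  expect_true(all(m$within_item[v] > atanh(1 - 1e-7) - 1e-9))
  expect_lt(max(abs(m$between_item[v])), 2)

  # trial-wise item value at identical patterns: z(1-) - z(1-) terms drop
  tw <- trialwise_distinctiveness(b, d, rep(TRUE, prod(b$dim3)), "item")
  expect_true(all(tw$value > 0))
})

test_that("trial-wise values match a brute-force loop and aggregate", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d)
  mask <- rep(TRUE, prod(b$dim3))
  tw <- trialwise_distinctiveness(b, d, mask, "item")

  td1 <- d[d$phase == "TD1" & d$category == "object", ]
  td2 <- d[d$phase == "TD2", ]
  X <- b$data
  z <- function(i, j) atanh(min(max(cor(X[, i], X[, j]), -(1 - 1e-7)),
                                1 - 1e-7))
  for (k in seq_len(nrow(tw))) {
    s <- tw$stimulus_id[k]
    i1 <- match(td1$trial_id[td1$stimulus_id == s], b$trial_id)
    own <- z(i1, match(td2$trial_id[td2$stimulus_id == s], b$trial_id))
    others <- vapply(setdiff(td2$stimulus_id, s), function(s2)
      z(i1, match(td2$trial_id[td2$stimulus_id == s2], b$trial_id)),
      numeric(1))
    expect_equal(tw$value[k], own - mean(others), tolerance = 1e-12)
  }

  # subject mean of trial-wise item values equals the mask-level
  # within-minus-between difference (equal partner counts per object)
  n <- nrow(td1)
  i1 <- match(td1$trial_id, b$trial_id)
  i2 <- match(td2$trial_id[match(td1$stimulus_id, td2$stimulus_id)],
              b$trial_id)
  within <- mean(vapply(seq_len(n), function(k) z(i1[k], i2[k]),
                        numeric(1)))
  between <- mean(unlist(lapply(seq_len(n), function(i)
    vapply(setdiff(seq_len(n), i), function(j) z(i1[i], i2[j]),
           numeric(1)))))
  expect_equal(mean(tw$value), within - between, tolerance = 1e-12)

  # category level against brute force
  twc <- trialwise_distinctiveness(b, d, mask, "category")
  sc <- d[d$phase == "TD1" & d$category == "scene", ]
  for (k in seq_len(nrow(twc))) {
    i1k <- match(twc$trial_id[k], b$trial_id)
    r1 <- td1$run[match(twc$stimulus_id[k], td1$stimulus_id)]
    part <- td1[td1$run != r1, ]
    wo <- mean(vapply(part$trial_id, function(t2)
      z(i1k, match(t2, b$trial_id)), numeric(1)))
    bo <- mean(vapply(sc$trial_id, function(t2)
      z(i1k, match(t2, b$trial_id)), numeric(1)))
    expect_equal(twc$value[k], wo - bo, tolerance = 1e-12)
  }

  expect_error(trialwise_distinctiveness(b, d, rep(FALSE, prod(b$dim3))),
               "empty mask")
})

test_that("maps are invariant to trial order and mask edges invalidate", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d)
  spec <- searchlight_spec(2, 2, min_voxels = 1)
  m1 <- item_distinctiveness(b, d, spec)

  perm <- sample(ncol(b$data))
  b2 <- beta_series(b$data[, perm], b$dim3, b$trial_id[perm])
  m2 <- item_distinctiveness(b2, d, spec)
  expect_equal(m1$within_item, m2$within_item)
  expect_equal(m1$item_diff, m2$item_diff)

  # min_voxels larger than any truncated sphere invalidates everything
  strict <- searchlight_spec(0, 2, min_voxels = 5)
  m3 <- item_distinctiveness(b, d, strict)
  expect_true(all(is.na(m3$item_diff)))
  expect_true(!any(m3$valid_mask))

  # group mask is the intersection of subject masks
  ma <- list(valid_mask = c(TRUE, TRUE, FALSE))
  mb <- list(valid_mask = c(TRUE, FALSE, FALSE))
  expect_equal(group_valid_mask(list(ma, mb)), c(TRUE, FALSE, FALSE))
})

test_that("scene-pairing controls are null by construction and detect an
          injected scene trace", {
  sp <- design_spec(n_objects = 13, n_object_targets = 0, n_paired = 12,
                    n_baseline = 1, n_scenes = 4, n_scene_targets = 0,
                    retrieval_counts = list(old_match = 6, old_mismatch = 4,
                                            old_new_scene = 2,
                                            new_objects = 4), seed = 3)
  d <- generate_design(sp)
  spec <- searchlight_spec(2, 2, min_voxels = 1)

  # pairing-agnostic generator: expected contrast 0 (check oracle equality
  # and that the mean over voxels is near zero)
  b <- toy_betas(d, a_cat = 0.2, b_item = 0.2, seed = 6)
  res <- scene_pairing_controls(b, d, spec, "all")
  expect_false(res$empty)
  expect_lt(abs(mean(res$contrast, na.rm = TRUE)), 0.1)

  # oracle equality for the TD1 session contrast on a toy
  keep <- d[d$phase == "TD1" & d$category == "object" &
              !is.na(d$paired_scene_id), ]
  cols <- match(keep$trial_id, b$trial_id)
  pr <- t(combn(nrow(keep), 2))
  pr <- pr[keep$run[pr[, 1]] != keep$run[pr[, 2]], , drop = FALSE]
  same <- keep$paired_scene_id[pr[, 1]] == keep$paired_scene_id[pr[, 2]]
  v <- which(b$mask)[1]
  cen <- arrayInd(v, b$dim3)
  sph <- brute_sphere(cen, b$dim3, b$mask, spec)
  X <- b$data[sph, ]
  w <- brute_mean_z(X, cbind(cols[pr[same, 1]], cols[pr[same, 2]]))
  bt <- brute_mean_z(X, cbind(cols[pr[!same, 1]], cols[pr[!same, 2]]))
  expect_equal(res$td1[v], w - bt, tolerance = 1e-12)

  # inject the paired scene's pattern into TD2 object trials only
  b2 <- b
  scene_pat <- lapply(unique(keep$paired_scene_id), function(s)
    rnorm(prod(b$dim3)))
  names(scene_pat) <- as.character(unique(keep$paired_scene_id))
  td2 <- d[d$phase == "TD2", ]
  for (k in seq_len(nrow(td2))) {
    ps <- keep$paired_scene_id[match(td2$stimulus_id[k], keep$stimulus_id)]
    if (is.na(ps)) next
    i <- match(td2$trial_id[k], b2$trial_id)
    b2$data[, i] <- b2$data[, i] + 1.5 * scene_pat[[as.character(ps)]]
  }
  res2 <- scene_pairing_controls(b2, d, spec, "all")
  expect_gt(mean(res2$contrast, na.rm = TRUE), 0.2)

  # a variant with no qualifying objects flags empty
  d_none <- d
  d_none$pair_outcome[d_none$phase == "RETRIEVAL"] <- "incorrect"
  res3 <- scene_pairing_controls(b, d_none, spec, "pair_correct_only")
  expect_true(res3$empty)
})

test_that("recovered variance fractions track the generator parameters", {
  # monotonicity of the category and item contrasts in a_cat / b_item at a
  # modest voxel count
  d <- generate_design(toy_spec(n_objects = 9, n_scenes = 4))
  mask_all <- function(b) rep(TRUE, prod(b$dim3))
  est <- function(a_cat, b_item) {
    b <- generate_betas(d, signal_params(a_cat, b_item, c(12, 12, 10)),
                        seed = 21)
    twc <- trialwise_distinctiveness(b, d, mask_all(b), "category")
    twi <- trialwise_distinctiveness(b, d, mask_all(b), "item")
    c(cat = mean(twc$value), item = mean(twi$value))
  }
  e1 <- est(0.05, 0.05); e2 <- est(0.15, 0.15); e3 <- est(0.30, 0.30)
  expect_true(e1["cat"] < e2["cat"] && e2["cat"] < e3["cat"])
  expect_true(e1["item"] < e2["item"] && e2["item"] < e3["item"])
})
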