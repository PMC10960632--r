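test_that("default design reproduces the study trial structure", {
  d <- generate_design(design_spec())
  td1_obj <- d[d$phase == "TD1" & d$category == "object", ]
  expect_equal(unname(table(td1_obj$run)), c(106L, 107L, 107L),
               ignore_attr = TRUE)
  expect_equal(sum(td1_obj$is_target), 20L)

  td2 <- d[d$phase == "TD2", ]
  expect_equal(unname(table(td2$run)), c(106L, 107L, 107L),
               ignore_attr = TRUE)
  expect_true(all(td2$category == "object"))

  ret <- d[d$phase == "RETRIEVAL", ]
  expect_equal(unname(table(ret$condition)[c("old_match", "old_mismatch",
                                             "old_new_scene", "new")]),
               c(100L, 100L, 50L, 150L), ignore_attr = TRUE)
  expect_equal(length(unique(ret$stimulus_id[ret$condition != "new"])),
               250L)

  # scenes only in TD1, every non-target object in both phases exactly once
  sc <- d[d$category == "scene", ]
  expect_true(all(sc$phase == "TD1"))
  nt <- td1_obj$stimulus_id[!td1_obj$is_target]
  expect_true(all(table(td2$stimulus_id[td2$stimulus_id %in% nt]) == 1))
  expect_equal(sort(unique(td2$stimulus_id)), sort(td1_obj$stimulus_id))

  # run labels globally unique across phases
  expect_equal(length(unique(d$run)), 4L + 3L + 1L)

  # exactly 5 paired objects per old scene
  pairing <- unique(d[!is.na(d$paired_scene_id) & d$phase == "TD1",
                      c("stimulus_id", "paired_scene_id")])
  expect_true(all(table(pairing$paired_scene_id) == 5))
})

test_that("tiny designs split evenly and inconsistent counts error", {
  sp <- design_spec(n_objects = 4, n_object_targets = 0, n_paired = 3,
                    n_baseline = 1, n_scenes = 2, n_scene_targets = 0,
                    n_object_runs_phase1 = 2, n_object_runs_phase2 = 2,
                    retrieval_counts = list(old_match = 1, old_mismatch = 1,
                                            old_new_scene = 1,
                                            new_objects = 2))
  d <- generate_design(sp)
  td1 <- d[d$phase == "TD1" & d$category == "object", ]
  expect_equal(unname(table(td1$run)), c(2L, 2L), ignore_attr = TRUE)
  td2 <- d[d$phase == "TD2", ]
  expect_setequal(td2$stimulus_id, td1$stimulus_id)

  expect_error(design_spec(n_objects = 10, n_object_targets = 2,
                           n_paired = 5, n_baseline = 2),
               "n_object_targets \\+ n_paired \\+ n_baseline")
  expect_error(design_spec(retrieval_counts = list(old_match = 99,
                                                   old_mismatch = 100,
                                                   old_new_scene = 50,
                                                   new_objects = 150)),
               "old_match \\+ old_mismatch")
})

test_that("same seed gives a bit-identical design and cohort", {
  sp <- toy_spec(seed = 11L)
  expect_identical(generate_design(sp), generate_design(sp))

  gp <- list(young = signal_params(0.2, 0.1, c(4, 4, 3)),
             old = signal_params(0.1, 0.05, c(4, 4, 3)))
  c1 <- generate_cohort(2, 2, gp, toy_spec(), seed = 5)
  c2 <- generate_cohort(2, 2, gp, toy_spec(), seed = 5)
  expect_identical(c1, c2)
  expect_equal(length(c1), 4L)
  expect_equal(vapply(c1, `[[`, character(1), "group"),
               c("young", "young", "old", "old"))
  expect_equal(length(generate_cohort(0, 3, gp, toy_spec(), seed = 1)), 3L)
})

test_that("signal model yields the designed correlation structure", {
  d <- generate_design(toy_spec())
  # no noise, pure item signal: within-item cross-phase correlation is 1
  b1 <- generate_betas(d, signal_params(0, 1, c(5, 5, 4)), seed = 3)
  td1 <- d[d$phase == "TD1" & d$category == "object", ]
  td2 <- d[d$phase == "TD2", ]
  i1 <- match(td1$trial_id, b1$trial_id)
  i2 <- match(td2$trial_id[match(td1$stimulus_id, td2$stimulus_id)],
              b1$trial_id)
  r_same <- vapply(seq_along(i1), function(k)
    cor(b1$data[, i1[k]], b1$data[, i2[k]]), numeric(1))
  expect_equal(r_same, rep(1, length(i1)), tolerance = 1e-12)

  # pure noise: correlations centred at zero
  b0 <- generate_betas(d, signal_params(0, 0, c(12, 12, 12)), seed = 4)
  i1b <- match(td1$trial_id, b0$trial_id)
  r0 <- cor(b0$data[, i1b[1]], b0$data[, i1b[2]])
  expect_lt(abs(r0), 4 / sqrt(prod(b0$dim3)))

  # a_cat = 0.3, b_item = 0.2 at 1e5 voxels: same-category r ~ 0.30,
  # same-item cross-phase r ~ 0.50
  bb <- generate_betas(d, signal_params(0.3, 0.2, c(50, 50, 40)), seed = 5)
  j1 <- match(td1$trial_id, bb$trial_id)
  j2 <- match(td2$trial_id[match(td1$stimulus_id, td2$stimulus_id)],
              bb$trial_id)
  r_cat <- mean(apply(combn(length(j1), 2), 2, function(p)
    cor(bb$data[, j1[p[1]]], bb$data[, j1[p[2]]])))
  r_item <- mean(vapply(seq_along(j1), function(k)
    cor(bb$data[, j1[k]], bb$data[, j2[k]]), numeric(1)))
  expect_equal(r_cat, 0.30, tolerance = 0.02)
  expect_equal(r_item, 0.50, tolerance = 0.02)

  expect_error(signal_params(0.7, 0.5, c(4, 4, 4)), "a_cat \\+ b_item")
})

test_that("memory outcomes follow the logistic generating model", {
  sp <- design_spec()  # 250 paired trials for stable rates
  d <- generate_design(sp)
  paired <- unique(d$stimulus_id[d$phase == "RETRIEVAL" &
                                   d$condition != "new"])
  set.seed(8)
  distinct <- data.frame(stimulus_id = paired,
                         d_item = rnorm(length(paired)),
                         d_cat = rnorm(length(paired)))

  # flat model: hit rate ~ 0.5 within 3 SE of 250 trials
  m0 <- generate_memory(d, distinct, memory_model(0, 0, 0, seed = 1))
  ret <- m0[m0$phase == "RETRIEVAL" & m0$condition != "new", ]
  hr <- mean(ret$item_outcome == "hit")
  expect_lt(abs(hr - 0.5), 3 * sqrt(0.25 / 250))

  # saturated intercept: all hits
  msat <- generate_memory(d, distinct, memory_model(50, 0, 0, seed = 2))
  ret2 <- msat[msat$phase == "RETRIEVAL" & msat$condition != "new", ]
  expect_true(all(ret2$item_outcome == "hit"))

  # category-driven outcomes: hit and miss groups separate in d_cat
  mc <- generate_memory(d, distinct,
                        memory_model(0, 0, beta1_cat = 2, seed = 3))
  ret3 <- mc[mc$phase == "RETRIEVAL" & mc$condition != "new", ]
  dmap <- distinct$d_cat[match(ret3$stimulus_id, distinct$stimulus_id)]
  expect_gt(mean(dmap[ret3$item_outcome == "hit"]),
            mean(dmap[ret3$item_outcome == "miss"]) + 0.3)
  # overall rate still ~ 0.5 by symmetry
  expect_lt(abs(mean(ret3$item_outcome == "hit") - 0.5), 0.1)

  # outcomes propagate to encoding trials, targets stay outcome-free
  enc <- mc[mc$phase == "TD1" & mc$category == "object", ]
  expect_true(all(enc$item_outcome[enc$is_target] == "none"))
  expect_true(any(enc$item_outcome %in% c("hit", "miss")))

  # alignment error when a paired stimulus has no distinctiveness value
  expect_error(generate_memory(d, distinct[-1, ], memory_model(seed = 4)),
               "missing distinctiveness")
})
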