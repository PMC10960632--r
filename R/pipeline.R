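#' Pipeline configuration
#'
#' Collects every tunable stage parameter of the end-to-end analysis with
#' per-stage seeds, so any stage can be rerun in isolation and an
#' identical configuration reproduces the report bit for bit. The default
#' is a desk-scale demonstration cohort (two groups of 8 subjects on a
#' 12^3 grid with 40 objects); the full study design is obtained by
#' passing `design = design_spec()` and the full group sizes.
#'
#' @param n_young,n_old group sizes.
#' @param design a [design_spec()] (per-subject seeds are derived from
#'   the master seed).
#' @param grid_shape simulation grid.
#' @param signal_region linear voxel indices of the signal-carrying
#'   region; default a central block of the grid.
#' @param group_acat,group_bitem named numeric vectors (`young`, `old`)
#'   of category-shared and item-specific variance fractions.
#' @param memory a [memory_model()] driving recognition outcomes from
#'   trial-wise distinctiveness, or NULL for outcome-free simulation.
#' @param radius_mm,voxel_size_mm,min_voxels searchlight geometry.
#' @param alpha,min_size,connectivity,n_perm cluster-permutation
#'   settings.
#' @param n_perm_plsc,n_boot_plsc PLSC resampling sizes.
#' @param do_memory_split run the subsequent-memory searchlight split.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_young = 8L, n_old = 8L,
                            design = NULL,
                            grid_shape = c(12L, 12L, 12L),
                            signal_region = NULL,
                            group_acat = c(young = 0.10, old = 0.05),
                            group_bitem = c(young = 0.10, old = 0.05),
                            memory = memory_model(beta0 = 0.4,
                                                  beta1_item = 2,
                                                  beta1_cat = 2),
                            radius_mm = 4, voxel_size_mm = 2,
                            min_voxels = 5L,
                            alpha = 0.005, min_size = 10L,
                            connectivity = 26L, n_perm = 200L,
                            n_perm_plsc = 1000L, n_boot_plsc = 1000L,
                            do_memory_split = FALSE,
                            seed = 1L) {
  if (is.null(design))
    design <- design_spec(n_objects = 40L, n_object_targets = 4L,
                          n_paired = 30L, n_baseline = 6L,
                          n_scenes = 10L, n_scene_targets = 2L,
                          retrieval_counts = list(old_match = 12L,
                                                  old_mismatch = 12L,
                                                  old_new_scene = 6L,
                                                  new_objects = 18L))
  grid_shape <- as.integer(grid_shape)
  if (is.null(signal_region))
    signal_region <- central_block(grid_shape, 4L)
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 design = design, grid_shape = grid_shape,
                 signal_region = as.integer(signal_region),
                 group_acat = group_acat, group_bitem = group_bitem,
                 memory = memory, radius_mm = radius_mm,
                 voxel_size_mm = voxel_size_mm,
                 min_voxels = as.integer(min_voxels), alpha = alpha,
                 min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity),
                 n_perm = as.integer(n_perm),
                 n_perm_plsc = as.integer(n_perm_plsc),
                 n_boot_plsc = as.integer(n_boot_plsc),
                 do_memory_split = do_memory_split,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Linear indices of a centred cubic block
#'
#' @param dim3 grid dimensions.
#' @param side block edge length in voxels.
#' @return integer vector of linear voxel indices.
#' @export
central_block <- function(dim3, side = 4L) {
  ranges <- lapply(dim3, function(d) {
    lo <- max(1L, (d - side) %/% 2L + 1L)
    lo:(min(d, lo + side - 1L))
  })
  g <- expand.grid(x = ranges[[1]], y = ranges[[2]], z = ranges[[3]])
  as.integer(g$x + (g$y - 1L) * dim3[1] + (g$z - 1L) * dim3[1] * dim3[2])
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates a cohort, computes per-subject item- and category-level
#' distinctiveness searchlight maps, tests for age differences with
#' cluster-mass permutation statistics, extracts subject- and trial-wise
#' distinctiveness from the significant age clusters (falling back to the
#' known signal region when no cluster survives), scores recognition
#' memory, runs the PLSC linking distinctiveness to memory, and the
#' two-stage trial-wise distinctiveness-memory association. The report is
#' a plain list (JSON-serialisable) whose every number reproduces from
#' the configuration and master seed alone.
#'
#' @param config a [pipeline_config()].
#' @param out optional directory; when given, the JSON report and a
#'   cluster table TSV are written there.
#' @return the report list.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sl <- searchlight_spec(config$radius_mm, config$voxel_size_mm,
                         config$min_voxels)
  gp <- list(
    young = signal_params(config$group_acat[["young"]],
                          config$group_bitem[["young"]],
                          config$grid_shape, config$signal_region,
                          config$voxel_size_mm),
    old = signal_params(config$group_acat[["old"]],
                        config$group_bitem[["old"]],
                        config$grid_shape, config$signal_region,
                        config$voxel_size_mm))
  cohort <- generate_cohort(config$n_young, config$n_old, gp,
                            config$design,
                            seed = derive_seed(config$seed, 11L),
                            memory_mod = config$memory)
  groups <- vapply(cohort, `[[`, character(1), "group")

  item_maps <- lapply(cohort, function(s)
    item_distinctiveness(s$betas, s$design, sl))
  cat_maps <- lapply(cohort, function(s)
    category_distinctiveness(s$betas, s$design, sl))

  gv_item <- group_valid_mask(item_maps)
  gv_cat <- group_valid_mask(cat_maps)
  stack <- function(maps, key, valid) {
    M <- vapply(maps, `[[`, numeric(prod(config$grid_shape)), key)
    M[!valid, ] <- NA_real_
    M
  }
  Mi <- stack(item_maps, "item_diff", gv_item)
  Mc <- stack(cat_maps, "category_diff", gv_cat)

  yi <- groups == "young"
  age_item <- cluster_permutation_test(
    Mi[, yi, drop = FALSE], Mi[, !yi, drop = FALSE], config$grid_shape,
    "independent", config$alpha, config$min_size, config$connectivity,
    config$n_perm, seed = derive_seed(config$seed, 21L))
  age_cat <- cluster_permutation_test(
    Mc[, yi, drop = FALSE], Mc[, !yi, drop = FALSE], config$grid_shape,
    "independent", config$alpha, config$min_size, config$connectivity,
    config$n_perm, seed = derive_seed(config$seed, 22L))

  sig_masks <- function(res) {
    keep <- Filter(function(cl) cl$significant, res$clusters)
    lapply(keep, `[[`, "voxels")
  }
  masks <- c(sig_masks(age_item), sig_masks(age_cat))
  levels_of_masks <- c(rep("item", length(sig_masks(age_item))),
                       rep("category", length(sig_masks(age_cat))))
  mask_source <- "age_clusters"
  if (length(masks) < 2) {
    masks <- list(config$signal_region, config$signal_region)
    levels_of_masks <- c("item", "category")
    mask_source <- "signal_region"
  }

  # subject-wise neural measures: mean distinctiveness inside each mask
  neural <- vapply(seq_along(masks), function(k) {
    M <- if (levels_of_masks[k] == "item") Mi else Mc
    colMeans(M[masks[[k]], , drop = FALSE], na.rm = TRUE)
  }, numeric(length(cohort)))
  neural <- as.matrix(neural)

  scores <- lapply(cohort, function(s) memory_scores(s$design))
  Y <- cbind(pr_item = vapply(scores, `[[`, numeric(1), "pr_item"),
             pr_pair = vapply(scores, `[[`, numeric(1), "pr_pair"))

  plsc <- tryCatch(
    plsc_analysis(neural, Y, group = groups,
                  n_perm = config$n_perm_plsc,
                  n_boot = config$n_boot_plsc,
                  seed = derive_seed(config$seed, 31L)),
    error = function(e) list(error = conditionMessage(e)))

  # trial-wise distinctiveness-memory association (two-stage), using the
  # first mask at its level
  long <- do.call(rbind, lapply(cohort, function(s) {
    tw <- trialwise_distinctiveness(
      s$betas, s$design, masks[[1]],
      level = levels_of_masks[1])
    ret <- s$design[s$design$phase == "RETRIEVAL" &
                      s$design$condition != "new", ]
    m <- match(ret$stimulus_id, tw$stimulus_id)
    data.frame(subject = s$subject_id, group = s$group,
               x = tw$value[m],
               y = as.integer(ret$item_outcome == "hit"))
  }))
  # separation warnings are routine at demonstration trial counts; slopes
  # are clipped inside twostage_association
  assoc <- tryCatch(
    suppressWarnings(twostage_association(long, family = "binomial")),
    error = function(e) list(error = conditionMessage(e)))

  report <- list(
    config = list(n_young = config$n_young, n_old = config$n_old,
                  grid_shape = config$grid_shape,
                  n_perm = config$n_perm, alpha = config$alpha,
                  min_size = config$min_size, seed = config$seed),
    behavior = list(
      mean_pr_item_young = mean(Y[yi, "pr_item"]),
      mean_pr_item_old = mean(Y[!yi, "pr_item"]),
      mean_pr_pair_young = mean(Y[yi, "pr_pair"]),
      mean_pr_pair_old = mean(Y[!yi, "pr_pair"]),
      chance = scores[[1]]$chance),
    age_clusters = list(
      item = cluster_table(age_item, config$grid_shape),
      category = cluster_table(age_cat, config$grid_shape),
      n_significant_item = age_item$n_significant,
      n_significant_category = age_cat$n_significant,
      mask_source = mask_source),
    plsc = if (!is.null(plsc$error)) plsc else list(
      p_perm = plsc$p_perm,
      singular_values = plsc$singular_values,
      bsr = plsc$bsr,
      group_latent_correlations =
        as.list(plsc$group_latent_correlations)),
    trialwise_association = if (!is.null(assoc$error)) assoc else list(
      mean_slope = assoc$mean_slope, t_main = assoc$t_main,
      p_main = assoc$p_main, t_group = assoc$t_group,
      p_group = assoc$p_group),
    seeds = list(master = config$seed,
                 cohort = derive_seed(config$seed, 11L),
                 perm_item = derive_seed(config$seed, 21L),
                 perm_category = derive_seed(config$seed, 22L),
                 plsc = derive_seed(config$seed, 31L)))

  if (config$do_memory_split) {
    split_diffs <- lapply(cohort, function(s) {
      tryCatch(subsequent_memory_maps(s$betas, s$design, sl,
                                      level = "category")$difference,
               error = function(e) NULL)
    })
    keep <- !vapply(split_diffs, is.null, logical(1))
    if (sum(keep) >= 4) {
      Md <- do.call(cbind, split_diffs[keep])
      smem <- cluster_permutation_test(
        Md, NULL, config$grid_shape, "dependent", config$alpha,
        config$min_size, config$connectivity, config$n_perm,
        seed = derive_seed(config$seed, 41L))
      report$subsequent_memory <- list(
        n_subjects = sum(keep),
        n_significant = smem$n_significant,
        clusters = cluster_table(smem, config$grid_shape))
    } else {
      report$subsequent_memory <- list(n_subjects = sum(keep),
                                       skipped = TRUE)
    }
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    write_trial_table(report$age_clusters$item,
                      file.path(out, "age_clusters_item.tsv"))
    write_trial_table(report$age_clusters$category,
                      file.path(out, "age_clusters_category.tsv"))
  }
  report
}

#' Family-wise error calibration of the cluster permutation test
#'
#' Generates replicate null cohorts (per-subject voxel maps of
#' independent unit-variance Gaussian noise, no group difference), runs
#' the full cluster-mass permutation test on each and reports the
#' fraction of replicates yielding at least one significant cluster — the
#' empirical family-wise error rate, to be compared with the nominal
#' level.
#'
#' @param n_cohorts number of replicate null cohorts.
#' @param n_per_group subjects per group.
#' @param dim3 grid dimensions.
#' @param design `"independent"` (group label shuffle) or `"dependent"`
#'   (sign flip of difference maps).
#' @param alpha cluster-forming threshold.
#' @param min_size minimum cluster extent.
#' @param connectivity adjacency.
#' @param n_perm permutations per cohort.
#' @param seed master seed.
#' @return list with `fwe_rate`, `n_false_positive`, `n_cohorts` and the
#'   binomial 95% bounds around 0.05 for this `n_cohorts`.
#' @export
null_cluster_calibration <- function(n_cohorts = 200L, n_per_group = 10L,
                                     dim3 = c(12L, 12L, 12L),
                                     design = c("independent",
                                                "dependent"),
                                     alpha = 0.005, min_size = 10L,
                                     connectivity = 26L, n_perm = 500L,
                                     seed = 1L) {
  design <- match.arg(design)
  V <- prod(dim3)
  hits <- logical(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    set.seed(derive_seed(seed, 2L * k))
    if (design == "independent") {
      A <- matrix(stats::rnorm(V * n_per_group), V)
      B <- matrix(stats::rnorm(V * n_per_group), V)
      res <- cluster_permutation_test(A, B, dim3, "independent", alpha,
                                      min_size, connectivity, n_perm,
                                      seed = derive_seed(seed, 2L * k + 1L))
    } else {
      D <- matrix(stats::rnorm(V * n_per_group), V)
      res <- cluster_permutation_test(D, NULL, dim3, "dependent", alpha,
                                      min_size, connectivity, n_perm,
                                      seed = derive_seed(seed, 2L * k + 1L))
    }
    hits[k] <- res$n_significant > 0
  }
  bounds <- stats::qbinom(c(0.025, 0.975), n_cohorts, 0.05) / n_cohorts
  list(fwe_rate = mean(hits), n_false_positive = sum(hits),
       n_cohorts = n_cohorts, binom95 = bounds)
}
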