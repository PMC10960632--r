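#' Study design specification
#'
#' Describes the trial structure of a two-session encoding experiment with a
#' subsequent recognition test: a first target-detection phase (TD1) with
#' object runs followed by one scene run, a second target-detection phase
#' (TD2) re-presenting all objects, and a retrieval phase in which old
#' (paired) objects are intermixed with new objects and old/new item and
#' pair judgments are collected. Defaults reproduce the full study design
#' (320 objects of which 20 are task targets, 250 paired with scenes and 50
#' baseline; 60 scenes of which 10 targets; 3+1 runs in TD1 and 3 object
#' runs in TD2).
#'
#' @param n_objects total number of object stimuli in TD1/TD2.
#' @param n_object_targets objects used as target-detection targets,
#'   excluded from all similarity analyses.
#' @param n_paired objects paired with scenes and tested at retrieval.
#' @param n_baseline objects shown in TD1/TD2 only.
#' @param n_scenes total scene stimuli (TD1 only).
#' @param n_scene_targets scene targets.
#' @param n_object_runs_phase1,n_scene_runs_phase1,n_object_runs_phase2
#'   run counts per phase.
#' @param retrieval_counts named list with elements `old_match`,
#'   `old_mismatch`, `old_new_scene`, `new_objects`; the three `old_*`
#'   counts must sum to `n_paired`.
#' @param seed integer seed controlling the pseudorandom assignment of
#'   stimuli to runs, targets, pairings and retrieval conditions.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_objects = 320L,
                        n_object_targets = 20L,
                        n_paired = 250L,
                        n_baseline = 50L,
                        n_scenes = 60L,
                        n_scene_targets = 10L,
                        n_object_runs_phase1 = 3L,
                        n_scene_runs_phase1 = 1L,
                        n_object_runs_phase2 = 3L,
                        retrieval_counts = list(old_match = 100L,
                                                old_mismatch = 100L,
                                                old_new_scene = 50L,
                                                new_objects = 150L),
                        seed = 1L) {
  spec <- list(n_objects = as.integer(n_objects),
               n_object_targets = as.integer(n_object_targets),
               n_paired = as.integer(n_paired),
               n_baseline = as.integer(n_baseline),
               n_scenes = as.integer(n_scenes),
               n_scene_targets = as.integer(n_scene_targets),
               n_object_runs_phase1 = as.integer(n_object_runs_phase1),
               n_scene_runs_phase1 = as.integer(n_scene_runs_phase1),
               n_object_runs_phase2 = as.integer(n_object_runs_phase2),
               retrieval_counts = lapply(retrieval_counts, as.integer),
               seed = as.integer(seed))
  class(spec) <- "design_spec"
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  with(spec, {
    if (n_object_targets + n_paired + n_baseline != n_objects)
      stop("design_spec: n_object_targets + n_paired + n_baseline must equal ",
           "n_objects (", n_object_targets, " + ", n_paired, " + ", n_baseline,
           " != ", n_objects, ")", call. = FALSE)
    old_sum <- retrieval_counts$old_match + retrieval_counts$old_mismatch +
      retrieval_counts$old_new_scene
    if (old_sum != n_paired)
      stop("design_spec: retrieval old_match + old_mismatch + old_new_scene ",
           "must equal n_paired (", old_sum, " != ", n_paired, ")",
           call. = FALSE)
    if (n_scene_targets > n_scenes)
      stop("design_spec: n_scene_targets must not exceed n_scenes",
           call. = FALSE)
  })
  invisible(spec)
}

# Near-equal partition of n into k parts, remainder assigned to later parts
# (320 objects over 3 runs -> 106, 107, 107).
partition_sizes <- function(n, k) {
  base <- n %/% k
  r <- n %% k
  sizes <- rep(base, k)
  if (r > 0) sizes[(k - r + 1):k] <- base + 1L
  as.integer(sizes)
}

#' Generate a trial table from a design specification
#'
#' Assigns stimuli to runs, target-detection targets, object-scene pairings
#' and retrieval conditions by uniform pseudorandom shuffling under the
#' spec's seed. Run labels are globally unique integers: TD1 occupies runs
#' 1..(object runs + scene runs), TD2 the following runs, retrieval the
#' last run.
#'
#' @param spec a [design_spec()].
#' @return a `data.frame` (trial table) with one row per trial and columns
#'   `trial_id`, `phase` (`TD1`/`TD2`/`RETRIEVAL`), `run`, `stimulus_id`,
#'   `category` (`object`/`scene`), `is_target`, `paired_scene_id`,
#'   `condition` (retrieval: `old_match`/`old_mismatch`/`old_new_scene`/
#'   `new`), `item_outcome`, `pair_outcome` (both `"none"` until memory
#'   outcomes are generated).
#' @seealso [generate_memory()] to fill in memory outcomes.
#' @export
generate_design <- function(spec) {
  validate_design_spec(spec)
  set.seed(spec$seed)

  obj_ids <- seq_len(spec$n_objects)
  scene_ids <- spec$n_objects + seq_len(spec$n_scenes)

  target_obj <- sort(sample(obj_ids, spec$n_object_targets))
  nontarget <- setdiff(obj_ids, target_obj)
  paired_obj <- sort(sample(nontarget, spec$n_paired))
  target_scene <- sort(sample(scene_ids, spec$n_scene_targets))
  old_scenes <- setdiff(scene_ids, target_scene)

  # round-robin object->scene pairing, then shuffled (250 objects over 50
  # scenes gives exactly 5 objects per scene)
  scene_assign <- sample(rep_len(old_scenes, spec$n_paired))
  pairing <- stats::setNames(scene_assign, paired_obj)

  run_counter <- 0L
  rows <- list()
  add_rows <- function(stim, phase, run, category, condition = "none") {
    data.frame(phase = phase, run = run, stimulus_id = stim,
               category = category, condition = condition,
               stringsAsFactors = FALSE)
  }

  # TD1 object runs
  perm <- sample(obj_ids)
  sizes <- partition_sizes(spec$n_objects, spec$n_object_runs_phase1)
  splits <- split(perm, rep(seq_along(sizes), sizes))
  for (k in seq_along(splits)) {
    run_counter <- run_counter + 1L
    rows[[length(rows) + 1L]] <- add_rows(splits[[k]], "TD1", run_counter,
                                          "object")
  }
  # TD1 scene run(s)
  perm_s <- sample(scene_ids)
  sizes_s <- partition_sizes(spec$n_scenes, spec$n_scene_runs_phase1)
  splits_s <- split(perm_s, rep(seq_along(sizes_s), sizes_s))
  for (k in seq_along(splits_s)) {
    run_counter <- run_counter + 1L
    rows[[length(rows) + 1L]] <- add_rows(splits_s[[k]], "TD1", run_counter,
                                          "scene")
  }
  # TD2 object runs (same objects, fresh shuffle)
  perm2 <- sample(obj_ids)
  sizes2 <- partition_sizes(spec$n_objects, spec$n_object_runs_phase2)
  splits2 <- split(perm2, rep(seq_along(sizes2), sizes2))
  for (k in seq_along(splits2)) {
    run_counter <- run_counter + 1L
    rows[[length(rows) + 1L]] <- add_rows(splits2[[k]], "TD2", run_counter,
                                          "object")
  }
  # Retrieval: paired objects under three old conditions plus new objects
  rc <- spec$retrieval_counts
  cond_pool <- sample(rep(c("old_match", "old_mismatch", "old_new_scene"),
                          times = c(rc$old_match, rc$old_mismatch,
                                    rc$old_new_scene)))
  new_ids <- max(scene_ids) + seq_len(rc$new_objects)
  run_counter <- run_counter + 1L
  ret <- data.frame(phase = "RETRIEVAL", run = run_counter,
                    stimulus_id = c(sample(paired_obj), new_ids),
                    category = "object",
                    condition = c(cond_pool[seq_len(spec$n_paired)],
                                  rep("new", rc$new_objects)),
                    stringsAsFactors = FALSE)
  ret <- ret[sample(nrow(ret)), ]
  rows[[length(rows) + 1L]] <- ret

  design <- do.call(rbind, rows)
  design$is_target <- design$stimulus_id %in% c(target_obj, target_scene)
  design$paired_scene_id <- unname(pairing[as.character(design$stimulus_id)])
  design$item_outcome <- "none"
  design$pair_outcome <- "none"
  design$trial_id <- seq_len(nrow(design))
  rownames(design) <- NULL
  design[, c("trial_id", "phase", "run", "stimulus_id", "category",
             "is_target", "paired_scene_id", "condition", "item_outcome",
             "pair_outcome")]
}

#' Voxel signal model parameters
#'
#' Parameters of the separable signal model used by [generate_betas()].
#' Within the signal region, the per-trial activation of a voxel is
#' \deqn{\beta = \sqrt{a_{cat}}\,C_v(c) + \sqrt{b_{item}}\,I_v(i) +
#'   \sqrt{1 - a_{cat} - b_{item}}\,\varepsilon}
#' with independent unit-variance Gaussian category, item and noise
#' components, so that the expected Pearson correlation between two trials
#' sharing only a category is `a_cat` and between two presentations of the
#' same item is `a_cat + b_item`.
#'
#' @param a_cat category-shared variance fraction in `[0, 1]`.
#' @param b_item item-specific variance fraction; `a_cat + b_item <= 1`.
#' @param grid_shape integer 3-vector of volume dimensions.
#' @param signal_region linear voxel indices carrying signal; all other
#'   voxels are pure unit-variance noise. Default: all voxels.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param rho_stability representational stability of item patterns across
#'   phases in `[0, 1]`: TD2 item components are
#'   `rho * I + sqrt(1 - rho^2) * I_new`. Default 1 (perfectly stable).
#' @return an object of class `signal_params`.
#' @export
signal_params <- function(a_cat, b_item, grid_shape,
                          signal_region = seq_len(prod(grid_shape)),
                          voxel_size_mm = 2, rho_stability = 1) {
  if (a_cat < 0 || b_item < 0 || a_cat + b_item > 1)
    stop("signal_params: need a_cat >= 0, b_item >= 0 and a_cat + b_item <= 1",
         call. = FALSE)
  if (rho_stability < 0 || rho_stability > 1)
    stop("signal_params: rho_stability must be in [0, 1]", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3)
  signal_region <- as.integer(signal_region)
  if (any(signal_region < 1L | signal_region > prod(grid_shape)))
    stop("signal_params: signal_region outside grid", call. = FALSE)
  structure(list(a_cat = a_cat, b_item = b_item, grid_shape = grid_shape,
                 signal_region = signal_region, voxel_size_mm = voxel_size_mm,
                 rho_stability = rho_stability),
            class = "signal_params")
}

#' Beta-series container
#'
#' A stack of per-trial activation volumes on a common grid: a voxels x
#' trials matrix plus the 3-D grid shape, an analysis mask and the voxel
#' size. The column order follows `trial_id`.
#'
#' @param data numeric matrix, `prod(dim3)` rows, one column per trial.
#' @param dim3 integer 3-vector of grid dimensions.
#' @param trial_id integer vector labelling the columns.
#' @param mask logical vector of length `prod(dim3)`; `FALSE` voxels carry
#'   no usable signal and are excluded from all similarity computations.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @return an object of class `beta_series`.
#' @export
beta_series <- function(data, dim3, trial_id,
                        mask = rep(TRUE, prod(dim3)), voxel_size_mm = 2) {
  dim3 <- as.integer(dim3)
  stopifnot(length(dim3) == 3, nrow(data) == prod(dim3),
            ncol(data) == length(trial_id), length(mask) == prod(dim3))
  structure(list(data = data, dim3 = dim3, trial_id = as.integer(trial_id),
                 mask = as.logical(mask), voxel_size_mm = voxel_size_mm),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("beta_series:", ncol(x$data), "trials on a",
      paste(x$dim3, collapse = "x"), "grid,",
      sum(x$mask), "in-mask voxels\n")
  invisible(x)
}

#' Generate trial-wise beta images with known signal structure
#'
#' Draws per-trial activation volumes for all scanned trials (phases TD1
#' and TD2) of a trial table under the separable signal model of
#' [signal_params()]. Category patterns (one per category) and item
#' patterns (one per stimulus) are sampled once and reused across phases,
#' making the expected within-item cross-phase correlation
#' `a_cat + b_item` and the expected same-category correlation `a_cat`
#' inside the signal region; voxels outside the region are independent
#' unit-variance noise.
#'
#' @param design trial table from [generate_design()].
#' @param params a [signal_params()].
#' @param seed integer seed; the draw is deterministic given it.
#' @return a [beta_series()] over the scanned (TD1/TD2) trials.
#' @export
generate_betas <- function(design, params, seed = 1L) {
  stopifnot(inherits(params, "signal_params"))
  set.seed(seed)
  scanned <- design[design$phase %in% c("TD1", "TD2"), ]
  scanned <- scanned[order(scanned$trial_id), ]
  n_trial <- nrow(scanned)
  V <- prod(params$grid_shape)
  reg <- params$signal_region
  nR <- length(reg)

  stim <- sort(unique(scanned$stimulus_id))
  cat_of <- vapply(stim, function(s)
    scanned$category[match(s, scanned$stimulus_id)], character(1))
  C <- matrix(stats::rnorm(nR * 2), nR, 2,
              dimnames = list(NULL, c("object", "scene")))
  I <- matrix(stats::rnorm(nR * length(stim)), nR, length(stim))
  colnames(I) <- as.character(stim)
  rho <- params$rho_stability
  I2 <- if (rho < 1) {
    rho * I + sqrt(1 - rho^2) *
      matrix(stats::rnorm(nR * length(stim)), nR, length(stim))
  } else I

  a <- params$a_cat; b <- params$b_item
  data <- matrix(stats::rnorm(V * n_trial), V, n_trial)
  if (a + b > 0) {
    for (k in seq_len(n_trial)) {
      s <- as.character(scanned$stimulus_id[k])
      Ik <- if (scanned$phase[k] == "TD2") I2[, s] else I[, s]
      data[reg, k] <- sqrt(a) * C[, scanned$category[k]] +
        sqrt(b) * Ik + sqrt(1 - a - b) * data[reg, k]
    }
  }
  beta_series(data, params$grid_shape, scanned$trial_id,
              voxel_size_mm = params$voxel_size_mm)
}

#' Memory generating model
#'
#' Logistic model linking trial-wise neural distinctiveness to recognition
#' outcomes: an old item is recognised (hit) with probability
#' `plogis(beta0 + beta1_item * d_item + beta1_cat * d_cat)`; pair
#' judgments for old items use `plogis(beta0_pair + beta1_cat * d_cat)`;
#' new objects are correctly rejected with fixed probability `specificity`.
#'
#' @param beta0 log-odds intercept for item hits.
#' @param beta1_item,beta1_cat slopes on item-/category-level trial-wise
#'   distinctiveness.
#' @param beta0_pair log-odds intercept for correct pair judgments.
#' @param specificity correct-rejection probability for new objects.
#' @param seed integer seed.
#' @return an object of class `memory_model`.
#' @export
memory_model <- function(beta0 = 0, beta1_item = 0, beta1_cat = 0,
                         beta0_pair = beta0, specificity = 0.85, seed = 1L) {
  structure(list(beta0 = beta0, beta1_item = beta1_item,
                 beta1_cat = beta1_cat, beta0_pair = beta0_pair,
                 specificity = specificity, seed = as.integer(seed)),
            class = "memory_model")
}

#' Generate memory outcomes from trial-wise distinctiveness
#'
#' Fills the `item_outcome` and `pair_outcome` columns of a trial table by
#' drawing Bernoulli recognition outcomes under a [memory_model()]. Old
#' retrieval trials become `hit`/`miss` (items) and `correct`/`incorrect`
#' (pairs); new-object trials become `corr_rej`/`false_alarm`. Item
#' outcomes are propagated to the TD1/TD2 rows of the same stimulus so
#' encoding trials can be split by subsequent memory.
#'
#' @param design trial table.
#' @param distinct data.frame with columns `stimulus_id`, `d_item`,
#'   `d_cat`: one row per non-target paired object. Missing values for any
#'   old retrieval stimulus raise an alignment error.
#' @param model a [memory_model()].
#' @return the trial table with outcomes filled in.
#' @export
generate_memory <- function(design, distinct, model) {
  stopifnot(inherits(model, "memory_model"))
  set.seed(model$seed)
  out <- design
  ret <- out$phase == "RETRIEVAL"
  old <- ret & out$condition != "new"
  idx <- match(out$stimulus_id[old], distinct$stimulus_id)
  if (anyNA(idx))
    stop("generate_memory: missing distinctiveness values for ",
         sum(is.na(idx)), " old retrieval stimuli", call. = FALSE)
  d_item <- distinct$d_item[idx]
  d_cat <- distinct$d_cat[idx]
  if (anyNA(d_item) || anyNA(d_cat))
    stop("generate_memory: NA distinctiveness values supplied", call. = FALSE)
  p_hit <- stats::plogis(model$beta0 + model$beta1_item * d_item +
                           model$beta1_cat * d_cat)
  out$item_outcome[old] <- ifelse(stats::runif(sum(old)) < p_hit,
                                  "hit", "miss")
  p_pair <- stats::plogis(model$beta0_pair + model$beta1_cat * d_cat)
  out$pair_outcome[old] <- ifelse(stats::runif(sum(old)) < p_pair,
                                  "correct", "incorrect")
  new <- ret & out$condition == "new"
  out$item_outcome[new] <- ifelse(stats::runif(sum(new)) < model$specificity,
                                  "corr_rej", "false_alarm")
  # propagate item outcome to encoding trials of the same stimulus
  enc <- out$phase %in% c("TD1", "TD2") & !out$is_target
  m <- match(out$stimulus_id[enc], out$stimulus_id[old])
  oc <- out$item_outcome[old][m]
  oc[is.na(oc)] <- "none"
  out$item_outcome[enc] <- oc
  pc <- out$pair_outcome[old][m]
  pc[is.na(pc)] <- "none"
  out$pair_outcome[enc] <- pc
  out
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(k)) %%
               2147483647)
}

#' Generate a synthetic cohort of subjects
#'
#' Draws independent subjects in two age groups, each with its own design
#' realisation and beta series under group-specific signal parameters.
#' Subject seeds are derived deterministically from the master seed, so the
#' same seed reproduces the cohort bit for bit. If a [memory_model()] is
#' supplied, trial-wise distinctiveness is computed on the signal region
#' and memory outcomes are generated from it.
#'
#' @param n_young,n_old group sizes.
#' @param group_params named list with elements `young` and `old`, each a
#'   [signal_params()].
#' @param spec a [design_spec()]; its seed field is overridden per subject.
#' @param seed master seed.
#' @param memory_mod optional [memory_model()]; slopes apply to trial-wise
#'   distinctiveness computed over the subject's signal region.
#' @return list of subjects, each a list with `subject_id`, `group`,
#'   `design`, `betas` and (if memory was generated) `distinct`.
#' @export
generate_cohort <- function(n_young, n_old, group_params, spec,
                            seed = 1L, memory_mod = NULL) {
  stopifnot(all(c("young", "old") %in% names(group_params)))
  groups <- c(rep("young", n_young), rep("old", n_old))
  lapply(seq_along(groups), function(i) {
    g <- groups[i]
    sp <- spec
    sp$seed <- derive_seed(seed, 3L * i)
    design <- generate_design(sp)
    params <- group_params[[g]]
    betas <- generate_betas(design, params, seed = derive_seed(seed, 3L * i + 1L))
    subj <- list(subject_id = i, group = g, design = design, betas = betas)
    if (!is.null(memory_mod)) {
      mask <- logical(prod(params$grid_shape))
      mask[params$signal_region] <- TRUE
      di <- trialwise_distinctiveness(betas, design, mask, level = "item")
      dc <- trialwise_distinctiveness(betas, design, mask, level = "category")
      distinct <- data.frame(stimulus_id = di$stimulus_id,
                             d_item = di$value,
                             d_cat = dc$value[match(di$stimulus_id,
                                                    dc$stimulus_id)])
      paired <- unique(design$stimulus_id[design$phase == "RETRIEVAL" &
                                            design$condition != "new"])
      distinct <- distinct[distinct$stimulus_id %in% paired, ]
      mm <- memory_mod
      mm$seed <- derive_seed(seed, 3L * i + 2L)
      subj$design <- generate_memory(design, distinct, mm)
      subj$distinct <- distinct
    }
    subj
  })
}
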