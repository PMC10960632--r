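#' Canonical haemodynamic response parameters
#'
#' The classic double-gamma canonical HRF: a positive gamma peaking around
#' 5 s minus a scaled undershoot gamma, sampled on `[0, duration]` and
#' normalised to unit sum.
#'
#' @param peak_delay,undershoot_delay delays (s) of the response and
#'   undershoot gammas.
#' @param dispersion,u_dispersion dispersions (s) of the two gammas.
#' @param ratio response-to-undershoot amplitude ratio.
#' @param duration kernel support (s).
#' @return an object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     dispersion = 1, u_dispersion = 1, ratio = 1 / 6,
                     duration = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, dispersion > 0,
            u_dispersion > 0, ratio >= 0, duration > 0)
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 dispersion = dispersion, u_dispersion = u_dispersion,
                 ratio = ratio, duration = duration),
            class = "hrf_spec")
}

#' Sample the canonical HRF
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling interval (s), must be positive.
#' @return numeric kernel sampled at `seq(0, duration, by = dt)`, scaled
#'   to unit sum.
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt = 0.1) {
  stopifnot(dt > 0)
  t <- seq(0, spec$duration, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$dispersion,
                     scale = spec$dispersion) -
    spec$ratio * stats::dgamma(t, shape = spec$undershoot_delay /
                                 spec$u_dispersion,
                               scale = spec$u_dispersion)
  h / sum(h)
}

#' A single BOLD run
#'
#' @param data numeric matrix, voxels x volumes (or a 4-D array which is
#'   reshaped).
#' @param dim3 grid dimensions (derived from a 4-D `data` automatically).
#' @param tr repetition time in seconds (default 2.307).
#' @param onsets stimulus onsets in seconds, strictly increasing.
#' @param trial_id trial identifiers matching `onsets`.
#' @param nuisance optional volumes x 6 matrix of motion series.
#' @param n_dummy number of initial dummy volumes modelled by an indicator
#'   regressor.
#' @return an object of class `run_bold`.
#' @export
run_bold <- function(data, dim3 = NULL, tr = 2.307, onsets, trial_id,
                     nuisance = NULL, n_dummy = 3L) {
  if (length(dim(data)) == 4) {
    dim3 <- dim(data)[1:3]
    data <- matrix(data, prod(dim3), dim(data)[4])
  }
  stopifnot(!is.null(dim3), length(onsets) == length(trial_id))
  if (is.unsorted(onsets, strictly = TRUE))
    stop("run_bold: onsets must be strictly increasing", call. = FALSE)
  if (!is.null(nuisance) && nrow(nuisance) != ncol(data))
    stop("run_bold: nuisance length must equal number of volumes",
         call. = FALSE)
  structure(list(data = data, dim3 = as.integer(dim3), tr = tr,
                 onsets = onsets, trial_id = as.integer(trial_id),
                 nuisance = nuisance, n_dummy = as.integer(n_dummy)),
            class = "run_bold")
}

# Convolve impulse sticks at the given onsets with the HRF kernel and
# sample at volume acquisition times.
convolved_regressor <- function(onsets, n_vol, tr, kernel, dt) {
  t_max <- (n_vol - 1) * tr
  n_hi <- floor(t_max / dt) + 1L
  stick <- numeric(n_hi + length(kernel))
  pos <- round(onsets / dt) + 1L
  pos <- pos[pos >= 1 & pos <= n_hi]
  for (p in pos) stick[p] <- stick[p] + 1
  # full causal convolution: conv[i] = sum_j stick[j] * kernel[i - j + 1]
  conv <- stats::convolve(stick, rev(kernel), type = "open")
  vol_idx <- round((0:(n_vol - 1)) * tr / dt) + 1L
  as.numeric(conv[vol_idx])
}

#' Least-squares-single design matrix for one trial
#'
#' Builds the LSS design: one regressor for the target trial and one for
#' all other trials in the same run (both impulse sticks at stimulus onset
#' convolved with the canonical HRF), six motion regressors if supplied,
#' one indicator of the initial dummy volumes, and an intercept.
#'
#' @param run a [run_bold()].
#' @param target_trial trial id of the target trial (must be in the run).
#' @param hrf an [hrf_spec()].
#' @param dt microtime resolution (s) for the convolution.
#' @return design matrix (volumes x regressors) with named columns; the
#'   attribute `single_trial_run` is TRUE when the run holds only the
#'   target trial (all-zero "others" column).
#' @export
build_lss_design <- function(run, target_trial, hrf = hrf_spec(),
                             dt = 0.1) {
  k <- match(target_trial, run$trial_id)
  if (is.na(k))
    stop("build_lss_design: target trial not in run", call. = FALSE)
  n_vol <- ncol(run$data)
  kernel <- canonical_hrf(hrf, dt)
  target <- convolved_regressor(run$onsets[k], n_vol, run$tr, kernel, dt)
  others <- convolved_regressor(run$onsets[-k], n_vol, run$tr, kernel, dt)
  X <- cbind(target = target, others = others)
  if (!is.null(run$nuisance)) {
    nn <- as.matrix(run$nuisance)
    colnames(nn) <- paste0("motion", seq_len(ncol(nn)))
    X <- cbind(X, nn)
  }
  if (run$n_dummy > 0) {
    X <- cbind(X, dummy = as.numeric(seq_len(n_vol) <= run$n_dummy))
  }
  X <- cbind(X, intercept = 1)
  attr(X, "single_trial_run") <- length(run$onsets) == 1L
  X
}

#' Fit trial-wise betas by least-squares-single GLM
#'
#' For every trial of every run, fits the LSS design by ordinary least
#' squares and keeps the target regressor's coefficient as that trial's
#' beta image. An implicit mask retains voxels whose mean signal exceeds
#' `mask_threshold` times the grand mean of the voxel means (computed over
#' the initial mask, i.e. all voxels unless `mask` is given); out-of-mask
#' voxels are NA. Rank-deficient designs are solved by pseudo-inverse
#' with a warning.
#'
#' @param runs list of [run_bold()] objects sharing a grid.
#' @param mask_threshold implicit masking fraction of the grand mean
#'   (default 0.4).
#' @param mask optional logical initial mask over the grid.
#' @param hrf an [hrf_spec()].
#' @param dt microtime resolution for the convolution.
#' @return a [beta_series()] (columns ordered by trial id) with the
#'   implicit mask applied; the attribute `mask_info` records the
#'   threshold and retained voxel count.
#' @export
fit_trial_betas <- function(runs, mask_threshold = 0.4, mask = NULL,
                            hrf = hrf_spec(), dt = 0.1) {
  stopifnot(length(runs) >= 1)
  dim3 <- runs[[1]]$dim3
  for (r in runs) if (!identical(r$dim3, dim3))
    stop("fit_trial_betas: runs must share a grid", call. = FALSE)
  V <- prod(dim3)
  if (is.null(mask)) mask <- rep(TRUE, V)

  vox_mean <- rowMeans(do.call(cbind, lapply(runs, `[[`, "data")))
  grand <- mean(vox_mean[mask])
  impl <- if (grand > 0) mask & (vox_mean > mask_threshold * grand) else mask

  beta_list <- list()
  id_list <- list()
  warned <- FALSE
  for (run in runs) {
    Yt <- t(run$data[impl, , drop = FALSE])
    for (k in seq_along(run$trial_id)) {
      X <- build_lss_design(run, run$trial_id[k], hrf, dt)
      qrX <- qr(X)
      if (qrX$rank < ncol(X)) {
        if (!warned) {
          warning("fit_trial_betas: rank-deficient design, using ",
                  "pseudo-inverse", call. = FALSE)
          warned <- TRUE
        }
        coefs <- MASS::ginv(X) %*% Yt
        b <- coefs[1, ]
      } else {
        b <- qr.coef(qrX, Yt)[1, ]
      }
      full <- rep(NA_real_, V)
      full[impl] <- b
      beta_list[[length(beta_list) + 1L]] <- full
      id_list[[length(id_list) + 1L]] <- run$trial_id[k]
    }
  }
  ids <- unlist(id_list)
  ord <- order(ids)
  bs <- beta_series(do.call(cbind, beta_list)[, ord, drop = FALSE],
                    dim3, ids[ord], mask = impl)
  attr(bs, "mask_info") <- list(threshold = mask_threshold,
                                grand_mean = grand,
                                n_retained = sum(impl))
  bs
}

#' Simulate BOLD runs from known trial betas
#'
#' Forward model matching [fit_trial_betas()]: each trial contributes its
#' beta image times the HRF-convolved stick regressor; optional Gaussian
#' noise is added. Useful for self-inversion checks of the LSS estimator.
#'
#' @param betas voxels x trials matrix of true amplitudes.
#' @param onsets per-trial onsets (s).
#' @param trial_id trial ids.
#' @param dim3 grid dimensions.
#' @param n_vol number of volumes.
#' @param tr repetition time (s).
#' @param noise_sd Gaussian noise standard deviation.
#' @param hrf an [hrf_spec()].
#' @param dt microtime resolution.
#' @param baseline constant added to every voxel (keeps the implicit mask
#'   trivially satisfied).
#' @param seed integer seed for the noise.
#' @return a [run_bold()].
#' @export
simulate_bold_run <- function(betas, onsets, trial_id, dim3, n_vol,
                              tr = 2.307, noise_sd = 0, hrf = hrf_spec(),
                              dt = 0.1, baseline = 100, seed = 1L) {
  kernel <- canonical_hrf(hrf, dt)
  Y <- matrix(baseline, nrow(betas), n_vol)
  for (k in seq_along(onsets)) {
    reg <- convolved_regressor(onsets[k], n_vol, tr, kernel, dt)
    Y <- Y + outer(betas[, k], reg)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y))
  }
  run_bold(Y, dim3 = dim3, tr = tr, onsets = onsets, trial_id = trial_id)
}
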