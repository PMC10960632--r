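#' Partial least squares correlation
#'
#' Relates a subjects x behaviours block to a subjects x neural-measures
#' block. Both blocks are column z-scored (optionally within age group),
#' the between-person Pearson correlation matrix `R = cor(X, Y)` is formed
#' and decomposed by SVD, `R = U S V'`. The neural saliences are the
#' columns of `U`, the behaviour saliences the columns of `V`; latent
#' scores are the standardized data projected on the saliences. The sign
#' of each latent variable is fixed by forcing the first behaviour
#' salience non-negative (a joint flip of the paired saliences).
#'
#' @param X numeric matrix, subjects x neural measures (e.g. mean
#'   distinctiveness per cluster).
#' @param Y numeric matrix, subjects x behaviours (e.g. item and pair Pr).
#' @param group optional factor of age-group labels; required for
#'   `standardize_within_group` and for per-group latent correlations.
#' @param standardize_within_group z-score each column within each group
#'   instead of across the sample.
#' @return a `plsc_result` list: `singular_values`, `neural_saliences`,
#'   `behavior_saliences`, `Lx`, `Ly`, `R`,
#'   `group_latent_correlations` (per-group Pearson r of the first latent
#'   score pair, if `group` given).
#' @export
plsc_fit <- function(X, Y, group = NULL, standardize_within_group = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("plsc_fit: X and Y row mismatch", call. = FALSE)
  if (n < 4) stop("plsc_fit: need at least 4 subjects", call. = FALSE)
  if (anyNA(X) || anyNA(Y)) stop("plsc_fit: missing values", call. = FALSE)
  check_const <- function(M, nm) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
      stop("plsc_fit: constant column in ", nm, ": ",
           paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  check_const(X, "X"); check_const(Y, "Y")

  zscore <- function(M) scale(M)[, , drop = FALSE]
  if (standardize_within_group) {
    if (is.null(group))
      stop("plsc_fit: group needed for within-group standardization",
           call. = FALSE)
    Xz <- X; Yz <- Y
    for (g in unique(group)) {
      i <- group == g
      Xz[i, ] <- zscore(X[i, , drop = FALSE])
      Yz[i, ] <- zscore(Y[i, , drop = FALSE])
    }
  } else {
    Xz <- zscore(X); Yz <- zscore(Y)
  }

  R <- stats::cor(Xz, Yz)
  sv <- svd(R)
  U <- sv$u; V <- sv$v; S <- sv$d
  for (k in seq_along(S)) {
    if (V[1, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  Lx <- Xz %*% U
  Ly <- Yz %*% V
  res <- list(singular_values = S, neural_saliences = U,
              behavior_saliences = V, Lx = Lx, Ly = Ly, R = R,
              group = group)
  if (!is.null(group)) {
    res$group_latent_correlations <- vapply(
      unique(group), function(g) {
        lx <- Lx[group == g, 1]; ly <- Ly[group == g, 1]
        if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
        stats::cor(lx, ly)
      }, numeric(1))
    names(res$group_latent_correlations) <- as.character(unique(group))
  }
  class(res) <- "plsc_result"
  res
}

#' Permutation test of the first latent variable
#'
#' The rows of `Y` are shuffled relative to `X` in each permutation and
#' the PLSC refit; `p = (1 + #{S1_perm >= S1_obs}) / (n_perm + 1)`.
#'
#' @inheritParams plsc_fit
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `p_perm`, `s1_obs` and the permutation distribution
#'   `s1_null`.
#' @export
plsc_permutation_test <- function(X, Y, group = NULL,
                                  standardize_within_group = FALSE,
                                  n_perm = 10000L, seed = 1L) {
  if (n_perm < 1) stop("plsc_permutation_test: n_perm must be >= 1",
                       call. = FALSE)
  fit <- plsc_fit(X, Y, group, standardize_within_group)
  s1 <- fit$singular_values[1]
  n <- nrow(as.matrix(X))
  set.seed(seed)
  s1_null <- vapply(seq_len(n_perm), function(k) {
    Yp <- as.matrix(Y)[sample.int(n), , drop = FALSE]
    f <- try(plsc_fit(X, Yp, group, standardize_within_group),
             silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    f$singular_values[1]
  }, numeric(1))
  s1_null <- s1_null[!is.na(s1_null)]
  list(p_perm = (1 + sum(s1_null >= s1)) / (length(s1_null) + 1),
       s1_obs = s1, s1_null = s1_null)
}

#' Bootstrap ratios of the neural saliences
#'
#' Subjects are resampled with replacement; for each resample the PLSC is
#' refit and the first neural salience is sign-aligned to the original
#' solution by the sign of their dot product. The bootstrap ratio of each
#' neural measure is the original salience divided by the bootstrap
#' standard error (floored at 1e-12); |BSR| > 1.96 is taken as reliably
#' robust. Degenerate resamples (constant column) are redrawn and counted.
#'
#' @inheritParams plsc_fit
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return list with `bsr` (per neural measure), `salience`, `se`,
#'   `robust` (|BSR| > 1.96), `n_redrawn`.
#' @export
plsc_bootstrap_ratios <- function(X, Y, group = NULL,
                                  standardize_within_group = FALSE,
                                  n_boot = 10000L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 4) stop("plsc_bootstrap_ratios: need at least 4 subjects",
                  call. = FALSE)
  fit <- plsc_fit(X, Y, group, standardize_within_group)
  u1 <- fit$neural_saliences[, 1]
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, length(u1))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (attempt in 1:100) {
      i <- sample.int(n, n, replace = TRUE)
      f <- try(plsc_fit(X[i, , drop = FALSE], Y[i, , drop = FALSE],
                        if (is.null(group)) NULL else group[i],
                        standardize_within_group), silent = TRUE)
      if (!inherits(f, "try-error")) break
      n_redrawn <- n_redrawn + 1L
    }
    if (inherits(f, "try-error"))
      stop("plsc_bootstrap_ratios: persistent degenerate resamples",
           call. = FALSE)
    ub <- f$neural_saliences[, 1]
    if (sum(ub * u1) < 0) ub <- -ub
    boots[b, ] <- ub
  }
  se <- pmax(apply(boots, 2, stats::sd), 1e-12)
  bsr <- u1 / se
  list(bsr = bsr, salience = u1, se = se, robust = abs(bsr) > 1.96,
       n_redrawn = n_redrawn)
}

#' Full PLSC analysis
#'
#' Fit, permutation test of the first latent variable, and bootstrap
#' ratios in one call.
#'
#' @inheritParams plsc_fit
#' @param n_perm,n_boot resampling sizes.
#' @param seed integer seed (permutation and bootstrap streams derived
#'   from it).
#' @return a `plsc_result` augmented with `p_perm` and `bsr` components.
#' @export
plsc_analysis <- function(X, Y, group = NULL,
                          standardize_within_group = FALSE,
                          n_perm = 10000L, n_boot = 10000L, seed = 1L) {
  fit <- plsc_fit(X, Y, group, standardize_within_group)
  perm <- plsc_permutation_test(X, Y, group, standardize_within_group,
                                n_perm, seed = derive_seed(seed, 1L))
  boot <- plsc_bootstrap_ratios(X, Y, group, standardize_within_group,
                                n_boot, seed = derive_seed(seed, 2L))
  fit$p_perm <- perm$p_perm
  fit$s1_null <- perm$s1_null
  fit$bsr <- boot$bsr
  fit$bsr_se <- boot$se
  fit$robust <- boot$robust
  fit
}
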