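#' Behavioural memory scores
#'
#' Item and pair recognition accuracy from the retrieval trials of a trial
#' table. Item Pr is the proportion of correct item responses pooling hits
#' (old objects judged old) and correct rejections (new objects judged
#' new) over all scored trials; pair Pr is the proportion of correct pair
#' judgments among old (paired) trials. Hit and false-alarm rates feed the
#' response-bias measure and the above-chance flag compares item Pr to the
#' design's chance level.
#'
#' @param design trial table with retrieval outcomes (see
#'   [generate_memory()]).
#' @param pair_item_correct_only score pair judgments only on trials with
#'   a correct item response (the default scores all old-pair judgments).
#' @return list with `pr_item`, `pr_pair`, `HR`, `FAR`, `bias`,
#'   `chance`, `above_chance` and the underlying counts.
#' @export
memory_scores <- function(design, pair_item_correct_only = FALSE) {
  ret <- design[design$phase == "RETRIEVAL", ]
  if (nrow(ret) == 0)
    stop("memory_scores: no retrieval trials", call. = FALSE)
  old <- ret[ret$condition != "new", ]
  new <- ret[ret$condition == "new", ]
  hits <- sum(old$item_outcome == "hit")
  misses <- sum(old$item_outcome == "miss")
  cr <- sum(new$item_outcome == "corr_rej")
  fa <- sum(new$item_outcome == "false_alarm")
  n_scored <- hits + misses + cr + fa
  if (n_scored == 0)
    stop("memory_scores: no scored retrieval outcomes", call. = FALSE)
  pr_item <- (hits + cr) / n_scored
  HR <- if (hits + misses > 0) hits / (hits + misses) else NA_real_
  FAR <- if (cr + fa > 0) fa / (cr + fa) else NA_real_

  pair_pool <- old[old$pair_outcome %in% c("correct", "incorrect"), ]
  if (pair_item_correct_only)
    pair_pool <- pair_pool[pair_pool$item_outcome == "hit", ]
  pr_pair <- if (nrow(pair_pool) > 0)
    mean(pair_pool$pair_outcome == "correct") else NA_real_

  ch <- chance_level(0.5, nrow(old), nrow(ret))
  list(pr_item = pr_item, pr_pair = pr_pair, HR = HR, FAR = FAR,
       bias = if (!is.na(HR) && !is.na(FAR)) response_bias(HR, FAR)
              else NA_real_,
       chance = ch$exact, above_chance = pr_item > ch$exact,
       counts = c(hits = hits, misses = misses, corr_rej = cr,
                  false_alarm = fa))
}

#' Chance level of item recognition
#'
#' With response probability `p_response` and `n_old` old items among
#' `n_total` scored trials, chance-level accuracy is
#' `p_response * n_old / n_total` (0.5 x 250/400 = 0.3125 for the default
#' design, conventionally printed as 0.31).
#'
#' @param p_response probability of an "old" response.
#' @param n_old number of old trials.
#' @param n_total total scored trials.
#' @return list with `exact` and `printed` (rounded to 2 decimals).
#' @export
chance_level <- function(p_response, n_old, n_total) {
  if (n_total <= 0) stop("chance_level: n_total must be positive",
                         call. = FALSE)
  if (n_old <= 0 || n_old > n_total)
    stop("chance_level: need 0 < n_old <= n_total", call. = FALSE)
  exact <- p_response * n_old / n_total
  list(exact = exact, printed = round(exact, 2))
}

#' Response bias for old/new judgments
#'
#' `FAR / (1 - (HR - FAR))`: the tendency to respond "old" corrected for
#' discrimination.
#'
#' @param HR hit rate in `[0, 1]`.
#' @param FAR false alarm rate in `[0, 1]`.
#' @return bias value.
#' @export
response_bias <- function(HR, FAR) {
  stopifnot(HR >= 0, HR <= 1, FAR >= 0, FAR <= 1)
  denom <- 1 - (HR - FAR)
  if (denom == 0) {
    # only reachable at HR = 1, FAR = 0: zero numerator, bias 0 by
    # continuity (no "old" bias with perfect discrimination)
    if (FAR == 0) return(0)
    stop("response_bias: undefined when HR - FAR = 1", call. = FALSE)
  }
  FAR / denom
}

#' Subsequent-memory distinctiveness maps
#'
#' Recomputes the searchlight distinctiveness maps separately over
#' subsequently remembered (item hits) and forgotten (item misses)
#' objects and returns their difference. The difference maps of a group of
#' subjects feed the dependent-design cluster permutation test
#' (remembered vs forgotten), and group contrasts of the difference feed
#' the independent design.
#'
#' @param betas a [beta_series()].
#' @param design trial table with item outcomes propagated to encoding
#'   trials.
#' @param spec a [searchlight_spec()].
#' @param level `"item"` or `"category"`.
#' @param min_per_subset subjects with fewer remembered or forgotten
#'   objects than this are rejected with an error (callers should catch
#'   and exclude).
#' @return list with `remembered`, `forgotten` (both
#'   `distinctiveness_maps`), `difference` (full-grid vector of the
#'   distinctiveness difference), `valid_mask`, and the subset sizes.
#' @export
subsequent_memory_maps <- function(betas, design,
                                   spec = searchlight_spec(),
                                   level = c("item", "category"),
                                   min_per_subset = 2L) {
  level <- match.arg(level)
  enc <- design[design$phase == "TD1" & design$category == "object" &
                  !design$is_target, ]
  rem <- unique(enc$stimulus_id[enc$item_outcome == "hit"])
  forg <- unique(enc$stimulus_id[enc$item_outcome == "miss"])
  if (length(rem) < min_per_subset || length(forg) < min_per_subset)
    stop("subsequent_memory_maps: fewer than ", min_per_subset,
         " remembered or forgotten objects", call. = FALSE)
  fun <- if (level == "item") item_distinctiveness else
    category_distinctiveness
  mr <- fun(betas, design, spec, stimuli = rem)
  mf <- fun(betas, design, spec, stimuli = forg)
  key <- if (level == "item") "item_diff" else "category_diff"
  diff <- mr[[key]] - mf[[key]]
  list(remembered = mr, forgotten = mf, difference = diff,
       valid_mask = mr$valid_mask & mf$valid_mask,
       n_remembered = length(rem), n_forgotten = length(forg))
}

#' Two-stage association between trial-wise measures
#'
#' Summary-statistics stand-in for a random-slopes mixed model: stage one
#' fits a per-subject slope of the outcome on the predictor (logistic
#' regression for a binary outcome, ordinary least squares otherwise);
#' stage two runs a one-sample t test on the slopes (main effect of the
#' predictor) and a two-sample t test across age groups (age x predictor
#' interaction). Logistic slopes are clipped at +/-10 to contain
#' separation, with a warning.
#'
#' @param data data.frame with columns `subject`, `group`, `x`
#'   (predictor) and `y` (outcome; binary 0/1 or numeric).
#' @param family `"binomial"` for binary outcomes, `"gaussian"` for
#'   linear.
#' @param min_trials subjects with fewer trials are dropped.
#' @return list with the per-subject `slopes` data.frame, `mean_slope`,
#'   `t_main`, `p_main` (slopes vs 0), `t_group`, `p_group` (slopes
#'   across groups; NA with fewer than two groups).
#' @export
twostage_association <- function(data, family = c("gaussian", "binomial"),
                                 min_trials = 5L) {
  family <- match.arg(family)
  stopifnot(all(c("subject", "group", "x", "y") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("x", "y")]), ]
  res <- lapply(split(data, data$subject), function(d) {
    if (nrow(d) < min_trials) return(NULL)
    if (stats::sd(d$x) == 0) return(NULL)
    slope <- if (family == "binomial") {
      fit <- suppressWarnings(
        stats::glm(y ~ x, data = d, family = stats::binomial()))
      s <- stats::coef(fit)[["x"]]
      if (!is.finite(s) || abs(s) > 10) {
        warning("twostage_association: separation in subject ",
                d$subject[1], ", slope clipped at +/-10", call. = FALSE)
        s <- sign(ifelse(is.finite(s), s, 0)) * 10
      }
      s
    } else {
      stats::coef(stats::lm(y ~ x, data = d))[["x"]]
    }
    data.frame(subject = d$subject[1], group = d$group[1], slope = slope)
  })
  slopes <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(slopes) || nrow(slopes) < 2)
    stop("twostage_association: fewer than 2 usable subjects",
         call. = FALSE)
  main <- stats::t.test(slopes$slope)
  groups <- unique(slopes$group)
  if (length(groups) == 2) {
    gt <- stats::t.test(slope ~ group, data = slopes, var.equal = TRUE)
    t_group <- unname(gt$statistic); p_group <- gt$p.value
  } else {
    t_group <- NA_real_; p_group <- NA_real_
  }
  list(slopes = slopes, mean_slope = mean(slopes$slope),
       t_main = unname(main$statistic), p_main = main$p.value,
       t_group = t_group, p_group = p_group)
}

#' Long-format export for external mixed-model replication
#'
#' Assembles a subject/group/trial/distinctiveness/outcome table so the
#' random-slopes generalized mixed models (e.g.
#' `Memory ~ Age * Distinctiveness + (1 + Distinctiveness | Subject)`)
#' can be fit in any mixed-model tool.
#'
#' @param cohort list of subjects from [generate_cohort()] (each with
#'   `design` and `distinct`).
#' @param level `"item"` or `"category"` distinctiveness column.
#' @return data.frame with columns `subject`, `group`, `stimulus_id`,
#'   `distinctiveness`, `memory` (1 = hit, 0 = miss).
#' @export
export_long_table <- function(cohort, level = c("item", "category")) {
  level <- match.arg(level)
  col <- if (level == "item") "d_item" else "d_cat"
  rows <- lapply(cohort, function(s) {
    ret <- s$design[s$design$phase == "RETRIEVAL" &
                      s$design$condition != "new" &
                      s$design$item_outcome %in% c("hit", "miss"), ]
    d <- s$distinct[[col]][match(ret$stimulus_id, s$distinct$stimulus_id)]
    data.frame(subject = s$subject_id, group = s$group,
               stimulus_id = ret$stimulus_id, distinctiveness = d,
               memory = as.integer(ret$item_outcome == "hit"))
  })
  do.call(rbind, rows)
}
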