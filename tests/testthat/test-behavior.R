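make_retrieval <- function(n_old_hit, n_old_miss, n_new_cr, n_new_fa,
                           pair_correct = NULL) {
  n_old <- n_old_hit + n_old_miss
  n_new <- n_new_cr + n_new_fa
  ret <- data.frame(
    trial_id = seq_len(n_old + n_new), phase = "RETRIEVAL", run = 8L,
    stimulus_id = seq_len(n_old + n_new), category = "object",
    is_target = FALSE, paired_scene_id = NA_integer_,
    condition = c(rep("old_match", n_old), rep("new", n_new)),
    item_outcome = c(rep("hit", n_old_hit), rep("miss", n_old_miss),
                     rep("corr_rej", n_new_cr), rep("false_alarm", n_new_fa)),
    pair_outcome = "none", stringsAsFactors = FALSE)
  if (!is.null(pair_correct))
    ret$pair_outcome[seq_len(n_old)] <- ifelse(seq_len(n_old) <=
                                                 pair_correct,
                                               "correct", "incorrect")
  ret
}

test_that("memory scores equal brute-force confusion-matrix counting", {
  # 250 old with 200 hits, 150 new with 120 correct rejections -> 0.8
  ret <- make_retrieval(200, 50, 120, 30, pair_correct = 175)
  s <- memory_scores(ret)
  expect_equal(s$pr_item, 320 / 400)
  expect_equal(s$HR, 200 / 250)
  expect_equal(s$FAR, 30 / 150)
  expect_equal(s$pr_pair, 175 / 250)
  expect_equal(s$chance, 0.5 * 250 / 400)
  expect_true(s$above_chance)
  expect_equal(unname(s$counts), c(200L, 50L, 120L, 30L))

  # all correct
  s2 <- memory_scores(make_retrieval(250, 0, 150, 0))
  expect_equal(s2$pr_item, 1)

  # pair scoring conditioned on a correct item response
  ret3 <- make_retrieval(200, 50, 120, 30, pair_correct = 175)
  s3 <- memory_scores(ret3, pair_item_correct_only = TRUE)
  expect_equal(s3$pr_pair, mean(ret3$pair_outcome[ret3$item_outcome ==
                                                    "hit"] == "correct"))

  expect_error(memory_scores(ret[0, ]), "no retrieval")
})

test_that("chance level and response bias implement the stated formulas", {
  ch <- chance_level(0.5, 250, 400)
  expect_equal(ch$exact, 0.3125)
  expect_equal(ch$printed, 0.31)
  expect_equal(chance_level(1.0, 7, 7)$exact, 1.0)
  expect_equal(chance_level(0.5, 100, 400)$exact, 0.125)
  expect_error(chance_level(0.5, 0, 400), "n_old")
  expect_error(chance_level(0.5, 10, 0), "n_total")

  expect_equal(response_bias(1, 0), 0)  # zero numerator at the 0/0 corner
  expect_equal(response_bias(0.8, 0.2), 0.5)
  expect_equal(response_bias(0.3, 0.3), 0.3)
  expect_error(response_bias(1.2, 0.2))
})

test_that("subsequent-memory split reproduces unsplit maps when all hit", {
  d <- generate_design(toy_spec())
  b <- toy_betas(d)
  spec <- searchlight_spec(2, 2, min_voxels = 1)
  d_all <- d
  enc_obj <- d_all$phase %in% c("TD1", "TD2") & d_all$category == "object" &
    !d_all$is_target
  d_all$item_outcome[enc_obj] <- "hit"
  # need >= 2 forgotten: all-hit must error, then check against unsplit
  expect_error(subsequent_memory_maps(b, d_all, spec, "item"),
               "remembered or forgotten")

  # split with both subsets and compare against brute-force subsetting
  td1 <- d[d$phase == "TD1" & d$category == "object" & !d$is_target, ]
  stim <- sort(td1$stimulus_id)
  rem <- stim[1:3]; forg <- stim[4:6]
  d2 <- d
  enc <- d2$phase %in% c("TD1", "TD2")
  d2$item_outcome[enc & d2$stimulus_id %in% rem] <- "hit"
  d2$item_outcome[enc & d2$stimulus_id %in% forg] <- "miss"
  sm <- subsequent_memory_maps(b, d2, spec, "item")
  expect_equal(sm$n_remembered, 3L)
  direct_rem <- item_distinctiveness(b, d, spec, stimuli = rem)
  expect_equal(sm$remembered$item_diff, direct_rem$item_diff)
  expect_equal(sm$difference,
               sm$remembered$item_diff - sm$forgotten$item_diff)

  # with the full object set the restricted map equals the plain map
  full <- item_distinctiveness(b, d, spec)
  restr <- item_distinctiveness(b, d, spec, stimuli = stim)
  expect_equal(full$item_diff, restr$item_diff)
})

test_that("two-stage association recovers a known slope", {
  set.seed(31)
  n_sub <- 20; n_tr <- 100
  dat <- do.call(rbind, lapply(seq_len(n_sub), function(s) {
    x <- rnorm(n_tr)
    data.frame(subject = s, group = ifelse(s <= 10, "young", "old"),
               x = x, y = 0.18 * x + rnorm(n_tr, sd = 0.3))
  }))
  fit <- twostage_association(dat, family = "gaussian")
  ci <- fit$mean_slope + c(-1, 1) * qt(0.975, n_sub - 1) *
    sd(fit$slopes$slope) / sqrt(n_sub)
  expect_true(ci[1] <= 0.18 && 0.18 <= ci[2])
  expect_lt(fit$p_main, 0.001)
  expect_gt(fit$p_group, 0.01)  # no group difference built in

  # binary outcome independent of predictor: slope near zero
  set.seed(32)
  datb <- do.call(rbind, lapply(seq_len(n_sub), function(s)
    data.frame(subject = s, group = ifelse(s <= 10, "young", "old"),
               x = rnorm(n_tr), y = rbinom(n_tr, 1, 0.5))))
  fitb <- twostage_association(datb, family = "binomial")
  expect_lt(abs(fitb$mean_slope), 0.15)
  expect_gt(fitb$p_main, 0.01)

  # perfect separation is clipped with a warning
  sep <- data.frame(subject = 1, group = "young",
                    x = c(-(5:1), 1:5), y = c(rep(0, 5), rep(1, 5)))
  sep2 <- data.frame(subject = 2, group = "young",
                     x = rnorm(10), y = rbinom(10, 1, 0.5))
  expect_warning(fs <- twostage_association(rbind(sep, sep2), "binomial"),
                 "clipped")
  expect_equal(max(abs(fs$slopes$slope)), 10)
})

test_that("long-format export aligns outcomes with distinctiveness", {
  gp <- list(young = signal_params(0.3, 0.3, c(6, 6, 4)),
             old = signal_params(0.1, 0.1, c(6, 6, 4)))
  co <- generate_cohort(2, 2, gp, toy_spec(), seed = 3,
                        memory_mod = memory_model(beta0 = 0.2,
                                                  beta1_cat = 1))
  long <- export_long_table(co, "category")
  expect_named(long, c("subject", "group", "stimulus_id",
                       "distinctiveness", "memory"))
  expect_true(all(long$memory %in% 0:1))
  expect_false(anyNA(long$distinctiveness))
  expect_equal(sort(unique(long$subject)), 1:4)
})
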