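test_that("draw_sample is uniform without replacement and reproducible", {
  ds <- make_dataset(100, p = 2, seed = 1)
  set.seed(10)
  s1 <- draw_sample(ds, 100)
  expect_equal(sort(s1$y), sort(ds$y)) # size = n is a permutation
  set.seed(10)
  s2 <- draw_sample(ds, 100)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_error(draw_sample(ds, 101), "exceeds")

  # inclusion frequency of each case ~ Binomial(draws, size/n)
  set.seed(11)
  counts <- numeric(100)
  draws <- 2000
  for (i in seq_len(draws)) {
    idx <- match(draw_sample(ds, 10)$y, ds$y)
    counts[idx] <- counts[idx] + 1
  }
  p_hat <- counts / draws
  se <- sqrt(0.1 * 0.9 / draws)
  expect_lt(max(abs(p_hat - 0.1)), 5 * se)
  expect_lt(mean(abs(p_hat - 0.1) > 3 * se), 0.05)
})

test_that("random 80/20 splits follow banker's rounding and are exhaustive", {
  ds <- make_dataset(100, p = 2, seed = 5)
  set.seed(1)
  sp <- random_split(draw_sample(ds, 100), 0.8)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sort(c(sp$train$y, sp$test$y)), sort(ds$y))

  set.seed(2)
  sp99 <- random_split(draw_sample(ds, 99), 0.8)
  expect_equal(nrow(sp99$train), 79) # round(79.2) = 79
  expect_equal(nrow(sp99$test), 20)
})

test_that("replicate groups never straddle a split or sample boundary", {
  base <- make_dataset(30, p = 2, seed = 9)
  reps <- add_replicates(base, 5, within_noise_sd = 0.1)
  set.seed(3)
  sub <- draw_sample(reps, 100)
  expect_equal(nrow(sub) %% 5, 0) # whole groups only
  sp <- random_split(sub, 0.8)
  tr_groups <- unique(sp$train$.sample)
  te_groups <- unique(sp$test$.sample)
  expect_length(intersect(tr_groups, te_groups), 0)
  expect_true(all(table(sp$train$.sample) == 5))
  expect_true(all(table(sp$test$.sample) == 5))
})

test_that("Kennard-Stone splitting executes the max-min rule deterministically", {
  # 1-D predictors {0, 1, 10}: the extreme pair forms the training set
  d <- data.frame(x1 = c(0, 1, 10), y = c(1, 2, 3))
  ds <- as_validation_dataset(d, "x1", "y")
  sp <- kennard_stone_split(ds, 2 / 3)
  expect_setequal(sp$train$x1, c(0, 10))
  expect_equal(sp$test$x1, 1)

  # deterministic: re-running gives the identical split
  ds2 <- make_dataset(60, p = 3, seed = 17)
  a <- kennard_stone_split(ds2, 0.8)
  b <- kennard_stone_split(ds2, 0.8)
  expect_identical(as.data.frame(a$train), as.data.frame(b$train))

  # an exact duplicate pair lands on opposite sides: the twin has min
  # distance 0 to the training set and is picked last
  d6 <- data.frame(x1 = c(0, 0, 3, 7, 10, 5), y = 1:6)
  ds6 <- as_validation_dataset(d6, "x1", "y")
  sp6 <- kennard_stone_split(ds6, 2 / 3) # n_train = 4 of 6
  expect_equal(sum(sp6$train$x1 == 0), 1)
  expect_equal(sum(sp6$test$x1 == 0), 1)
})

test_that("run_sweep bookkeeping, determinism and failure logging", {
  ds <- make_dataset(200, p = 3, seed = 23)
  sw <- run_sweep(ds, model_spec("mlr"), sizes = 30, n_repeats = 3,
                  cv = list(loo = TRUE, m = 2), seed = 77)
  expect_equal(nrow(sw$records), 3)
  expect_equal(nrow(sw$cv), 6) # loo + one m-fold per repetition
  expect_equal(sw$records$n_train + sw$records$n_test,
               rep(30, 3))

  sw2 <- run_sweep(ds, model_spec("mlr"), sizes = 30, n_repeats = 3,
                   cv = list(loo = TRUE, m = 2), seed = 77)
  expect_identical(sw$records, sw2$records)
  expect_identical(sw$cv, sw2$cv)
  expect_equal(nrow(attr(sw, "failures")), 0)
})

test_that("summary statistics behave as order statistics per cell", {
  ds <- make_dataset(200, p = 3, seed = 29)
  sw <- run_sweep(ds, model_spec("mlr"), sizes = c(30, 60), n_repeats = 9,
                  cv = list(loo = TRUE), seed = 5)
  med <- summarize_sweep(sw, "median")
  avg <- summarize_sweep(sw, "mean")
  qrt <- summarize_sweep(sw, "quartiles")
  expect_true(all(qrt$q25 <= qrt$value & qrt$value <= qrt$q75))

  # an injected outlier record drags the mean much further than the median
  sw_out <- sw
  sw_out$records$r2[1] <- -50
  med2 <- summarize_sweep(sw_out, "median")
  avg2 <- summarize_sweep(sw_out, "mean")
  pick <- med$metric == "r2" & med$size == 30
  med_shift <- abs(med2$value[pick] - med$value[pick])
  avg_shift <- abs(avg2$value[pick] - avg$value[pick])
  expect_gt(avg_shift, 10 * med_shift + 1)
  expect_lt(med_shift, 0.2)
})
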