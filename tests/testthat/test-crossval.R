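test_that("LOO Q2 via the hat matrix matches hand arithmetic on the intercept-only case", {
  # y = (1,2,3), intercept-only: PRESS = 4.5, TSS = 2, q2 = 1 - 4.5/2
  press <- press_hat_matrix(matrix(numeric(0), 3, 0), c(1, 2, 3))
  tss <- sum((c(1, 2, 3) - 2)^2)
  expect_equal(1 - press / tss, -1.25)
})

test_that("hat-matrix LOO equals explicit refitting for MLR", {
  set.seed(25)
  inst <- random_ols_instance(25, 3)
  ds <- as_ds(inst$X, inst$y)
  res <- loo_cv(ds, model_spec("mlr"))
  press_bf <- brute_force_press(inst$X, inst$y)
  tss <- sum((inst$y - mean(inst$y))^2)
  expect_equal(res$q2, 1 - press_bf / tss, tolerance = 1e-8)
  expect_equal(res$n_fitted, 24)
  expect_equal(res$rmse_cv, sqrt(press_bf / 25), tolerance = 1e-8)

  # noiseless linear data: perfect cross-validated predictions
  clean <- random_ols_instance(30, 3, noise_sd = 0)
  expect_equal(loo_cv(as_ds(clean$X, clean$y), model_spec("mlr"))$q2, 1,
               tolerance = 1e-10)
})

test_that("Q2_LOO <= R2 and PRESS >= RSS for MLR fits", {
  set.seed(71)
  for (i in 1:50) {
    inst <- random_ols_instance(sample(12:40, 1), sample(1:4, 1))
    ds <- as_ds(inst$X, inst$y)
    r2 <- glance(fit_model(ds, model_spec("mlr")))$r2
    cv <- loo_cv(ds, model_spec("mlr"))
    expect_lte(cv$q2, r2 + 1e-12)
    # PRESS >= RSS: every LOO residual magnifies the ordinary one
    tss <- sum((inst$y - mean(inst$y))^2)
    press <- (1 - cv$q2) * tss
    rss <- (1 - r2) * tss
    expect_gte(press, rss - 1e-10)
  }
})

test_that("n-fold cross-validation with m = n reproduces LOO per-case predictions", {
  set.seed(13)
  inst <- random_ols_instance(20, 3)
  ds <- as_ds(inst$X, inst$y)
  loo <- loo_cv(ds, model_spec("mlr"))
  set.seed(1)
  nf <- mfold_cv(ds, model_spec("mlr"), m = 20)
  expect_equal(attr(nf, "cv_predictions"), attr(loo, "cv_predictions"),
               tolerance = 1e-10)
  expect_equal(nf$q2, loo$q2, tolerance = 1e-10)
  expect_equal(nf$n_fitted, loo$n_fitted)
})

test_that("m-fold balanced partitions give the stated n_fitted", {
  set.seed(2)
  ds <- make_dataset(100, p = 3, seed = 2)
  r <- mfold_cv(ds, model_spec("mlr"), m = 5)
  expect_equal(r$n_fitted, 80)

  ds10 <- make_dataset(10, p = 2, seed = 3)
  r <- mfold_cv(ds10, model_spec("mlr"), m = 3)
  # folds of sizes {4,3,3}: n_fitted = (6+7+7)/3
  expect_equal(r$n_fitted, 20 / 3, tolerance = 1e-12)
  expect_error(mfold_cv(ds10, model_spec("mlr"), m = 11), "between 2 and")
})

test_that("grouped schemes reduce to LOO in their degenerate limits", {
  set.seed(41)
  base <- make_dataset(15, p = 2, seed = 41)
  # singleton groups: leave-sample-out is exactly leave-case-out
  df <- as.data.frame(base)
  df$g <- seq_len(nrow(df))
  singles <- as_validation_dataset(df, predictors = c("x1", "x2"),
                                   responses = "y", group = "g")
  lso <- grouped_cv(singles, model_spec("mlr"), "leave_sample_out")
  loo <- loo_cv(base, model_spec("mlr"))
  expect_equal(lso$q2, loo$q2, tolerance = 1e-10)

  # exact replicates: group-means scheme equals LOO on the deduplicated set
  rep3 <- add_replicates(base, 3, within_noise_sd = 0)
  gm <- grouped_cv(rep3, model_spec("mlr"), "loo_on_group_means")
  expect_equal(gm$q2, loo$q2, tolerance = 1e-10)
})

test_that("leave-sample-out removes the leakage that inflates leave-case-out Q2", {
  set.seed(57)
  wins <- 0
  n_sims <- 40
  for (i in 1:n_sims) {
    base <- make_dataset(20, p = 3, noise_sd = 2)
    reps <- add_replicates(base, 3, within_noise_sd = 0.05)
    q2_case <- loo_cv(reps, model_spec("mlr"))$q2
    q2_sample <- grouped_cv(reps, model_spec("mlr"), "leave_sample_out")$q2
    wins <- wins + (q2_case > q2_sample)
  }
  expect_gt(wins / n_sims, 0.8)
})

test_that("the n_fitted overlay interpolates LOO at LMO abscissae", {
  # single LOO curve: nothing to compare
  loo_only <- tibble::tibble(scheme = "loo", n_fitted = c(20, 40), q2 = c(0.5, 0.7))
  expect_equal(nrow(rescale_to_fitted(loo_only)), 0)

  # exact abscissa match by construction: LOO at n_train=101 vs 2-fold at 200
  curves <- tibble::tibble(
    scheme = c("loo", "loo", "mfold2"),
    n_fitted = c(100, 300, 100),
    q2 = c(0.60, 0.80, 0.61))
  out <- rescale_to_fitted(curves)
  expect_equal(nrow(out), 1)
  expect_equal(out$q2_loo, 0.60)
  expect_equal(out$gap, 0.01)

  # no overlap is an error
  bad <- tibble::tibble(scheme = c("loo", "mfold2"), n_fitted = c(100, 10),
                        q2 = c(0.6, 0.2))
  expect_error(rescale_to_fitted(bad), "empty overlap|inside")
})
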