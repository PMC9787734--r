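test_that("MLR recovers exact linear data and matches the normal equations", {
  set.seed(11)
  # noiseless y = 2 x1 - x2 + 3
  X <- matrix(rnorm(60), 30, 2)
  y <- 2 * X[, 1] - X[, 2] + 3
  fit <- fit_model(as_ds(X, y), model_spec("mlr"))
  expect_equal(unname(fit$coefficients), c(3, 2, -1), tolerance = 1e-10)
  expect_equal(glance(fit)$r2, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$p_params, 2)

  # random instance: predictions equal the normal-equations closed form
  inst <- random_ols_instance(30, 4)
  ds <- as_ds(inst$X, inst$y)
  fit <- fit_model(ds, model_spec("mlr"))
  Xi <- cbind(1, inst$X)
  beta_ne <- solve(crossprod(Xi), crossprod(Xi, inst$y))
  expect_equal(unname(predict(fit, ds)), unname(drop(Xi %*% beta_ne)),
               tolerance = 1e-8)
})

test_that("MLR rejects degenerate designs", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_model(as_ds(cbind(X, X[, 1] * 2), rnorm(10)),
                         model_spec("mlr")), "singular")
  expect_error(fit_model(as_ds(matrix(rnorm(12), 4, 3), rnorm(4)),
                         model_spec("mlr")), "underdetermined")
})

test_that("MLR training R2 never decreases when a predictor is added", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_ols_instance(40, 4)
    r2_small <- glance(fit_model(as_ds(inst$X[, 1:3], inst$y),
                                 model_spec("mlr")))$r2
    r2_big <- glance(fit_model(as_ds(inst$X, inst$y), model_spec("mlr")))$r2
    expect_gte(r2_big, r2_small - 1e-12)
  }
})

test_that("PLS with full latent rank reproduces OLS", {
  set.seed(5)
  inst <- random_ols_instance(60, 4)
  ds <- as_ds(inst$X, inst$y)
  pls <- fit_model(ds, model_spec("pls2", n_latent = 4))
  ols <- fit_model(ds, model_spec("mlr"))
  expect_equal(predict(pls, ds), unname(predict(ols, ds)), tolerance = 1e-6)
})

test_that("one latent variable suffices when y follows a single predictor", {
  set.seed(8)
  n <- 200
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- 2 * X[, 1] # exactly proportional to x1; x2, x3 pure noise
  ds <- as_ds(X, y)
  fit <- fit_model(ds, model_spec("pls2", n_latent = 1, standardize_y = FALSE))
  expect_gt(glance(fit)$r2, 0.99)
  expect_equal(glance(fit)$n_latent, 1)
})

test_that("PLS training RSS is non-increasing in the latent-variable count", {
  set.seed(12)
  inst <- random_ols_instance(50, 5)
  ds <- as_ds(inst$X, inst$y)
  rss <- vapply(1:5, function(a) {
    fit <- fit_model(ds, model_spec("pls2", n_latent = a))
    sum((inst$y - fit$fitted[, 1])^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("PLS standardization changes fits only for unequal-scale predictors", {
  set.seed(19)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1] - X[, 2] + rnorm(40, sd = 0.3)
  # pre-standardized data: the flag is immaterial
  Xs <- scale(X)
  ds_s <- as_ds(Xs, y)
  f_on <- fit_model(ds_s, model_spec("pls2", n_latent = 1, standardize_x = TRUE))
  f_off <- fit_model(ds_s, model_spec("pls2", n_latent = 1, standardize_x = FALSE))
  expect_equal(predict(f_on, ds_s), predict(f_off, ds_s), tolerance = 1e-10)
  # wildly different scales: the flag matters
  Xu <- X %*% diag(c(1, 1000))
  ds_u <- as_ds(Xu, y)
  g_on <- fit_model(ds_u, model_spec("pls2", n_latent = 1, standardize_x = TRUE))
  g_off <- fit_model(ds_u, model_spec("pls2", n_latent = 1, standardize_x = FALSE))
  expect_gt(max(abs(predict(g_on, ds_u) - predict(g_off, ds_u))), 1e-4)
})

test_that("PLS agrees with the mixOmics implementation on a multiresponse fit", {
  skip_if_not_installed("mixOmics")
  set.seed(77)
  ds <- make_dataset(80, p = 6, q = 2,
                     structure = "latent_factor_multiresponse",
                     n_latent = 2, seed = 77)
  fit <- fit_model(ds, model_spec("pls2", n_latent = 2))
  X <- as.matrix(as.data.frame(ds)[paste0("x", 1:6)])
  Y <- as.matrix(as.data.frame(ds)[c("y1", "y2")])
  mo <- mixOmics::pls(X, Y, ncomp = 2, mode = "regression", scale = TRUE)
  mo_pred <- predict(mo, X)$predict[, , 2]
  expect_equal(unname(fit$fitted), unname(mo_pred), tolerance = 1e-6)
})

test_that("PLS precondition failures are caught", {
  set.seed(3)
  inst <- random_ols_instance(20, 3)
  ds <- as_ds(inst$X, inst$y)
  expect_error(fit_model(ds, model_spec("pls2", n_latent = 7)), "n_latent")
  expect_error(fit_model(ds, model_spec("pls2")), "n_latent")
  X0 <- inst$X; X0[, 2] <- 1 # zero-variance column under standardization
  expect_error(fit_model(as_ds(X0, inst$y),
                         model_spec("pls2", n_latent = 2)), "zero-variance")
})

test_that("ANN capacity rule and weight count follow the stated arithmetic", {
  # p = 5 predictors, 30 cases: 4 hidden units give 29 weights
  expect_equal(hidden_units_for(5, 30), 4L)
  set.seed(21)
  ds <- make_dataset(40, p = 5, seed = 21)
  fit <- fit_model(ds, model_spec("ann", n_hidden = 4, maxit = 10))
  expect_equal(fit$p_params, 29)
})

test_that("ANN fits are reproducible given the RNG and learn a smooth surface", {
  ds <- make_dataset(400, p = 3, structure = "nonlinear_smooth",
                     noise_sd = 0.1, seed = 31)
  set.seed(99)
  f1 <- fit_model(ds, model_spec("ann", n_hidden = 8, maxit = 2000))
  set.seed(99)
  f2 <- fit_model(ds, model_spec("ann", n_hidden = 8, maxit = 2000))
  expect_identical(f1$fitted, f2$fitted)

  # at least one point of a small grid reaches R2 > 0.95 on sin(x1) + x2^2
  r2s <- vapply(c(4, 8, 12), function(H) {
    set.seed(100 + H)
    glance(fit_model(ds, model_spec("ann", n_hidden = H,
                                    maxit = 2000)))$r2
  }, numeric(1))
  expect_gt(max(r2s), 0.95)
})

test_that("SVR epsilon controls the support-vector count as expected", {
  set.seed(55)
  ds <- make_dataset(100, p = 3, seed = 55)
  y_range <- diff(range(ds$y))

  # tube wider than the response range swallows every case
  wide <- fit_model(ds, model_spec("svr", epsilon = 2 * y_range))
  expect_lte(glance(wide)$n_support_vectors, 2)
  expect_lt(sd(predict(wide, ds)), 0.05 * sd(ds$y)) # essentially flat

  # epsilon -> 0 on noisy data: nearly every case becomes a support vector
  tight <- fit_model(ds, model_spec("svr", epsilon = 1e-4))
  expect_gte(glance(tight)$sv_fraction, 0.95)

  # support-vector fraction is non-increasing in epsilon
  fr <- vapply(c(0.01, 0.1, 0.5, 1), function(eps) {
    glance(fit_model(ds, model_spec("svr", epsilon = eps)))$sv_fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))

  # determinism: same spec, same data, same support-vector count
  f1 <- fit_model(ds, model_spec("svr", epsilon = 0.1))
  f2 <- fit_model(ds, model_spec("svr", epsilon = 0.1))
  expect_identical(glance(f1)$n_support_vectors, glance(f2)$n_support_vectors)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("hyperparameter validation rejects bad specs", {
  expect_error(model_spec("svr", cost = -1), "cost")
  expect_error(model_spec("svr", gamma = 0), "gamma")
  expect_error(model_spec("mlr", n_latent = 2), "unknown")
  expect_error(model_spec("ann", n_hidden = 0), "n_hidden")
})

test_that("tidy returns interpretable coefficients for linear families", {
  set.seed(61)
  inst <- random_ols_instance(40, 3)
  ds <- as_ds(inst$X, inst$y)
  td <- tidy(fit_model(ds, model_spec("mlr")))
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 4)

  # pls2 coefficients back-transformed to original units reproduce fitted values
  fit <- fit_model(ds, model_spec("pls2", n_latent = 3))
  td <- tidy(fit)
  b <- td$estimate[td$term != "(Intercept)"]
  a <- td$estimate[td$term == "(Intercept)"]
  manual <- drop(inst$X %*% b) + a
  expect_equal(manual, fit$fitted[, 1], tolerance = 1e-8)
})
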