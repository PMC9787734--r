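# small fixture builders shared across test files

# random full-rank OLS instance with a linear signal
random_ols_instance <- function(n, p, noise_sd = 1) {
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  list(X = X, y = y, beta = beta)
}

as_ds <- function(X, y) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$y <- y
  as_validation_dataset(df, predictors = paste0("x", seq_len(ncol(X))),
                        responses = "y")
}

# independent brute-force leave-one-out PRESS oracle: n explicit refits
# through stats::lm, never touching the package fitting code
brute_force_press <- function(X, y) {
  n <- length(y)
  df <- data.frame(X, y = y)
  sum(vapply(seq_len(n), function(i) {
    f <- stats::lm(y ~ ., data = df[-i, , drop = FALSE])
    (y[i] - stats::predict(f, newdata = df[i, , drop = FALSE]))^2
  }, numeric(1)))
}

# closed-form simple linear regression (slope = Sxy/Sxx)
simple_ols_predictions <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  a + b * x
}
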