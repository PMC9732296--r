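test_that("design matrix matches element-wise kernel evaluation", {
  x <- matrix(c(0.3, -1.2, 2.0, 0.1, -0.7, 1.5), ncol = 2)
  k <- rvm_kernel("rbf", width = 1, include_bias = TRUE)
  phi <- rvm_design_matrix(x, x, k)
  expect_equal(dim(phi), c(3L, 4L))
  expect_equal(phi[, 1], rep(1, 3))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(phi[i, j + 1],
                 exp(-sum((x[i, ] - x[j, ])^2) / 2), tolerance = 1e-14)
  }
  expect_equal(diag(phi[, -1]), rep(1, 3))  # K(x, x) = 1 for rbf

  klin <- rvm_kernel("linear", include_bias = FALSE)
  phil <- rvm_design_matrix(x, x, klin)
  expect_equal(phil, tcrossprod(x))
  expect_equal(phil, t(phil))

  kpoly <- rvm_kernel("polynomial", degree = 3, include_bias = FALSE)
  expect_equal(rvm_design_matrix(x, x, kpoly), (1 + tcrossprod(x))^3)
})

test_that("weight posterior has the diagonal closed form when phi is identity", {
  phi <- diag(2)
  t <- c(1.5, -2)
  alpha <- c(0.5, 0.5); sigma2 <- 0.25
  post <- rvm_posterior(phi, t, alpha, sigma2)
  expect_equal(diag(post$C), rep(1 / (1 / sigma2 + 0.5), 2), tolerance = 1e-10)
  expect_equal(post$mu, (1 / sigma2) / (1 / sigma2 + 0.5) * t, tolerance = 1e-10)
})

test_that("an enormous prior precision pins the posterior weight at zero", {
  set.seed(4)
  phi <- matrix(rnorm(20), 5, 4)
  t <- rnorm(5)
  alpha <- c(1, 1e12, 1, 1)
  post <- rvm_posterior(phi, t, alpha, 0.1)
  expect_lt(abs(post$mu[2]), 1e-8)
})

test_that("posterior equals the brute-force matrix-inverse oracle", {
  set.seed(11)
  for (rep in 1:5) {
    phi <- matrix(rnorm(25), 5, 5)
    t <- rnorm(5)
    alpha <- runif(5, 0.01, 10)
    sigma2 <- runif(1, 0.05, 2)
    post <- rvm_posterior(phi, t, alpha, sigma2, jitter = 0)
    ora <- oracle_posterior(phi, t, alpha, sigma2)
    expect_equal(post$mu, ora$mu, tolerance = 1e-10)
    expect_equal(post$C, ora$C, tolerance = 1e-10)
  }
})

test_that("hyperparameter update follows the fixed-point formulas", {
  # gamma = 1 - alpha * C_ii exactly, including the limit alpha * C_ii = 0
  C <- diag(c(0, 0.5, 0.1))
  mu <- c(1, 2, -1)
  phi <- diag(3)
  t <- c(1, 2, -1)
  upd <- rvm_hyperparameter_step(mu, C, phi, t, alpha = c(5, 1, 2))
  expect_identical(upd$gamma, 1 - c(5, 1, 2) * diag(C))
  expect_equal(upd$gamma[1], 1)

  # perfect fit: residual 0 drives the variance to its floor
  expect_equal(upd$sigma2, 1e-12)

  # one full update on a fixed 4-point instance vs the scalar oracle
  set.seed(21)
  phi4 <- cbind(1, matrix(rnorm(12), 4, 3))
  t4 <- rnorm(4)
  alpha4 <- runif(4, 0.1, 2)
  post <- rvm_posterior(phi4, t4, alpha4, 0.3, jitter = 0)
  upd4 <- rvm_hyperparameter_step(post$mu, post$C, phi4, t4, alpha4)
  ora4 <- oracle_hyper_step(post$mu, post$C, phi4, t4, alpha4)
  expect_equal(upd4$gamma, ora4$gamma, tolerance = 1e-10)
  expect_equal(upd4$alpha, ora4$alpha, tolerance = 1e-10)
  expect_equal(upd4$sigma2, ora4$sigma2, tolerance = 1e-10)
})

test_that("pruning removes only diverged bases and preserves predictions", {
  d <- generate_titration(titration_config(n_batches = 40, basal_glucose = 80,
                                           seed = 31))
  fit <- rvm(cbgm ~ g_add + v_u, data = d)
  # nothing above threshold: unchanged
  expect_identical(rvm_prune(fit, threshold = max(fit$alpha) + 1), fit)
  # push one precision past a lowered threshold: that basis disappears
  thr <- sort(fit$alpha, decreasing = TRUE)[2] * 1.01
  if (max(fit$alpha) > thr) {
    pruned <- rvm_prune(fit, threshold = thr)
    expect_equal(length(pruned$active), length(fit$active) - 1L)
    expect_false(which.max(fit$alpha) %in% match(pruned$active, fit$active))
  }
  # removing near-zero-weight bases barely moves training predictions
  soft <- rvm_prune(fit, threshold = 1e7)
  keep_w <- fit$mu[fit$alpha > 1e7]
  if (length(keep_w) && all(abs(keep_w) < 1e-8)) {
    expect_equal(predict(soft, d), predict(fit, d), tolerance = 1e-6)
  }
  expect_error(rvm_prune(fit, threshold = min(fit$alpha) / 2), "every basis")
})

test_that("fit recovers a noise-free linear map", {
  g <- seq(1, 30)
  d <- data.frame(g = g, y = 2 * g)
  fit <- rvm(y ~ g, data = d, kernel = rvm_kernel("linear"))
  expect_lt(max(abs(predict(fit, d) - d$y)), 1e-3)
})

test_that("constant targets are carried by the bias basis alone", {
  set.seed(8)
  d <- data.frame(g = rnorm(20), y = rep(3.5, 20))
  fit <- suppressWarnings(
    rvm(y ~ g, data = d,
        kernel = rvm_kernel("rbf", width = 1),
        control = rvm_control(sigma2_init = 1e-4)))
  expect_lt(max(abs(fitted(fit) - 3.5)), 1e-3)
  w <- coef(fit)
  non_bias <- w[names(w) != "(bias)"]
  if (length(non_bias)) expect_lt(max(abs(non_bias)), 1e-3)
})

test_that("prediction matches the direct formula on the active bases", {
  d <- generate_titration(titration_config(n_batches = 30, basal_glucose = 80,
                                           seed = 13))
  fit <- rvm(cbgm ~ g_add + v_u, data = d)
  new <- d[c(2, 9, 25), ]
  pr <- predict(fit, new, se.fit = TRUE)
  # direct evaluation: phi(z) mu and sigma2 + phi C phi'
  Xs <- sweep(sweep(as.matrix(new[c("g_add", "v_u")]), 2, fit$center),
              2, fit$scale, "/")
  rv <- fit$relevance_vectors
  K <- exp(-as.matrix(stats::dist(rbind(Xs, rv)))[1:3, 3 + seq_len(nrow(rv))]^2 /
             (2 * fit$kernel$width^2))
  phi <- if (0 %in% fit$active) cbind(1, K) else K
  expect_equal(pr$fit, drop(phi %*% fit$mu), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pr$variance,
               fit$sigma2 + rowSums((phi %*% fit$C) * phi),
               tolerance = 1e-12, ignore_attr = TRUE)
  # predictive variance never drops below the noise floor
  expect_true(all(pr$variance >= fit$sigma2))
  expect_error(predict(fit, matrix(1, 2, 5)), "feature")
})

test_that("interpolation: zero-noise fits reproduce training targets", {
  d <- generate_titration(titration_config(n_batches = 60, basal_glucose = 80,
                                           sensor_noise_sd = 0, meter_cv = 0))
  fit <- suppressWarnings(rvm(cbgm ~ g_add + v_u, data = d))
  expect_lt(max(abs(predict(fit, d) - d$cbgm) / d$cbgm), 5e-3)
})

test_that("the fit is deterministic and logs its convergence", {
  d <- generate_titration(titration_config(n_batches = 40, basal_glucose = 80,
                                           seed = 17))
  f1 <- rvm(cbgm ~ g_add + v_u, data = d)
  f2 <- rvm(cbgm ~ g_add + v_u, data = d)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$sigma2, f2$sigma2)
  log <- f1$convergence_log
  expect_true(all(c("iteration", "sigma2", "n_active", "max_dlogalpha",
                    "log_evidence") %in% names(log)))
  expect_equal(nrow(log), f1$iterations)
  expect_true(all(is.finite(log$log_evidence)))
})

test_that("zero-variance features are rejected", {
  d <- data.frame(g = rep(2, 10), y = rnorm(10))
  expect_error(rvm(y ~ g, data = d), "zero-variance")
})

test_that("serialized models predict identically after a JSON round trip", {
  d <- generate_titration(titration_config(n_batches = 40, basal_glucose = 80,
                                           seed = 23))
  fit <- rvm(cbgm ~ g_add + v_u, data = d)
  path <- withr::local_tempfile(fileext = ".json")
  write_rvm(fit, path)
  back <- read_rvm(path)
  p1 <- predict(fit, d, se.fit = TRUE)
  p2 <- predict(back, d, se.fit = TRUE)
  expect_equal(p1$fit, p2$fit, tolerance = 1e-12)
  expect_equal(p1$variance, p2$variance, tolerance = 1e-12)
})

test_that("summary and simulate expose the fitted model sensibly", {
  d <- generate_titration(titration_config(n_batches = 40, basal_glucose = 80,
                                           seed = 29))
  fit <- rvm(cbgm ~ g_add + v_u, data = d)
  s <- summary(fit)
  expect_s3_class(s, "summary.rvm")
  expect_equal(s$n_relevance, length(fit$relevance_index))
  sims <- simulate(fit, nsim = 3, seed = 1, newdata = d[1:5, ])
  expect_equal(dim(sims), c(5L, 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
})
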