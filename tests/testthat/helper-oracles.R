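# Independent oracles used by the tests. These re-derive expected values by
# a different route than the package code (direct linear algebra, scalar
# loops, ray casting) so agreement is evidence, not tautology.

# -- linear algebra ----------------------------------------------------------

# weight posterior by direct matrix inversion (no Cholesky, no jitter)
oracle_posterior <- function(phi, t, alpha, sigma2) {
  H <- crossprod(phi) / sigma2 + diag(alpha, length(alpha))
  C <- solve(H)
  mu <- drop(C %*% crossprod(phi, t)) / sigma2
  list(mu = mu, C = C)
}

# one hyperparameter update, scalar by scalar
oracle_hyper_step <- function(mu, C, phi, t, alpha) {
  m <- length(mu)
  gamma <- numeric(m)
  alpha_new <- numeric(m)
  for (i in seq_len(m)) {
    gamma[i] <- 1 - alpha[i] * C[i, i]
    alpha_new[i] <- gamma[i] / mu[i]^2
  }
  rss <- 0
  for (k in seq_along(t)) {
    rss <- rss + (t[k] - sum(phi[k, ] * mu))^2
  }
  sigma2_new <- rss / (length(t) - sum(gamma))
  list(alpha = alpha_new, sigma2 = sigma2_new, gamma = gamma)
}

# -- agreement statistics ----------------------------------------------------

oracle_agreement <- function(ref, pred) {
  n <- length(ref)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- 100 * (pred[i] - ref[i]) / ref[i]
  bias <- sum(d) / n
  mard <- sum(abs(d)) / n
  sd_rel <- sqrt(sum((d - bias)^2) / (n - 1))
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + ref[i] * pred[i]
    sxx <- sxx + ref[i]^2
    syy <- syy + pred[i]^2
  }
  diffs <- pred - ref
  mdiff <- sum(diffs) / n
  sdd <- sqrt(sum((diffs - mdiff)^2) / (n - 1))
  list(bias = bias, mard = mard, sd_rel = sd_rel,
       ncc = sxy / sqrt(sxx * syy),
       ba_bias = mdiff, ba_limits = c(mdiff - 1.96 * sdd, mdiff + 1.96 * sdd))
}

# -- geometry ----------------------------------------------------------------

# even-odd ray casting; boundary behaviour is unspecified, so oracle tests
# use continuous random points (a.s. off the boundaries)
point_in_poly <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xcross <- (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# closed zone polygons assembled from the same vertex tables the package
# embeds, closed along the 0-550 grid frame
parkes_polygons <- function(type) {
  b <- parkes_boundaries(type)
  rev2 <- function(bd, drop_last = 0) {
    k <- length(bd$x) - drop_last
    list(x = rev(bd$x[seq_len(k)]), y = rev(bd$y[seq_len(k)]))
  }
  cat2 <- function(...) {
    parts <- list(...)
    list(x = unlist(lapply(parts, `[[`, "x")),
         y = unlist(lapply(parts, `[[`, "y")))
  }
  if (type == "type1") {
    list(
      E = list(x = c(0, 35, 50, 0), y = c(150, 155, 550, 550)),
      D = cat2(b$D_upper, list(x = 50, y = 550), rev2(b$E_upper, drop_last = 1)),
      C = cat2(b$C_upper, list(x = 125, y = 550), rev2(b$D_upper, drop_last = 1)),
      B_up = cat2(b$B_upper, list(x = 260, y = 550), rev2(b$C_upper, drop_last = 1)),
      A = list(x = c(0, 0, 30, 140, 280, 430, 550, 550, 385, 170, 50, 50),
               y = c(0, 50, 50, 170, 380, 550, 550, 450, 300, 145, 30, 0)),
      B_low = cat2(b$B_lower, list(x = 550, y = 250),
                   rev2(b$C_lower, drop_last = 0)),
      C_low = cat2(b$C_lower, list(x = 550, y = 150),
                   rev2(b$D_lower, drop_last = 0)),
      D_low = cat2(b$D_lower, list(x = 550, y = 0))
    )
  } else {
    list(
      D = cat2(b$D_upper, list(x = 0, y = 550)),
      C = cat2(b$C_upper, list(x = 125, y = 550), rev2(b$D_upper, drop_last = 1)),
      B_up = cat2(b$B_upper, list(x = 280, y = 550), rev2(b$C_upper, drop_last = 1)),
      A = list(x = c(0, 0, 30, 230, 440, 550, 550, 330, 90, 50, 50),
               y = c(0, 50, 50, 330, 550, 550, 450, 230, 80, 30, 0)),
      B_low = cat2(b$B_lower, list(x = 550, y = 250),
                   rev2(b$C_lower, drop_last = 0)),
      C_low = cat2(b$C_lower, list(x = 550, y = 160),
                   rev2(b$D_lower, drop_last = 0)),
      D_low = cat2(b$D_lower, list(x = 550, y = 0))
    )
  }
}

oracle_parkes_zone <- function(ref, pred, type) {
  polys <- parkes_polygons(type)
  for (nm in names(polys)) {
    if (point_in_poly(ref, pred, polys[[nm]]$x, polys[[nm]]$y)) {
      return(substr(nm, 1, 1))
    }
  }
  NA_character_
}

# -- benchmark data ----------------------------------------------------------

sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

make_sinc_data <- function(n = 100, noise_sd = 0.1, seed = 3) {
  set.seed(seed)
  x <- matrix(seq(-10, 10, length.out = n), ncol = 1)
  list(x = x, y = sinc(x[, 1]) + rnorm(n, 0, noise_sd))
}
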