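#' Kernel specification for relevance vector regression
#'
#' @param kind Kernel family: `"rbf"` (Gaussian, `exp(-||x-y||^2 / (2 w^2))`),
#'   `"linear"` (`<x, y>`), or `"polynomial"` (`(1 + <x, y>)^degree`).
#' @param width Length-scale `w` of the rbf kernel, in standardized feature
#'   units. `NULL` (default) resolves at fit time to the median pairwise
#'   distance between standardized training features.
#' @param degree Degree of the polynomial kernel (>= 1).
#' @param include_bias Include a constant bias basis function. The bias is
#'   an ordinary basis with its own precision hyperparameter and may be
#'   pruned like any other.
#' @return An object of class `"rvm_kernel"`.
#' @export
rvm_kernel <- function(kind = c("rbf", "linear", "polynomial"),
                       width = NULL, degree = 2L, include_bias = TRUE) {
  kind <- match.arg(kind)
  if (!is.null(width) && width <= 0) stop("'width' must be positive", call. = FALSE)
  if (degree < 1) stop("'degree' must be >= 1", call. = FALSE)
  structure(list(kind = kind, width = width, degree = as.integer(degree),
                 include_bias = isTRUE(include_bias)),
            class = "rvm_kernel")
}

#' @export
print.rvm_kernel <- function(x, ...) {
  cat(sprintf("%s kernel", x$kind))
  if (x$kind == "rbf") {
    cat(sprintf(" (width = %s)",
                if (is.null(x$width)) "median heuristic" else format(x$width)))
  }
  if (x$kind == "polynomial") cat(sprintf(" (degree = %d)", x$degree))
  cat(if (x$include_bias) ", with bias\n" else ", no bias\n")
  invisible(x)
}

# raw kernel Gram block K(x_i, y_j); x, y matrices with matching columns
kernel_cross <- function(x, y, kernel) {
  x <- as.matrix(x); y <- as.matrix(y)
  switch(kernel$kind,
    rbf = {
      w <- kernel$width
      if (is.null(w)) stop("rbf width unresolved; fit first", call. = FALSE)
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
      exp(-pmax(d2, 0) / (2 * w^2))
    },
    linear = tcrossprod(x, y),
    polynomial = (1 + tcrossprod(x, y))^kernel$degree
  )
}

#' Build a relevance-vector design matrix
#'
#' One row per input point, one kernel column per basis centre, preceded by
#' a constant bias column when the kernel includes one. Features are
#' expected on the scale the kernel was resolved for (the fitter
#' standardizes internally and stores the parameters).
#'
#' @param x Matrix of input points (rows).
#' @param centers Matrix of basis centres (the training exemplars).
#' @param kernel An [rvm_kernel()], with `width` resolved if rbf.
#' @return A `nrow(x)` by `nrow(centers) + include_bias` matrix.
#' @export
rvm_design_matrix <- function(x, centers, kernel) {
  stopifnot(inherits(kernel, "rvm_kernel"))
  K <- kernel_cross(x, centers, kernel)
  if (!all(is.finite(K))) stop("non-finite design matrix entries", call. = FALSE)
  if (kernel$include_bias) K <- cbind(1, K)
  unname(K)
}

#' Posterior over relevance-vector weights
#'
#' Given the Gaussian likelihood with noise variance `sigma2` and
#' independent zero-mean Gaussian weight priors with precisions `alpha`,
#' the weight posterior is Gaussian with covariance
#' `C = (sigma2^-1 Phi'Phi + A)^-1` and mean `mu = sigma2^-1 C Phi' t`,
#' where `A = diag(alpha)`. Computed via a Cholesky factorization with a
#' small diagonal jitter; the jitter is escalated a few times before a
#' numerical error is raised.
#'
#' @param phi Design matrix (N x M).
#' @param targets Response vector (length N).
#' @param alpha Weight precisions (length M, all > 0).
#' @param sigma2 Noise variance (> 0).
#' @param jitter Initial diagonal jitter.
#' @return List with components `mu` (length M) and `C` (M x M).
#' @export
rvm_posterior <- function(phi, targets, alpha, sigma2, jitter = 1e-10) {
  phi <- as.matrix(phi)
  if (length(alpha) != ncol(phi)) stop("length(alpha) != ncol(phi)", call. = FALSE)
  if (any(alpha <= 0)) stop("all alpha must be positive", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  H <- crossprod(phi) / sigma2
  diag(H) <- diag(H) + alpha
  R <- NULL
  jit <- jitter
  for (try in 1:4) {
    R <- tryCatch(chol(H + diag(jit, ncol(H))), error = function(e) NULL)
    if (!is.null(R)) break
    jit <- jit * 1e3
  }
  if (is.null(R)) {
    stop(sprintf(
      "posterior precision matrix not positive definite (M = %d, sigma2 = %.3g, max jitter %.1g)",
      ncol(H), sigma2, jit), call. = FALSE)
  }
  C <- chol2inv(R)
  mu <- drop(C %*% crossprod(phi, targets)) / sigma2
  list(mu = mu, C = C, chol = R)
}

#' One type-II maximum-likelihood hyperparameter update
#'
#' Re-estimates the weight precisions and noise variance from the current
#' posterior: `gamma_i = 1 - alpha_i * C_ii` (the well-determinedness of
#' basis i), `alpha_i_new = gamma_i / mu_i^2`, and
#' `sigma2_new = ||t - Phi mu||^2 / (N - sum(gamma))`. A zero posterior
#' mean sends the corresponding precision to the pruning scale; the
#' variance denominator and the variance itself are floored to keep the
#' iteration defined on degenerate (perfect-fit) instances.
#'
#' @param mu,C Posterior mean and covariance from [rvm_posterior()].
#' @param phi Design matrix used for the posterior.
#' @param targets Response vector.
#' @param alpha Current weight precisions.
#' @param sigma2_floor Lower clamp for the re-estimated noise variance.
#' @return List with `alpha` (new precisions), `sigma2` (new noise
#'   variance), and `gamma`.
#' @export
rvm_hyperparameter_step <- function(mu, C, phi, targets, alpha,
                                    sigma2_floor = 1e-12) {
  gamma <- 1 - alpha * diag(C)
  alpha_new <- ifelse(mu == 0, Inf, pmax(gamma, 0) / mu^2)
  alpha_new[alpha_new <= 0] <- .Machine$double.xmin
  n <- length(targets)
  rss <- sum((targets - drop(as.matrix(phi) %*% mu))^2)
  denom <- max(n - sum(gamma), .Machine$double.eps)
  sigma2_new <- max(rss / denom, sigma2_floor)
  list(alpha = alpha_new, sigma2 = sigma2_new, gamma = gamma)
}

# log marginal likelihood of the active model, using the determinant and
# quadratic-form identities that avoid forming the N x N covariance:
# log|B| = N log s2 - sum(log alpha) + log|H|,  t'B^-1 t = (t'(t - Phi mu))/s2
rvm_log_evidence <- function(phi, targets, alpha, sigma2, post = NULL,
                             jitter = 1e-10) {
  if (is.null(post)) post <- rvm_posterior(phi, targets, alpha, sigma2, jitter)
  n <- length(targets)
  logdetH <- 2 * sum(log(diag(post$chol)))
  logdetB <- n * log(sigma2) - sum(log(alpha)) + logdetH
  quad <- sum(targets * (targets - drop(as.matrix(phi) %*% post$mu))) / sigma2
  -0.5 * (n * log(2 * pi) + logdetB + quad)
}

#' Control parameters for the relevance vector machine fit
#'
#' @param max_iter Maximum number of update iterations.
#' @param tol Convergence tolerance on `max |delta log alpha|` over the
#'   active set.
#' @param alpha_init Initial weight precision for every basis.
#' @param sigma2_init Initial noise variance; `NULL` uses
#'   `0.1 * var(targets)`.
#' @param prune_threshold Bases with `alpha` above this are removed.
#' @param jitter Diagonal jitter for the posterior factorization.
#' @param sigma2_floor Lower clamp on the noise variance.
#' @param evidence_tol Secondary stopping rule: the fit also stops once the
#'   log evidence has moved by less than this for three consecutive
#'   iterations. Late in a fit a doomed basis can take hundreds of
#'   iterations to cross the pruning threshold while the evidence (and
#'   every prediction) is already stationary; the plateau rule ends such
#'   runs without waiting for the precision to diverge.
#' @return An object of class `"rvm_control"`.
#' @export
rvm_control <- function(max_iter = 500L, tol = 1e-3, alpha_init = 1e-4,
                        sigma2_init = NULL, prune_threshold = 1e9,
                        jitter = 1e-10, sigma2_floor = 1e-12,
                        evidence_tol = 1e-8) {
  stopifnot(max_iter >= 1, tol > 0, alpha_init > 0, prune_threshold > 0,
            jitter >= 0, sigma2_floor > 0, evidence_tol >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 alpha_init = alpha_init, sigma2_init = sigma2_init,
                 prune_threshold = prune_threshold, jitter = jitter,
                 sigma2_floor = sigma2_floor, evidence_tol = evidence_tol),
            class = "rvm_control")
}

#' Relevance vector machine regression
#'
#' Sparse Bayesian kernel regression. Each training exemplar contributes a
#' kernel basis function (plus an optional bias); independent zero-mean
#' Gaussian priors with per-basis precisions `alpha_i` are placed on the
#' weights, and the hyperparameters `(alpha, sigma2)` are estimated by
#' type-II maximum likelihood: the fit alternates the exact Gaussian weight
#' posterior with the fixed-point re-estimates
#' `alpha_i <- gamma_i / mu_i^2` and
#' `sigma2 <- ||t - Phi mu||^2 / (N - sum gamma)`, pruning bases whose
#' precision diverges. Most precisions diverge, so the surviving basis
#' centres — the relevance vectors — form a sparse model. The fit is a
#' deterministic function of the data, kernel and control settings.
#'
#' @param x For the default method, a numeric matrix (or data frame) of
#'   features, one row per exemplar; for the formula method, a model
#'   formula such as `cbgm ~ g_add + v_u`.
#' @param y Response vector (default method).
#' @param kernel An [rvm_kernel()].
#' @param control An [rvm_control()].
#' @param data Data frame for the formula method.
#' @param ... Passed between methods.
#' @return An object of class `"rvm"`: a list with the posterior mean `mu`
#'   and covariance `C` over the active bases, precisions `alpha`, noise
#'   variance `sigma2`, the relevance vectors, the standardization
#'   parameters, a per-iteration `convergence_log` (noise variance, active
#'   count, max log-alpha change, log evidence), and the usual
#'   `fitted.values` / `residuals`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @export
#' @examples
#' cfg <- titration_config(n_batches = 60, basal_glucose = 80, seed = 7)
#' d <- generate_titration(cfg)
#' fit <- rvm(cbgm ~ g_add + v_u, data = d)
#' fit
#' predict(fit, d[1:3, ])
rvm <- function(x, ...) UseMethod("rvm")

#' @rdname rvm
#' @export
rvm.formula <- function(x, data, kernel = rvm_kernel(),
                        control = rvm_control(), ...) {
  mf <- stats::model.frame(x, data)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(tt, mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  fit <- rvm.default(mm, y, kernel = kernel, control = control)
  fit$terms <- tt
  fit$formula <- x
  fit$call <- match.call()
  fit
}

#' @rdname rvm
#' @export
rvm.default <- function(x, y, kernel = rvm_kernel(),
                        control = rvm_control(), ...) {
  stopifnot(inherits(kernel, "rvm_kernel"), inherits(control, "rvm_control"))
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 5L) stop("need at least 5 training exemplars", call. = FALSE)
  if (length(y) != n) stop("length(y) != nrow(x)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in training data", call. = FALSE)

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  if (kernel$kind == "rbf" && is.null(kernel$width)) {
    dd <- stats::dist(Xs)
    w <- stats::median(dd[dd > 0])
    if (!is.finite(w) || w <= 0) w <- 1
    kernel$width <- w
  }

  phi_full <- rvm_design_matrix(Xs, Xs, kernel)
  m_full <- ncol(phi_full)
  # basis 0 is the bias (when present); bases 1..N are the exemplar kernels
  basis_id <- if (kernel$include_bias) 0:n else 1:n

  active <- seq_len(m_full)
  alpha <- rep(control$alpha_init, m_full)
  sigma2 <- if (is.null(control$sigma2_init)) {
    max(0.1 * stats::var(y), control$sigma2_floor)
  } else control$sigma2_init

  log_ev <- numeric(0)
  trace_sigma2 <- numeric(0)
  trace_active <- integer(0)
  trace_delta <- numeric(0)
  converged <- FALSE
  post <- NULL
  gamma <- rep(NA_real_, length(active))

  for (it in seq_len(control$max_iter)) {
    phi <- phi_full[, active, drop = FALSE]
    post <- rvm_posterior(phi, y, alpha, sigma2, control$jitter)
    log_ev <- c(log_ev, rvm_log_evidence(phi, y, alpha, sigma2, post))
    upd <- rvm_hyperparameter_step(post$mu, post$C, phi, y, alpha,
                                   control$sigma2_floor)
    gamma <- upd$gamma
    keep <- upd$alpha <= control$prune_threshold
    if (!any(keep)) {
      stop(paste("all basis functions pruned; try a larger kernel width",
                 "or a larger prune_threshold"), call. = FALSE)
    }
    # watch the noise variance too: near noise-free data the precisions
    # settle while sigma2 is still falling toward its floor
    delta <- max(abs(log(upd$alpha[keep]) - log(alpha[keep])),
                 abs(log(upd$sigma2) - log(sigma2)))
    trace_sigma2 <- c(trace_sigma2, upd$sigma2)
    trace_active <- c(trace_active, sum(keep))
    trace_delta <- c(trace_delta, delta)
    alpha <- upd$alpha[keep]
    sigma2 <- upd$sigma2
    active <- active[keep]
    gamma <- gamma[keep]
    if (delta < control$tol) { converged <- TRUE; break }
    k <- length(log_ev)
    if (k >= 4 &&
        all(abs(diff(log_ev[(k - 3):k])) < control$evidence_tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("relevance vector machine did not converge in ",
            control$max_iter, " iterations", call. = FALSE)
  }

  phi <- phi_full[, active, drop = FALSE]
  post <- rvm_posterior(phi, y, alpha, sigma2, control$jitter)
  gamma <- 1 - alpha * diag(post$C)
  fitted <- drop(phi %*% post$mu)

  active_id <- basis_id[active]
  rv_index <- active_id[active_id > 0L]
  out <- structure(list(
    call = match.call(),
    kernel = kernel,
    control = control,
    center = ctr, scale = scl,
    feature_names = colnames(X),
    x_std = Xs, y = y, nobs = n,
    active = active_id,
    relevance_index = rv_index,
    relevance_vectors = Xs[rv_index, , drop = FALSE],
    mu = post$mu, C = post$C,
    alpha = alpha, gamma = gamma, sigma2 = sigma2,
    convergence_log = data.frame(
      iteration = seq_along(log_ev), sigma2 = trace_sigma2,
      n_active = trace_active, max_dlogalpha = trace_delta,
      log_evidence = log_ev),
    iterations = length(log_ev),
    converged = converged,
    fitted.values = fitted,
    residuals = y - fitted,
    terms = NULL, formula = NULL
  ), class = "rvm")
  out
}

#' Prune weakly supported basis functions from a fitted model
#'
#' Removes bases whose weight precision exceeds `threshold` (their
#' posterior weight is pinned at zero) and recomputes the posterior,
#' fitted values and residuals on the survivors.
#'
#' @param object A fitted [rvm()] model.
#' @param threshold Precision above which a basis is dropped.
#' @return The pruned `"rvm"` model.
#' @export
rvm_prune <- function(object, threshold = object$control$prune_threshold) {
  stopifnot(inherits(object, "rvm"))
  keep <- object$alpha <= threshold
  if (!any(keep)) {
    stop(paste("pruning would remove every basis; try a larger kernel width",
               "or a larger threshold"), call. = FALSE)
  }
  if (all(keep)) return(object)
  object$active <- object$active[keep]
  object$alpha <- object$alpha[keep]
  object$gamma <- object$gamma[keep]
  object$relevance_index <- object$active[object$active > 0L]
  object$relevance_vectors <-
    object$x_std[object$relevance_index, , drop = FALSE]
  phi <- design_for(object, object$x_std, standardized = TRUE)
  post <- rvm_posterior(phi, object$y, object$alpha, object$sigma2,
                        object$control$jitter)
  object$mu <- post$mu
  object$C <- post$C
  object$fitted.values <- drop(phi %*% post$mu)
  object$residuals <- object$y - object$fitted.values
  object
}

# design matrix over the model's active bases for arbitrary inputs
design_for <- function(object, x, standardized = FALSE) {
  X <- as.matrix(x)
  if (!standardized) {
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  }
  K <- kernel_cross(X, object$x_std[object$relevance_index, , drop = FALSE],
                    object$kernel)
  if (0L %in% object$active) K <- cbind(1, K)
  unname(K)
}
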