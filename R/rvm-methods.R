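#' @export
print.rvm <- function(x, ...) {
  cat("Relevance vector machine regression\n")
  if (!is.null(x$formula)) cat("  formula:", deparse(x$formula), "\n")
  cat("  kernel: "); print(x$kernel)
  cat(sprintf("  %d training exemplars, %d active bases (%d relevance vectors%s)\n",
              x$nobs, length(x$active), length(x$relevance_index),
              if (0L %in% x$active) " + bias" else ""))
  cat(sprintf("  noise SD: %.4g, iterations: %d%s\n",
              sqrt(x$sigma2), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.rvm <- function(object, ...) {
  structure(list(
    call = object$call,
    formula = object$formula,
    kernel = object$kernel,
    nobs = object$nobs,
    n_active = length(object$active),
    n_relevance = length(object$relevance_index),
    has_bias = 0L %in% object$active,
    sigma2 = object$sigma2,
    iterations = object$iterations,
    converged = object$converged,
    log_evidence = utils::tail(object$convergence_log$log_evidence, 1L),
    residual_summary = summary(object$residuals),
    rmse = sqrt(mean(object$residuals^2))
  ), class = "summary.rvm")
}

#' @export
print.summary.rvm <- function(x, ...) {
  cat("Relevance vector machine regression\n")
  if (!is.null(x$formula)) cat("Formula:", deparse(x$formula), "\n")
  cat("Kernel: "); print(x$kernel)
  cat(sprintf("Exemplars: %d   relevance vectors: %d%s   sparsity: %.1f%%\n",
              x$nobs, x$n_relevance, if (x$has_bias) " (+ bias)" else "",
              100 * x$n_relevance / x$nobs))
  cat(sprintf("Noise variance sigma^2: %.6g (SD %.4g)\n", x$sigma2, sqrt(x$sigma2)))
  cat(sprintf("Log evidence: %.4f after %d iterations%s\n",
              x$log_evidence, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("Training RMSE: %.4g\n", x$rmse))
  cat("Residuals:\n"); print(x$residual_summary)
  invisible(x)
}

#' @export
coef.rvm <- function(object, ...) {
  cf <- object$mu
  names(cf) <- ifelse(object$active == 0L, "(bias)",
                      paste0("rv", object$active))
  cf
}

#' Predict glucose from a fitted relevance vector machine
#'
#' The predictive distribution at a new point `z` is Gaussian with mean
#' `mu' phi(z)` and variance `sigma2 + phi(z)' C phi(z)`: the converged
#' noise variance plus the weight-uncertainty term, so the predictive
#' variance is never below `sigma2`.
#'
#' @param object A fitted [rvm()] model.
#' @param newdata Data frame (formula fits) or feature matrix. Omitted:
#'   training fitted values are returned.
#' @param se.fit Also return predictive standard errors and variances.
#' @param ... Unused.
#' @return Numeric vector of predictive means, or when `se.fit = TRUE` a
#'   list with `fit`, `se.fit` and `variance`.
#' @export
predict.rvm <- function(object, newdata, se.fit = FALSE, ...) {
  if (missing(newdata) || is.null(newdata)) {
    X <- object$x_std
    phi <- design_for(object, X, standardized = TRUE)
  } else {
    if (is.data.frame(newdata)) {
      if (!is.null(object$terms)) {
        tt <- stats::delete.response(object$terms)
        mf <- stats::model.frame(tt, newdata)
        X <- stats::model.matrix(tt, mf)
        X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
      } else {
        miss <- setdiff(object$feature_names, names(newdata))
        if (length(miss)) {
          stop("newdata is missing feature(s): ",
               paste(miss, collapse = ", "), call. = FALSE)
        }
        X <- as.matrix(newdata[object$feature_names])
      }
    } else {
      X <- as.matrix(newdata)
      if (ncol(X) != length(object$center)) {
        stop(sprintf("newdata has %d feature(s); model expects %d",
                     ncol(X), length(object$center)), call. = FALSE)
      }
    }
    phi <- design_for(object, X)
  }
  mean <- drop(phi %*% object$mu)
  if (!se.fit) return(mean)
  wvar <- rowSums((phi %*% object$C) * phi)
  variance <- object$sigma2 + pmax(wvar, 0)
  list(fit = mean, se.fit = sqrt(variance), variance = variance)
}

#' @export
residuals.rvm <- function(object, ...) object$residuals

#' @export
fitted.rvm <- function(object, ...) object$fitted.values

#' Simulate responses from the predictive distribution
#'
#' @param object A fitted [rvm()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newdata Points to simulate at; training inputs by default.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of draws from the per-point
#'   Gaussian predictive distributions.
#' @export
simulate.rvm <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- if (is.null(newdata)) predict(object, se.fit = TRUE)
        else predict(object, newdata, se.fit = TRUE)
  n <- length(pr$fit)
  out <- as.data.frame(replicate(nsim, stats::rnorm(n, pr$fit, pr$se.fit),
                                 simplify = FALSE),
                       col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.rvm <- function(x, which = c("fit", "evidence"), ...) {
  which <- match.arg(which)
  if (which == "evidence") {
    graphics::plot(x$convergence_log$iteration, x$convergence_log$log_evidence,
                   type = "l", xlab = "iteration", ylab = "log evidence",
                   main = "RVM evidence trace", ...)
    return(invisible(x))
  }
  graphics::plot(x$y, x$fitted.values,
                 xlab = "observed response", ylab = "fitted response",
                 main = "RVM fit", ...)
  graphics::abline(0, 1, lty = 2)
  rv_y <- x$y[x$relevance_index]
  rv_f <- x$fitted.values[x$relevance_index]
  graphics::points(rv_y, rv_f, pch = 19, col = "red3")
  graphics::legend("topleft", legend = c("exemplar", "relevance vector"),
                   pch = c(1, 19), col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Save and restore a fitted relevance vector machine as JSON
#'
#' Persists everything prediction needs: the kernel specification,
#' standardization parameters, active basis identities, the retained
#' (standardized) relevance vectors, posterior mean and covariance,
#' precisions and noise variance. The restored model predicts identically
#' but drops the training data and convergence trace.
#'
#' @param object A fitted [rvm()] model.
#' @param path File path for the JSON document.
#' @return `write_rvm()` returns `path` invisibly; `read_rvm()` a model of
#'   class `"rvm"` usable with [predict.rvm()].
#' @export
write_rvm <- function(object, path) {
  stopifnot(inherits(object, "rvm"))
  doc <- list(
    type = "glucalib_rvm", version = 1L,
    kernel = object$kernel[c("kind", "width", "degree", "include_bias")],
    formula = if (is.null(object$formula)) NULL else deparse(object$formula),
    feature_names = object$feature_names,
    center = as.numeric(object$center), scale = as.numeric(object$scale),
    nobs = object$nobs,
    active = as.integer(object$active),
    relevance_vectors = unname(as.matrix(object$relevance_vectors)),
    mu = as.numeric(object$mu),
    C = unname(as.matrix(object$C)),
    alpha = as.numeric(object$alpha),
    sigma2 = object$sigma2,
    converged = object$converged
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rvm
#' @export
read_rvm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "glucalib_rvm")) {
    stop("not a serialized rvm model: ", path, call. = FALSE)
  }
  kernel <- rvm_kernel(doc$kernel$kind,
                       width = doc$kernel$width,
                       degree = if (is.null(doc$kernel$degree)) 2L else doc$kernel$degree,
                       include_bias = doc$kernel$include_bias)
  rv <- matrix(as.numeric(doc$relevance_vectors),
               nrow = length(doc$active[doc$active > 0]),
               ncol = length(doc$center))
  active <- as.integer(doc$active)
  rv_index <- seq_len(nrow(rv))  # re-indexed: stored vectors are the survivors
  C <- matrix(as.numeric(doc$C), nrow = length(doc$mu))
  obj <- structure(list(
    call = NULL, kernel = kernel, control = rvm_control(),
    center = as.numeric(doc$center), scale = as.numeric(doc$scale),
    feature_names = doc$feature_names,
    x_std = rv, y = NULL, nobs = doc$nobs,
    active = active,
    relevance_index = rv_index,
    relevance_vectors = rv,
    mu = as.numeric(doc$mu), C = C,
    alpha = as.numeric(doc$alpha), gamma = NULL,
    sigma2 = doc$sigma2,
    convergence_log = NULL, iterations = NA_integer_,
    converged = isTRUE(doc$converged),
    fitted.values = NULL, residuals = NULL,
    terms = NULL,
    formula = if (is.null(doc$formula)) NULL else stats::as.formula(doc$formula)
  ), class = "rvm")
  if (!is.null(obj$formula)) {
    obj$terms <- stats::terms(obj$formula)
  }
  obj
}
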