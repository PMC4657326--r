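# Classifiers: 20-predictor logistic regression and a 20->10->1
# feed-forward neural network.  Both fit on internally z-scored predictors
# and report coefficients/weights on the original scale where applicable.

#' Fit the 20-predictor logistic regression
#'
#' Maximum-likelihood logistic regression of a binary label on the
#' 20-vector encoding, P(y = 1) = 1 / (1 + exp(-(b0 + sum b_i x_i))).
#' Columns are standardized internally (coefficients mapped back), constant
#' columns get coefficient 0 with a warning, and complete separation
#' (non-convergence / diverging coefficient norm) triggers an automatic
#' ridge refit with lambda = 1e-4 and a notice.
#'
#' @param X n x 20 numeric matrix.
#' @param y binary 0/1 labels, length n.
#' @param lambda L2 penalty on the standardized non-intercept coefficients
#'   (0 = plain MLE).
#' @param sign_convention `"standard"` stores coefficients for the usual
#'   sigmoid P = 1/(1+e^(-eta)); `"paper"` stores the negated coefficients
#'   of the positive-exponent form P = 1/(1+e^(+eta)). Predictions are
#'   identical.
#' @return A `logistic_model`: list with `b` (21 named coefficients
#'   b0..b20 on the original scale), `se` (standard errors, NA under
#'   ridge), `lambda`, `sign_convention`, `converged`.
#' @export
fit_logistic <- function(X, y, lambda = 0,
                         sign_convention = c("standard", "paper")) {
  sign_convention <- match.arg(sign_convention)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains NA or non-finite values")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  n <- nrow(X); p <- ncol(X)
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0 && n < p + 1L)
    stop(sprintf("n = %d < %d predictors + intercept: use lambda > 0", n, p))
  sds <- apply(X, 2, stats::sd)
  mus <- colMeans(X)
  keep <- sds > 0
  if (!all(keep) && lambda == 0)
    warning(sprintf("constant column(s) %s: coefficient fixed at 0",
                    paste(colnames(X)[!keep], collapse = ",")),
            call. = FALSE)
  Z <- scale(X[, keep, drop = FALSE])
  beta <- stats::setNames(numeric(p + 1L),
                          c("b0", colnames(X)))
  se <- rep(NA_real_, p + 1L)
  converged <- TRUE
  if (length(y) && all(y == y[1L])) {
    # single-class data: intercept-only Bernoulli MLE (degenerate +-Inf);
    # callers wanting the prevalence model should use lambda > 0 or this.
    beta["b0"] <- if (y[1L] == 1L) Inf else -Inf
    model <- structure(list(b = beta, se = se, lambda = lambda,
                            sign_convention = sign_convention,
                            converged = TRUE, scale = list(mu = mus, sd = sds)),
                       class = "logistic_model")
    return(model)
  }
  fit_ridge <- function(lam) ridge_logistic(Z, y, lam)
  if (lambda == 0) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, Z), y,
                     family = stats::binomial()))
    z_coef <- fit$coefficients
    mu <- fit$fitted.values
    # complete separation: diverging coefficients, or a perfect fit with
    # every fitted probability numerically at its label
    separated <- !fit$converged || any(!is.finite(z_coef)) ||
      max(abs(z_coef), na.rm = TRUE) > 30 ||
      all(abs(y - mu) < 1e-5)
    if (separated) {
      message("complete separation detected: refitting with lambda = 1e-4")
      lambda <- 1e-4
      z_coef <- fit_ridge(lambda)
      converged <- TRUE
    } else {
      # standard errors on the original scale via the delta method
      W <- fit$weights
      XtWX <- crossprod(cbind(1, Z) * sqrt(W))
      V <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (!is.null(V)) {
        se_z <- sqrt(diag(V))
        se[1L] <- NA_real_  # intercept SE on original scale not propagated
        se[c(FALSE, keep)] <- se_z[-1L] / sds[keep]
      }
      converged <- fit$converged
    }
  } else {
    z_coef <- fit_ridge(lambda)
  }
  z_coef[is.na(z_coef)] <- 0
  bk <- z_coef[-1L] / sds[keep]
  beta[c(FALSE, keep)] <- bk
  beta["b0"] <- z_coef[1L] - sum(bk * mus[keep])
  if (sign_convention == "paper") beta <- -beta
  structure(list(b = beta, se = se, lambda = lambda,
                 sign_convention = sign_convention, converged = converged,
                 scale = list(mu = mus, sd = sds)),
            class = "logistic_model")
}

# Newton/IRLS for L2-penalized logistic regression on standardized
# predictors; the intercept is unpenalized.  Returns (intercept, coefs).
ridge_logistic <- function(Z, y, lambda, max_iter = 500L, tol = 1e-8) {
  A <- cbind(1, Z)
  p <- ncol(A)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(A %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(A, y - mu)) - drop(pen %*% beta)
    if (sqrt(sum(grad^2)) < tol) break
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(A * sqrt(W)) + pen
    step <- solve(H, grad)
    beta <- beta + step
  }
  beta
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> lambda = %g, convention = %s, converged = %s\n",
              x$lambda, x$sign_convention, x$converged))
  print(round(x$b, 4))
  invisible(x)
}

#' Predict crystallization probability from a logistic model
#'
#' @param model a [fit_logistic()] result.
#' @param x a 20-vector or n x 20 matrix of predictors.
#' @return Probability (or vector of probabilities) in \[0, 1\].
#' @export
predict_logistic <- function(model, x) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  eta <- model$b[["b0"]] + drop(as.matrix(x) %*% model$b[-1L])
  if (model$sign_convention == "paper") eta <- -eta
  stats::plogis(eta)
}

#' Fit the 20->10->1 neural network
#'
#' Single-hidden-layer feed-forward network with 10 hidden units and one
#' sigmoid output, trained on cross-entropy via `nnet::nnet` with an
#' explicit seeded uniform(-0.5, 0.5) weight initialization, so the fit is
#' deterministic given (X, y, seed, config). Predictors are z-scored
#' internally.
#'
#' @param X n x 20 numeric matrix.
#' @param y binary 0/1 labels; both classes must be present.
#' @param seed integer seed for the weight initialization.
#' @param config list: `max_epochs` (default 500), `tol` (`abstol`,
#'   default 1e-6), `decay` (L2 weight decay, default 0), `hidden`
#'   (default 10).
#' @return A `nn_model` wrapping the fitted `nnet` object plus the seed,
#'   config and scaling.
#' @export
fit_nn <- function(X, y, seed = 1L, config = list()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (anyNA(X)) stop("X contains NA")
  if (length(unique(y)) < 2L)
    stop("single-class y: fit a prevalence model instead")
  cfg <- utils::modifyList(
    list(max_epochs = 500L, tol = 1e-6, decay = 0, hidden = 10L), config)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  mus <- colMeans(X)
  Z <- sweep(sweep(X, 2, mus), 2, sds, "/")
  nw <- (ncol(Z) + 1L) * cfg$hidden + (cfg$hidden + 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  wts <- stats::runif(nw, -0.5, 0.5)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  fit <- nnet::nnet(Z, y, size = cfg$hidden, entropy = TRUE,
                    Wts = wts, decay = cfg$decay, maxit = cfg$max_epochs,
                    abstol = cfg$tol, trace = FALSE, MaxNWts = 5000L)
  structure(list(fit = fit, seed = seed, config = cfg,
                 scale = list(mu = mus, sd = sds)),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %d-%d-1 network, seed = %d, final loss = %.6g\n",
              length(x$scale$mu), x$config$hidden, x$seed, x$fit$value))
  invisible(x)
}

#' Predict crystallization probability from a neural-network model
#'
#' @param model a [fit_nn()] result.
#' @param x a 20-vector or n x 20 matrix.
#' @return Probability (or vector) in \[0, 1\].
#' @export
predict_nn <- function(model, x) {
  stopifnot(inherits(model, "nn_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  Z <- sweep(sweep(as.matrix(x), 2, model$scale$mu), 2, model$scale$sd, "/")
  drop(stats::predict(model$fit, Z))
}

#' Generic probability prediction
#'
#' Dispatches to [predict_logistic()] or [predict_nn()].
#'
#' @param model a `logistic_model` or `nn_model`.
#' @param x predictors.
#' @return Probabilities in \[0, 1\].
#' @export
predict_prob <- function(model, x) {
  if (inherits(model, "logistic_model")) predict_logistic(model, x)
  else if (inherits(model, "nn_model")) predict_nn(model, x)
  else stop("unknown model class")
}

#' Fit either classifier by name
#'
#' @param X n x 20 matrix.
#' @param y binary labels.
#' @param model_kind `"logistic"` or `"nn"`.
#' @param seed seed (used by the neural network).
#' @param ... passed on to the fitter.
#' @return Fitted model.
#' @export
fit_model <- function(X, y, model_kind = c("logistic", "nn"), seed = 1L,
                      ...) {
  model_kind <- match.arg(model_kind)
  switch(model_kind,
         logistic = fit_logistic(X, y, ...),
         nn = fit_nn(X, y, seed = seed, ...))
}

#' Threshold a probability into a class
#'
#' Ties at the threshold go to the positive class (1 iff p >= threshold).
#'
#' @param p probability (vector allowed) in \[0, 1\].
#' @param threshold decision threshold, default 0.5.
#' @return Integer 0/1 of the same length.
#' @export
classify <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  as.integer(p >= threshold)
}

#' Serialize a fitted model to JSON
#'
#' Flat text serialization (coefficients or weights, seed, config) for
#' jackknife reproducibility audits.
#'
#' @param model a `logistic_model` or `nn_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
serialize_model <- function(model, path) {
  obj <- if (inherits(model, "logistic_model")) {
    list(kind = "logistic", b = as.list(model$b), lambda = model$lambda,
         sign_convention = model$sign_convention)
  } else if (inherits(model, "nn_model")) {
    list(kind = "nn", wts = model$fit$wts, seed = model$seed,
         config = model$config,
         scale = list(mu = as.list(model$scale$mu),
                      sd = as.list(model$scale$sd)))
  } else stop("unknown model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
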