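#' Build the propensity feature matrix for user chat sessions
#'
#' One-hot topic (14 columns) and device (3 columns) indicators plus the
#' initial emotional intensity of the struggle on the emotion's reporting
#' scale. Exactly one topic and one device indicator are set per row.
#'
#' @param topic,device Character vectors over [chat_topics] / [chat_devices].
#' @param intensity Numeric struggle intensity on the reporting scale.
#' @return Numeric matrix with named columns `topic.*`, `device.*`,
#'   `intensity`.
#' @export
session_features <- function(topic, device, intensity) {
  if (any(!topic %in% chat_topics) || any(!device %in% chat_devices)) {
    ptr_error("unknown topic or device", "ptr_validation_error")
  }
  tmat <- outer(topic, chat_topics, `==`) * 1
  dmat <- outer(device, chat_devices, `==`) * 1
  colnames(tmat) <- paste0("topic.", gsub(" ", "_", chat_topics))
  colnames(dmat) <- paste0("device.", chat_devices)
  cbind(tmat, dmat, intensity = as.numeric(intensity))
}

#' Fit a ridge-stabilized logistic propensity model
#'
#' Maximizes the binomial log-likelihood with a small L2 penalty
#' (`lambda/2 * sum(beta^2)`, intercept included) by Newton iterations with
#' step halving. The penalty (default 1e-6) keeps the optimum finite even
#' under perfect separation or collinear one-hot blocks while perturbing the
#' maximum-likelihood solution negligibly. Feature columns that are constant
#' across rows are dropped with a warning. Convergence requires the
#' penalized gradient's max norm to fall to `tol`.
#'
#' @param x Feature matrix (rows = sessions), e.g. [session_features()].
#' @param y 0/1 labels (1 = group cohort) with at least one of each.
#' @param lambda Ridge penalty (default 1e-6).
#' @param tol Gradient max-norm convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `propensity_model`: list with `coefficients`
#'   (intercept first), `kept` (retained column names), `lambda`,
#'   `iterations`, `converged`.
#' @export
fit_propensity <- function(x, y, lambda = 1e-6, tol = 1e-8,
                           max_iter = 200L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2L || !all(y %in% c(0, 1))) {
    ptr_error("labels must contain both classes, coded 0/1",
              "ptr_validation_error")
  }
  if (nrow(x) != length(y)) {
    ptr_error("x and y sizes differ", "ptr_validation_error")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  kept <- colnames(x)
  X <- cbind(`(intercept)` = 1, x)
  p_dim <- ncol(X)
  beta <- numeric(p_dim)

  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - lambda / 2 * sum(b^2)
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - lambda * beta
    if (max(abs(g)) <= tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(lambda, p_dim)
    step <- solve(H, g)
    sz <- 1
    repeat {
      cand <- beta + sz * step
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) break
    }
    beta <- beta + sz * step
    ll_old <- pen_ll(beta)
  }
  if (!converged) {
    # final gradient check (tolerance may be reached on the last iteration)
    eta <- drop(X %*% beta)
    g <- drop(crossprod(X, y - stats::plogis(eta))) - lambda * beta
    converged <- max(abs(g)) <= tol
    if (!converged) {
      ptr_error(sprintf(
        "propensity fit did not converge in %d iterations (max |gradient| = %.3g)",
        max_iter, max(abs(g))), "ptr_fit_error")
    }
  }
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    kept = kept,
    lambda = lambda,
    iterations = iter,
    converged = converged
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d coefficients, lambda = %g, %d iterations\n",
              length(x$coefficients), x$lambda, x$iterations))
  invisible(x)
}

#' Propensity scores for sessions
#'
#' @param model A [fit_propensity()] model.
#' @param x Feature matrix with (at least) the columns the model kept.
#' @return Propensities strictly in (0, 1).
#' @export
predict_propensity <- function(model, x) {
  stopifnot(inherits(model, "propensity_model"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  miss <- setdiff(model$kept, colnames(x))
  if (length(miss)) {
    ptr_error(paste0("feature matrix is missing column(s): ",
                     paste(miss, collapse = ", ")), "ptr_validation_error")
  }
  eta <- drop(cbind(1, x[, model$kept, drop = FALSE]) %*% model$coefficients)
  p <- stats::plogis(eta)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}
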