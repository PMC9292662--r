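## Internal numerical helpers shared across modules.

#' @keywords internal
.invlogit <- function(x) stats::plogis(x)

## log(exp(x) + exp(y)) without overflow; x, y may be -Inf
#' @keywords internal
.logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log(exp(x - m) + exp(y - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' @keywords internal
.stopCondition <- function(class, message, call. = FALSE) {
  stop(structure(
    class = c(class, "ddiError", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

## Deterministic substream seed derivation. Keeps every derived seed inside
## 32-bit integer range and prefix-stable in `index` so element i of a stream
## does not depend on how many elements are drawn in total.
#' @keywords internal
.deriveSeed <- function(seed, stream, index = 0L) {
  m <- 2147483629
  base <- (as.numeric(seed) %% m) * 11117 + as.numeric(stream) * 2003
  as.integer((base + as.numeric(index) * 7919) %% m)
}

## Weighted-least-squares IRLS for a binary logistic model. Coefficients agree
## with stats::glm.fit to optimizer precision but the loop avoids the QR
## decomposition per iteration, which matters when thousands of n=1e5 fits are
## run in the simulation benchmark.
#' @keywords internal
.irlsLogistic <- function(X, y, maxit = 100L, tol = 1e-8, ridge = 0) {
  p <- ncol(X)
  beta <- numeric(p)
  ybar <- min(max(mean(y), 1e-9), 1 - 1e-9)
  beta[1L] <- stats::qlogis(ybar)
  ll_old <- -Inf
  converged <- FALSE
  penalty <- diag(ridge, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    upd <- tryCatch(
      solve(crossprod(X, X * w) + penalty, crossprod(X, w * z)),
      error = function(e) NULL
    )
    if (is.null(upd) || any(!is.finite(upd))) {
      return(list(coefficients = beta, converged = FALSE,
                  logLik = ll_old, iterations = it, singular = TRUE))
    }
    beta <- drop(upd)
    ll <- sum(stats::dbinom(y, 1L, stats::plogis(drop(X %*% beta)), log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(coefficients = beta, converged = converged, logLik = ll_old,
       iterations = it, singular = FALSE)
}
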