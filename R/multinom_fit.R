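# Baseline-category multinomial logistic regression by Newton-Raphson.
# Counts may be real-valued (they enter the likelihood as weights).
# Y: samples x sites (column 1 = reference/baseline); X: samples x p.
fit_multinom_logit <- function(Y, X, tol = 1e-10, maxit = 100L, beta_cap = 15) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  K <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  stopifnot(nrow(X) == K, S >= 2L)
  n <- rowSums(Y)
  B <- matrix(0, p, S - 1L)
  npar <- p * (S - 1L)

  loglik <- function(B) {
    eta <- X %*% B
    # log p_s with baseline: log-denominator via stable log-sum-exp
    mx <- pmax(0, apply(eta, 1L, max))
    lden <- mx + log(exp(-mx) + rowSums(exp(eta - mx)))
    sum(Y[, -1L, drop = FALSE] * eta) - sum(n * lden)
  }

  probs <- function(B) {
    eta <- X %*% B
    mx <- pmax(0, apply(eta, 1L, max))
    den <- exp(-mx) + rowSums(exp(eta - mx))
    cbind(exp(-mx) / den, exp(eta - mx) / den)
  }

  ll <- loglik(B)
  converged <- FALSE
  separated <- FALSE
  H <- NULL
  for (it in seq_len(maxit)) {
    P <- probs(B)
    g <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (s in 2:S) {
      ix <- ((s - 2L) * p + 1L):((s - 1L) * p)
      g[ix] <- crossprod(X, Y[, s] - n * P[, s])
      for (t2 in 2:S) {
        iy <- ((t2 - 2L) * p + 1L):((t2 - 1L) * p)
        w <- n * P[, s] * ((s == t2) - P[, t2])
        H[ix, iy] <- crossprod(X, X * w)
      }
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    newB <- B + matrix(step, p, S - 1L)
    newll <- loglik(newB)
    halv <- 0L
    while ((!is.finite(newll) || newll < ll - 1e-12) && halv < 30L) {
      step <- step / 2
      newB <- B + matrix(step, p, S - 1L)
      newll <- loglik(newB)
      halv <- halv + 1L
    }
    delta <- max(abs(newB - B))
    B <- newB; ll <- newll
    if (max(abs(B)) > beta_cap) { separated <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  P <- probs(B)
  # observed-information covariance at the optimum
  H <- matrix(0, npar, npar)
  for (s in 2:S) {
    ix <- ((s - 2L) * p + 1L):((s - 1L) * p)
    for (t2 in 2:S) {
      iy <- ((t2 - 2L) * p + 1L):((t2 - 1L) * p)
      w <- n * P[, s] * ((s == t2) - P[, t2])
      H[ix, iy] <- crossprod(X, X * w)
    }
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  dimnames(B) <- list(colnames(X), colnames(Y)[-1L])
  list(coef = B, vcov = V, loglik = ll, converged = converged,
       separated = separated, niter = it, fitted = P)
}
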