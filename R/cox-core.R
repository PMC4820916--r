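# Cox partial-likelihood engine (Efron ties), written against the linear
# predictor eta so the same derivatives serve the fixed-effect Newton step
# and the joint (beta, frailty) step.
#
# For event time t_k with tied death set D_k (size d_k) and risk set R_k,
# Efron's approximation contributes, for l = 0..d_k-1,
#   denom_kl = S_k - (l/d_k) s_k,  S_k = sum_{R_k} exp(eta),
#   s_k = sum_{D_k} exp(eta),
# with per-subject shares pi^kl_i = exp(eta_i) (1 - (l/d_k)[i in D_k]) /
# denom_kl. Collecting the shares in a matrix P (one row per (k, l)):
#   loglik   = sum_k [ sum_{D_k} eta - sum_l log denom_kl ]
#   score    = status - colSums(P)
#   -Hessian = diag(colSums(P)) - t(P) %*% P   (in eta)

cox_eta_derivs <- function(time, status, eta, strata = NULL,
                           need_P = TRUE) {
  n <- length(time)
  strata <- if (is.null(strata)) rep(1L, n) else as.integer(factor(strata))
  eta <- eta - mean(eta) # stabilizes exp(); partial likelihood is invariant
  r <- exp(eta)
  loglik <- 0
  dvec <- numeric(n)
  P_rows <- list()
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ts <- time[idx]; st <- status[idx]; rs <- r[idx]; es <- eta[idx]
    o <- order(ts)
    ts <- ts[o]; st <- st[o]; rs <- rs[o]; es <- es[o]
    sub <- idx[o]
    revcum <- rev(cumsum(rev(rs)))
    ev_times <- unique(ts[st == 1])
    for (tk in ev_times) {
      first <- match(TRUE, ts >= tk)
      Dk <- which(ts == tk & st == 1)
      dk <- length(Dk)
      Sk <- revcum[first]
      sk <- sum(rs[Dk])
      risk <- first:length(ts)
      loglik <- loglik + sum(es[Dk])
      for (l in seq_len(dk) - 1L) {
        denom <- Sk - (l / dk) * sk
        loglik <- loglik - log(denom)
        if (need_P) {
          v <- numeric(n)
          v[sub[risk]] <- rs[risk] / denom
          if (l > 0) v[sub[Dk]] <- v[sub[Dk]] - (l / dk) * rs[Dk] / denom
          P_rows[[length(P_rows) + 1L]] <- v
        } else {
          v <- numeric(length(ts))
          v[risk] <- rs[risk] / denom
          if (l > 0) v[Dk] <- v[Dk] - (l / dk) * rs[Dk] / denom
          dvec[sub] <- dvec[sub] + v
        }
      }
    }
  }
  if (need_P) {
    P <- if (length(P_rows) > 0) do.call(rbind, P_rows) else
      matrix(0, 0, n)
    dvec <- colSums(P)
  } else {
    P <- NULL
  }
  list(loglik = loglik, u = status - dvec, d = dvec, P = P)
}

# Fixed-effects Newton-Raphson on the partial likelihood.
cox_newton <- function(X, time, status, strata = NULL, offset = NULL,
                       init = NULL, tol = 1e-9, max_iter = 30) {
  n <- nrow(X); p <- ncol(X)
  offset <- offset %||% numeric(n)
  if (p == 0L) { # null model: partial likelihood at the offset
    dv <- cox_eta_derivs(time, status, offset, strata, need_P = FALSE)
    return(list(beta = numeric(0), vcov = matrix(numeric(0), 0, 0),
                loglik = dv$loglik, converged = TRUE, iter = 0L,
                derivs = dv))
  }
  beta <- init %||% numeric(p)
  dv <- cox_eta_derivs(time, status, as.numeric(X %*% beta) + offset, strata)
  ll <- dv$loglik
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    g <- drop(crossprod(X, dv$u))
    PX <- dv$P %*% X
    H <- crossprod(X, dv$d * X) - crossprod(PX)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix (constant or collinear covariate?)",
           call. = FALSE))
    halve <- 0
    repeat {
      beta_new <- beta + step
      dv_new <- cox_eta_derivs(time, status,
                               as.numeric(X %*% beta_new) + offset, strata)
      if (dv_new$loglik >= ll - 1e-12 || halve >= 20) break
      step <- step / 2
      halve <- halve + 1
    }
    improved <- dv_new$loglik - ll
    beta <- beta_new; dv <- dv_new; ll <- dv$loglik
    if (abs(improved) < tol) { conv <- TRUE; break }
  }
  PX <- dv$P %*% X
  H <- crossprod(X, dv$d * X) - crossprod(PX)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov, loglik = ll, converged = conv,
       iter = it, derivs = dv)
}

# Joint Newton on (beta, b) for the penalized partial likelihood with
# penalty t(b) %*% Kinv %*% b / (2 sigma2). Returns the optimum plus the
# log-determinant of the b-block Hessian for the Laplace marginal.
cox_frailty_newton <- function(X, time, status, Kinv, sigma2, strata = NULL,
                               init = NULL, tol = 1e-8, max_iter = 30) {
  n <- nrow(X); p <- ncol(X)
  beta <- if (is.null(init)) numeric(p) else init$beta
  b <- if (is.null(init)) numeric(n) else init$b
  Kinv_s <- Kinv / sigma2
  pen_ll <- function(dv, b) dv$loglik - sum(b * (Kinv_s %*% b)) / 2
  dv <- cox_eta_derivs(time, status, as.numeric(X %*% beta) + b, strata)
  ll <- pen_ll(dv, b)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    PX <- dv$P %*% X
    Hbb <- -crossprod(dv$P)
    diag(Hbb) <- diag(Hbb) + dv$d
    Hbb_pen <- Hbb + Kinv_s
    Hxx <- crossprod(X, dv$d * X) - crossprod(PX)
    Hxb <- t(dv$d * X) - crossprod(PX, dv$P)
    H <- rbind(cbind(Hxx, Hxb), cbind(t(Hxb), Hbb_pen))
    g <- c(drop(crossprod(X, dv$u)),
           dv$u - drop(Kinv_s %*% b))
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix in frailty fit", call. = FALSE))
    halve <- 0
    repeat {
      beta_new <- beta + step[seq_len(p)]
      b_new <- b + step[-seq_len(p)]
      dv_new <- cox_eta_derivs(time, status,
                               as.numeric(X %*% beta_new) + b_new, strata)
      ll_new <- pen_ll(dv_new, b_new)
      if (ll_new >= ll - 1e-12 || halve >= 20) break
      step <- step / 2
      halve <- halve + 1
    }
    improved <- ll_new - ll
    beta <- beta_new; b <- b_new; dv <- dv_new; ll <- ll_new
    if (abs(improved) < tol) { conv <- TRUE; break }
  }
  PX <- dv$P %*% X
  Hbb <- -crossprod(dv$P)
  diag(Hbb) <- diag(Hbb) + dv$d
  Hbb_pen <- Hbb + Kinv_s
  Hxx <- crossprod(X, dv$d * X) - crossprod(PX)
  Hxb <- t(dv$d * X) - crossprod(PX, dv$P)
  H <- rbind(cbind(Hxx, Hxb), cbind(t(Hxb), Hbb_pen))
  Hinv <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, p + n, p + n))
  logdet_Hbb <- as.numeric(determinant(Hbb_pen, logarithm = TRUE)$modulus)
  list(beta = beta, b = b, vcov = Hinv[seq_len(p), seq_len(p), drop = FALSE],
       loglik_partial = dv$loglik, loglik_pen = ll,
       penalty = sum(b * (Kinv_s %*% b)) / 2,
       logdet_Hbb = logdet_Hbb, converged = conv)
}
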