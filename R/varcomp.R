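# Average-information REML for linear mixed models with GRM-structured
# random effects, heritability with delta-method standard errors, and
# likelihood-ratio tests.
#
# Two computational paths share one update rule:
#  - diagonal path: a single genetic component is rotated by the GRM's
#    eigenvectors so every per-iteration quantity is O(n p^2);
#  - dense path: any number of components, with V factorized by Cholesky.

# restricted log-likelihood convention used throughout:
#   lR = -1/2 [ (n - p) log 2 pi + log|V| + log|X' V^-1 X| + y' P y ]

.remlDiag <- function(yt, Xt, dlist, maxIter, tol, init = NULL) {
  n <- length(yt); p <- ncol(Xt); k <- length(dlist)
  structs <- c(dlist, list(rep(1, n)))
  vp <- var(drop(stats::lm.fit(Xt, yt)$residuals)) * (n - 1) / max(1, n - p)
  floorv <- 1e-6 * vp
  theta <- if (is.null(init)) rep(vp / (k + 1), k + 1) else pmax(init, floorv)
  llOld <- -Inf; converged <- FALSE; AI <- NULL; ll <- NA_real_
  for (it in seq_len(maxIter)) {
    v <- Reduce(`+`, Map(`*`, structs, theta))
    w <- 1 / v
    WX <- Xt * w
    XtVX <- crossprod(Xt, WX)
    cx <- chol(XtVX)
    XtVXinv <- chol2inv(cx)
    A <- WX %*% XtVXinv                       # n x p
    Py <- w * yt - A %*% crossprod(WX, yt)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cx))) + sum(yt * Py) +
                    (n - p) * log(2 * pi))
    u <- lapply(structs, function(d) d * Py)
    trPG <- vapply(structs, function(d)
      sum(w * d) - sum(A * (WX * d)), numeric(1))
    yPGPy <- vapply(structs, function(d) sum(Py * Py * d), numeric(1))
    score <- -0.5 * (trPG - yPGPy)
    Pu <- lapply(u, function(ui) w * ui - A %*% crossprod(WX, ui))
    AI <- matrix(0, k + 1, k + 1)
    for (i in seq_len(k + 1)) for (j in i:(k + 1))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(u[[i]] * Pu[[j]])
    llAt <- function(th) {
      vv <- Reduce(`+`, Map(`*`, structs, th))
      ww <- 1 / vv
      WXl <- Xt * ww
      cxl <- chol(crossprod(Xt, WXl))
      Pyl <- ww * yt - (WXl %*% chol2inv(cxl)) %*% crossprod(WXl, yt)
      -0.5 * (sum(log(vv)) + 2 * sum(log(diag(cxl))) + sum(yt * Pyl) +
                (n - p) * log(2 * pi))
    }
    upd <- .aiUpdate(theta, AI, score, yPGPy, trPG, n, floorv, ll, llAt)
    thetaNew <- upd$theta
    if (max(abs(thetaNew - theta)) / sum(thetaNew) < tol &&
        abs(upd$ll - ll) < max(tol, tol * abs(ll))) {
      theta <- thetaNew; converged <- TRUE; ll <- upd$ll; break
    }
    theta <- thetaNew; llOld <- ll
  }
  list(theta = theta, loglik = ll, AI = AI, nIter = it,
       converged = converged, floor = floorv)
}

# AI proposal with per-component clamping at the floor, EM fallback when
# the AI system is unsolvable, and step-halving under a monotone-likelihood
# safeguard
.aiUpdate <- function(theta, AI, score, yPGPy, trPG, n, floorv, ll, llAt) {
  llSafe <- function(th) tryCatch(llAt(th), error = function(e) -Inf)
  step <- tryCatch(solve(AI, score), error = function(e) NULL)
  thetaAI <- if (!is.null(step) && all(is.finite(step))) theta + step
    else NULL
  best <- list(theta = theta, ll = ll)
  consider <- function(th) {
    th <- pmax(th, floorv)
    lln <- llSafe(th)
    if (lln > best$ll + 1e-10) best <<- list(theta = th, ll = lln)
  }
  if (!is.null(thetaAI)) {
    th <- pmax(thetaAI, floorv)
    lln <- llSafe(th)
    h <- 0
    while (lln < ll - 1e-8 && h < 12) {        # step-halving safeguard
      th <- (theta + th) / 2
      lln <- llSafe(th)
      h <- h + 1
    }
    if (lln > best$ll + 1e-10) best <- list(theta = th, ll = lln)
  }
  consider(theta + theta^2 * (yPGPy - trPG) / n)   # EM-REML step
  if (any(score < 0)) {                            # drive components with a
    th <- theta                                    # negative score to the
    th[score < 0] <- floorv                        # boundary directly
    consider(th)
  }
  best
}

.remlDense <- function(y, X, Glist, maxIter, tol, init = NULL) {
  n <- length(y); p <- ncol(X); k <- length(Glist)
  structs <- c(Glist, list(diag(n)))
  vp <- var(drop(stats::lm.fit(X, y)$residuals)) * (n - 1) / max(1, n - p)
  floorv <- 1e-6 * vp
  theta <- if (is.null(init)) rep(vp / (k + 1), k + 1) else pmax(init, floorv)
  llOld <- -Inf; converged <- FALSE; AI <- NULL; ll <- NA_real_
  for (it in seq_len(maxIter)) {
    V <- matrix(0, n, n)
    for (i in seq_len(k)) V <- V + theta[i] * Glist[[i]]
    diag(V) <- diag(V) + theta[k + 1]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {                        # V lost definiteness: inflate
      theta[k + 1] <- theta[k + 1] * 2 + floorv
      next
    }
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    cx <- chol(XtVX)
    XtVXinv <- chol2inv(cx)
    M <- VX %*% tcrossprod(XtVXinv, VX)       # X-projection part of P
    P <- Vinv - M
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
    u <- lapply(structs, function(G) G %*% Py)
    trPG <- vapply(structs, function(G) sum(P * G), numeric(1))
    yPGPy <- vapply(u, function(ui) sum(Py * ui), numeric(1))
    score <- -0.5 * (trPG - yPGPy)
    Pu <- lapply(u, function(ui) P %*% ui)
    AI <- matrix(0, k + 1, k + 1)
    for (i in seq_len(k + 1)) for (j in i:(k + 1))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(u[[i]] * Pu[[j]])
    llAt <- function(th) {
      Vl <- matrix(0, n, n)
      for (i in seq_len(k)) Vl <- Vl + th[i] * Glist[[i]]
      diag(Vl) <- diag(Vl) + th[k + 1]
      chl <- chol(Vl)
      Vli <- chol2inv(chl)
      VlX <- Vli %*% X
      cxl <- chol(crossprod(X, VlX))
      Pyl <- Vli %*% y - VlX %*% (chol2inv(cxl) %*% crossprod(VlX, y))
      -0.5 * (2 * sum(log(diag(chl))) + 2 * sum(log(diag(cxl))) +
                sum(y * Pyl) + (n - p) * log(2 * pi))
    }
    upd <- .aiUpdate(theta, AI, score, yPGPy, trPG, n, floorv, ll, llAt)
    thetaNew <- upd$theta
    if (max(abs(thetaNew - theta)) / sum(thetaNew) < tol &&
        abs(upd$ll - ll) < max(tol, tol * abs(ll))) {
      theta <- thetaNew; converged <- TRUE; ll <- upd$ll; break
    }
    theta <- thetaNew; llOld <- ll
  }
  list(theta = theta, loglik = ll, AI = AI, nIter = it,
       converged = converged, floor = floorv)
}

.remlLLAt <- function(y, X, Glist, sigma2) {
  n <- length(y); p <- ncol(X); k <- length(Glist)
  V <- diag(sigma2[k + 1], n)
  for (i in seq_len(k)) if (sigma2[i] > 0) V <- V + sigma2[i] * Glist[[i]]
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  XtVX <- crossprod(X, Vinv %*% X)
  cx <- chol(XtVX)
  P <- Vinv - Vinv %*% X %*% chol2inv(cx) %*% crossprod(X, Vinv)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cx))) +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

.asGRMList <- function(grms) {
  if (is(grms, "GRM")) grms <- list(grms)
  if (is.matrix(grms)) grms <- list(grms)
  lapply(grms, function(g) if (is(g, "GRM")) grmValues(g) else as.matrix(g))
}

#' Fit variance components by average-information REML
#'
#' Mixed model \eqn{y = X b + \sum_i u_i + e} with \eqn{u_i \sim N(0,
#' \sigma^2_{g_i} G_i)} and \eqn{e \sim N(0, \sigma^2_e I)}. Updates are
#' average-information steps with an EM-REML fallback whenever an AI step
#' would leave the parameter space; estimates are clamped at (a small
#' multiple above) zero with a boundary flag. Single-component fits are
#' rotated by the GRM's eigenvectors so each iteration costs O(n).
#' Standard errors come from the inverse AI matrix; the heritability SE
#' uses the delta method.
#'
#' @param y numeric phenotype vector (n >= 10).
#' @param grms a \linkS4class{GRM}, a matrix, or a list of them (one per
#'   genetic component); may be an empty list for the residual-only model.
#' @param X fixed-effect design matrix; default intercept-only.
#' @param componentNames labels for the genetic components.
#' @param maxIter,tol convergence controls: iteration stops when both the
#'   scaled parameter change and the log-likelihood change fall below
#'   \code{tol}.
#' @param init optional numeric vector of starting values (genetic
#'   components then residual).
#' @return a \linkS4class{VarCompFit}. Non-convergence is reported via the
#'   \code{converged} flag, never silently.
#' @export
fitREML <- function(y, grms, X = NULL, componentNames = NULL, maxIter = 100,
                    tol = 1e-6, init = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("REML needs at least 10 observations")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X is not full column rank")
  Glist <- .asGRMList(grms)
  k <- length(Glist)
  if (k && any(vapply(Glist, nrow, 1L) != n))
    stop("GRM dimensions do not match length(y)")
  if (is.null(componentNames))
    componentNames <- if (k == 1) "genetic" else
      if (k) paste0("genetic", seq_len(k)) else character()
  p <- ncol(X)
  if (k == 0) {
    # residual-only model: closed form
    qrX <- qr(X)
    r <- qr.resid(qrX, y)
    s2 <- sum(r^2) / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) +
                    log(det(crossprod(X))) + (n - p))
    return(new("VarCompFit", sigma2 = c(residual = s2),
               se = sqrt(2 * s2^2 / (n - p)), loglik = ll, h2 = numeric(),
               h2Se = numeric(), nIter = 1L, converged = TRUE,
               boundary = FALSE, n = as.integer(n), nFixed = as.integer(p)))
  }
  if (k == 1) {
    e <- eigen(Glist[[1]], symmetric = TRUE)
    U <- e$vectors
    lam <- pmax(e$values, 0)
    fit <- .remlDiag(drop(crossprod(U, y)), crossprod(U, X), list(lam),
                     maxIter, tol, init)
  } else {
    fit <- .remlDense(y, X, Glist, maxIter, tol, init)
  }
  theta <- fit$theta
  loglik <- fit$loglik
  nIterTot <- fit$nIter
  bd <- theta[seq_len(k)] <= 2 * fit$floor
  if (any(bd)) {
    # components clamped at the floor are reported as exactly zero; the
    # remaining components are re-optimized in the reduced model so the
    # reported optimum is exact (keeps nested-model comparisons honest)
    keep <- which(!bd)
    sub <- fitREML(y, Glist[keep], X = X,
                   componentNames = componentNames[keep],
                   maxIter = maxIter, tol = tol)
    theta[seq_len(k)][bd] <- 0
    if (length(keep))
      theta[keep] <- sub@sigma2[seq_along(keep)]
    theta[k + 1] <- sub@sigma2[["residual"]]
    loglik <- sub@loglik
    nIterTot <- nIterTot + sub@nIter
  }
  names(theta) <- c(componentNames, "residual")
  covTheta <- tryCatch(solve(fit$AI), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  se <- sqrt(pmax(diag(covTheta), 0))
  tot <- sum(theta)
  h2 <- theta[seq_len(k)] / tot
  h2Se <- vapply(seq_len(k), function(i) {
    grad <- rep(-theta[i] / tot^2, k + 1)
    grad[i] <- (tot - theta[i]) / tot^2
    v <- drop(t(grad) %*% covTheta %*% grad)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, numeric(1))
  boundary <- theta[seq_len(k)] <= 2 * fit$floor | bd
  new("VarCompFit", sigma2 = theta, se = se, loglik = loglik,
      h2 = unname(h2), h2Se = h2Se, nIter = as.integer(nIterTot),
      converged = fit$converged, boundary = unname(c(boundary, FALSE)),
      n = as.integer(n), nFixed = as.integer(p))
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the same restricted likelihood that [fitREML()] maximizes, at
#' arbitrary (non-negative, residual strictly positive) component values.
#' Useful for profiling and grid diagnostics.
#'
#' @inheritParams fitREML
#' @param sigma2 numeric vector: genetic component(s) then residual.
#' @return scalar restricted log-likelihood.
#' @export
remlLogLik <- function(y, grms, sigma2, X = NULL) {
  y <- as.numeric(y); n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X); p <- ncol(X)
  Glist <- .asGRMList(grms)
  k <- length(Glist)
  stopifnot(length(sigma2) == k + 1, sigma2[k + 1] > 0, all(sigma2 >= 0))
  .remlLLAt(y, X, Glist, sigma2)
}

#' Narrow-sense heritability from a single-component fit
#'
#' \eqn{h^2 = \hat\sigma^2_g / (\hat\sigma^2_g + \hat\sigma^2_e)} with its
#' delta-method standard error.
#'
#' @param fit a \linkS4class{VarCompFit} with exactly one genetic component.
#' @return list with \code{h2} and \code{se}.
#' @export
heritability <- function(fit) {
  stopifnot(is(fit, "VarCompFit"))
  if (length(fit@sigma2) != 2)
    stop("heritability() is defined for single-genetic-component fits")
  if (sum(fit@sigma2) <= 0) stop("total variance is zero")
  list(h2 = unname(fit@sigma2[1] / sum(fit@sigma2)),
       se = if (length(fit@h2Se)) unname(fit@h2Se[1]) else NA_real_)
}

#' Likelihood-ratio test for a genetic variance component
#'
#' \eqn{LRT = 2(\ell_{full} - \ell_{null})}, clamped at zero, referred to a
#' chi-square with \code{df} degrees of freedom (df = 1 by convention for a
#' single variance component; note the zero boundary makes this reference
#' distribution conservative).
#'
#' @param full,null \linkS4class{VarCompFit} objects for the model with and
#'   without the tested component; fixed effects must match.
#' @param df degrees of freedom (default 1).
#' @return list with \code{statistic}, \code{df} and \code{p}.
#' @export
lrtGenetic <- function(full, null, df = 1) {
  stopifnot(is(full, "VarCompFit"), is(null, "VarCompFit"))
  if (full@nFixed != null@nFixed || full@n != null@n)
    stop("full and null fits must share fixed effects and samples")
  if (length(null@sigma2) >= length(full@sigma2))
    stop("null must drop a component relative to the full model")
  if (null@loglik > full@loglik + 1e-3)
    warning("null log-likelihood exceeds full; full fit may not have converged")
  stat <- max(0, 2 * (full@loglik - null@loglik))
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Write a variance-component fit as a flat TSV
#'
#' @param fit a \linkS4class{VarCompFit}.
#' @param path output file.
#' @export
writeVarCompFit <- function(fit, path) {
  df <- data.frame(component = names(fit@sigma2),
                   sigma2 = unname(fit@sigma2), se = unname(fit@se),
                   boundary = unname(fit@boundary))
  meta <- data.frame(component = c("loglik", "n_iter", "converged", "h2",
                                   "h2_se"),
                     sigma2 = c(fit@loglik, fit@nIter,
                                as.numeric(fit@converged),
                                if (length(fit@h2)) fit@h2[1] else NA,
                                if (length(fit@h2Se)) fit@h2Se[1] else NA),
                     se = NA, boundary = NA)
  write.table(rbind(df, meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
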