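# Twelve statistical genomic-prediction models behind one train/predict
# contract. Marker-effect models store raw-scale effects + intercept;
# kinship/kernel models store the training context for kernel regression.

#' Names of the supported genomic-prediction models
#'
#' @return character vector: rrBLUP, GBLUP, RR, LASSO, EN, BayesA, BayesB,
#'   BayesC, BRR, BL, RKHS, MKRKHS.
#' @export
gsModelNames <- function() {
  c("rrBLUP", "GBLUP", "RR", "LASSO", "EN", "BayesA", "BayesB", "BayesC",
    "BRR", "BL", "RKHS", "MKRKHS")
}

.stdMarkers <- function(D) {
  p <- colMeans(D) / 2
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  poly <- scale > 0
  Ws <- sweep(D[, poly, drop = FALSE], 2, center[poly])
  Ws <- sweep(Ws, 2, scale[poly], "/")
  list(Ws = Ws, center = center, scale = scale, poly = poly)
}

.essChain <- function(x) {
  n <- length(x)
  if (n < 10) return(as.numeric(n))
  r <- drop(stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf)[-1]
  k <- which(r < 0)[1]
  if (!is.na(k)) r <- r[seq_len(max(k - 1, 0))]
  max(1, n / (1 + 2 * sum(r)))
}

# GLS intercept + V^-1 residual machinery shared by kinship/kernel models
.glsContext <- function(y, Ks, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * Ks[[i]]
  Vinv <- chol2inv(chol(V))
  one <- rep(1, n)
  Vi1 <- Vinv %*% one
  mu <- drop(crossprod(Vi1, y)) / drop(crossprod(Vi1, one))
  r <- y - mu
  list(mu = mu, Vinvr = drop(Vinv %*% r))
}

.trainRRBLUP <- function(y, D, config) {
  p <- colMeans(D) / 2
  W <- sweep(D, 2, 2 * p)
  cden <- sum(2 * p * (1 - p))
  K <- tcrossprod(W) / cden
  fit <- fitREML(y, K)
  th <- varComp(fit)
  g <- .glsContext(y, list(K), th)
  # ridge-system marker effects via the kinship identity:
  # a = (sg/c) W' V^-1 (y - mu)
  a <- drop(crossprod(W, g$Vinvr)) * th[[1]] / cden
  list(effects = a, intercept = g$mu - sum(2 * p * a),
       hyper = list(sigma2g = th[[1]], sigma2e = th[[2]],
                    lambda = th[[2]] / (th[[1]] / cden), h2 = fit@h2),
       fit = fit)
}

.trainGBLUP <- function(y, D, config) {
  grm <- .grmFromDosage(D, scope = "all")
  G <- grmValues(grm)
  fit <- fitREML(y, grm)
  th <- varComp(fit)
  g <- .glsContext(y, list(G), th)
  alphaV <- th[[1]] * g$Vinvr            # so gebv = Gcross %*% alphaV
  p <- colMeans(D) / 2
  list(context = list(type = "gblup", W = sweep(D, 2, 2 * p),
                      center = 2 * p, cden = sum(2 * p * (1 - p)),
                      alphaV = alphaV, mu = g$mu,
                      trainGEBV = drop(G %*% alphaV) + g$mu),
       hyper = list(sigma2g = th[[1]], sigma2e = th[[2]], h2 = fit@h2),
       fit = fit)
}

.trainGlmnet <- function(y, D, alpha, config, seed) {
  st <- .stdMarkers(D)
  lam <- config$lambda
  if (is.null(lam)) {
    cv <- glmnet::cv.glmnet(st$Ws, y, alpha = alpha, nfolds = 5,
                            nlambda = 50, standardize = FALSE)
    lam <- cv$lambda.min
    fitg <- cv$glmnet.fit
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else {
    path <- sort(unique(c(lam, max(lam, sd(y)) * c(8, 4, 2, 1))),
                 decreasing = TRUE)
    fitg <- glmnet::glmnet(st$Ws, y, alpha = alpha, lambda = path,
                           standardize = FALSE, thresh = 1e-12)
    co <- as.numeric(stats::coef(fitg, s = lam, exact = TRUE, x = st$Ws,
                                 y = y, alpha = alpha,
                                 standardize = FALSE, thresh = 1e-12))
  }
  aStd <- co[-1]
  a <- numeric(ncol(D))
  a[st$poly] <- aStd / st$scale[st$poly]
  list(effects = a, intercept = co[1] - sum(a * st$center),
       hyper = list(alpha = alpha, lambda = lam))
}

.trainBayes <- function(y, D, model, config, seed) {
  st <- .stdMarkers(D)
  if (isFALSE(config$standardize)) {
    # center-only coding: common effect variance on the raw dosage scale
    st$Ws <- sweep(D[, st$poly, drop = FALSE], 2, st$center[st$poly])
    st$scale[] <- 1
  }
  m <- ncol(st$Ws)
  vy <- var(y)
  nIter <- config$nIter %||% 12000
  burnIn <- config$burnIn %||% 2000
  thin <- config$thin %||% 5
  nuE <- config$nuE %||% 5
  nuA <- config$nuA %||% 5
  # prior scales: phenotypic variance split half genetic, half residual
  piIn <- switch(model, BayesB = config$piIn %||% 0.05,
                 BayesC = config$piIn %||% 0.10, 1)
  Sa <- (vy / 2) / (m * piIn)
  Se <- vy / 2
  fixVar <- isTRUE(config$fixVar)
  res <- .gibbsAlphabet(y, st$Ws, model, as.integer(nIter),
                        as.integer(burnIn), as.integer(thin),
                        nuE, Se, nuA, Sa,
                        piIn, model == "BayesC" && is.null(config$piIn),
                        config$piBetaA %||% 1, config$piBetaB %||% 9,
                        config$blShape %||% 1, config$blRate %||% 0.1,
                        fixVar, config$fixedSa2 %||% 0,
                        config$fixedS2e %||% 0)
  a <- numeric(ncol(D))
  a[st$poly] <- res$effects / st$scale[st$poly]
  list(effects = a, intercept = res$intercept - sum(a * st$center),
       hyper = list(nIter = nIter, burnIn = burnIn, thin = thin,
                    nuE = nuE, nuA = nuA, Sa = Sa, Se = Se, piIn = piIn,
                    piPosterior = res$pi_mean),
       mcmc = list(chainLength = nIter, burnIn = burnIn, thin = thin,
                   nSamples = res$n_samples,
                   essSigma2e = .essChain(res$s2e_chain),
                   sigma2ePostMean = mean(res$s2e_chain)))
}

.gaussKernel <- function(D2, h, med) exp(-h * D2 / med)

.trainRKHS <- function(y, D, config) {
  D2 <- as.matrix(stats::dist(D))^2
  med <- median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) stop("degenerate distance matrix in RKHS")
  h <- config$h %||% 1
  K <- .gaussKernel(D2, h, med)
  fit <- fitREML(y, K)
  th <- varComp(fit)
  g <- .glsContext(y, list(K), th)
  list(context = list(type = "rkhs", Dtrain = D, med = med, h = h,
                      alphaV = th[[1]] * g$Vinvr, mu = g$mu,
                      trainGEBV = drop(K %*% (th[[1]] * g$Vinvr)) + g$mu),
       hyper = list(h = h, sigma2k = th[[1]], sigma2e = th[[2]]),
       fit = fit)
}

.trainMKRKHS <- function(y, D, config) {
  D2 <- as.matrix(stats::dist(D))^2
  med <- median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) stop("degenerate distance matrix in MKRKHS")
  hs <- config$hs %||% c(0.25, 1, 4)
  Ks <- lapply(hs, .gaussKernel, D2 = D2, med = med)
  fit <- fitREML(y, Ks, componentNames = paste0("kernel_h", hs))
  th <- varComp(fit)
  g <- .glsContext(y, Ks, th)
  gebv <- g$mu
  for (i in seq_along(Ks)) gebv <- gebv + drop(Ks[[i]] %*% (th[[i]] * g$Vinvr))
  list(context = list(type = "mkrkhs", Dtrain = D, med = med, hs = hs,
                      Vinvr = g$Vinvr, sigma2k = unname(th[seq_along(hs)]),
                      mu = g$mu, trainGEBV = gebv),
       hyper = list(hs = hs, sigma2k = unname(th[seq_along(hs)]),
                    sigma2e = unname(th[[length(th)]])),
       fit = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a genomic-prediction model
#'
#' One entry point for the twelve statistical models: rrBLUP (REML ridge in
#' marker space via the kinship identity), GBLUP (GRM REML + BLUP
#' back-solve), RR/LASSO/EN (glmnet coordinate descent on standardized
#' markers, penalty from an inner 5-fold cross-validation over a 50-point
#' path; elastic-net mixing 0.5), the Bayesian alphabet (Gibbs samplers,
#' 12,000 iterations / 2,000 burn-in / thinning 5, scaled-inverse-chi-square
#' priors with 5 df and scales from var(y) split half genetic half
#' residual; Bayes B inclusion probability 0.05 fixed, Bayes C inclusion
#' estimated under a Beta(1, 9) prior), and Gaussian-kernel RKHS
#' (\eqn{K = \exp(-h D^2 / median(D^2))}, h = 1) with its multi-kernel
#' variant averaging h in {0.25, 1, 4} through per-kernel variance
#' components.
#'
#' @param modelName one of [gsModelNames()].
#' @param geno a fully observed \linkS4class{GenotypeData}.
#' @param pheno data.frame with \code{sample_id} and \code{tar}.
#' @param config named list of model-specific overrides (e.g.
#'   \code{lambda}, \code{nIter}, \code{piIn}, \code{h}).
#' @param seed integer seed; training is bitwise reproducible under it.
#' @return a \linkS4class{GSModel}.
#' @export
trainModel <- function(modelName, geno, pheno, config = list(), seed = 1) {
  if (!modelName %in% gsModelNames())
    stop("unknown model '", modelName, "'; see gsModelNames()")
  al <- alignSamples(geno, pheno)
  geno <- al$geno
  y <- al$pheno$tar
  D <- dosageMatrix(geno)
  if (anyNA(D)) stop("training requires imputed (complete) dosages")
  bayes <- modelName %in% c("BayesA", "BayesB", "BayesC", "BRR", "BL")
  if (bayes && length(y) < 30)
    stop("MCMC models need at least 30 training individuals")
  .withSeed(seed, {
    res <- switch(modelName,
      rrBLUP = .trainRRBLUP(y, D, config),
      GBLUP = .trainGBLUP(y, D, config),
      RR = .trainGlmnet(y, D, 0, config, seed),
      LASSO = .trainGlmnet(y, D, 1, config, seed),
      EN = .trainGlmnet(y, D, 0.5, config, seed),
      RKHS = .trainRKHS(y, D, config),
      MKRKHS = .trainMKRKHS(y, D, config),
      .trainBayes(y, D, modelName, config, seed))
    new("GSModel", modelName = modelName,
        intercept = res$intercept %||% NA_real_,
        markerEffects = res$effects %||% numeric(),
        markerIDs = markerInfo(geno)$id,
        scaling = list(),
        trainContext = res$context %||% list(),
        hyperparams = res$hyper %||% list(),
        mcmc = res$mcmc %||% list(),
        seed = as.integer(seed))
  })
}

#' Predict genomic estimated breeding values
#'
#' Marker-effect models return \code{intercept + dosages \%*\% effects};
#' kinship/kernel models perform kernel regression through the
#' cross-relationship between new and training samples. New genotypes must
#' carry every training marker (matched by id); missing markers raise an
#' error listing the offending ids.
#'
#' @param object a \linkS4class{GSModel}.
#' @param newdata a fully observed \linkS4class{GenotypeData}.
#' @return named numeric vector of GEBVs.
#' @export
setMethod("predict", "GSModel", function(object, newdata, ...) {
  stopifnot(is(newdata, "GenotypeData"))
  ids <- markerInfo(newdata)$id
  miss <- setdiff(object@markerIDs, ids)
  if (length(miss))
    stop("new genotypes lack ", length(miss), " training marker(s): ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  D <- dosageMatrix(newdata)[, match(object@markerIDs, ids), drop = FALSE]
  if (anyNA(D)) stop("prediction requires imputed (complete) dosages")
  if (length(object@markerEffects)) {
    return(setNames(drop(object@intercept + D %*% object@markerEffects),
                    rownames(D)))
  }
  ctx <- object@trainContext
  out <- switch(ctx$type,
    gblup = {
      Wnew <- sweep(D, 2, ctx$center)
      ctx$mu + drop(Wnew %*% crossprod(ctx$W, ctx$alphaV)) / ctx$cden
    },
    rkhs = {
      D2c <- outer(rowSums(D^2), rowSums(ctx$Dtrain^2), "+") -
        2 * tcrossprod(D, ctx$Dtrain)
      ctx$mu + drop(.gaussKernel(pmax(D2c, 0), ctx$h, ctx$med) %*% ctx$alphaV)
    },
    mkrkhs = {
      D2c <- outer(rowSums(D^2), rowSums(ctx$Dtrain^2), "+") -
        2 * tcrossprod(D, ctx$Dtrain)
      D2c <- pmax(D2c, 0)
      g <- rep(ctx$mu, nrow(D))
      for (i in seq_along(ctx$hs))
        g <- g + drop(.gaussKernel(D2c, ctx$hs[i], ctx$med) %*%
                        (ctx$sigma2k[i] * ctx$Vinvr))
      g
    },
    stop("unknown training context type"))
  setNames(out, rownames(D))
})

#' Serialize / restore a fitted model as plain text
#'
#' Versioned YAML archive of the model name, hyperparameters, effect
#' vectors and kernel context (training dosages included for kernel
#' models).
#'
#' @param model a \linkS4class{GSModel}.
#' @param path output file.
#' @export
writeGSModel <- function(model, path) {
  obj <- list(format_version = 1L,
              model_name = model@modelName,
              seed = model@seed,
              intercept = model@intercept,
              marker_ids = model@markerIDs,
              marker_effects = model@markerEffects,
              hyperparams = model@hyperparams,
              mcmc = model@mcmc,
              train_context = lapply(model@trainContext, function(x)
                if (is.matrix(x)) list(.matrix = dim(x),
                                       data = as.numeric(x),
                                       rn = rownames(x)) else x))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname writeGSModel
#' @export
readGSModel <- function(path) {
  obj <- yaml::read_yaml(path)
  ctx <- lapply(obj$train_context, function(x) {
    if (is.list(x) && !is.null(x$.matrix)) {
      m <- matrix(unlist(x$data), x$.matrix[1], x$.matrix[2])
      rownames(m) <- x$rn
      m
    } else if (is.list(x)) unlist(x) else x
  })
  new("GSModel", modelName = obj$model_name,
      intercept = as.numeric(obj$intercept),
      markerEffects = as.numeric(unlist(obj$marker_effects)),
      markerIDs = as.character(unlist(obj$marker_ids)),
      scaling = list(), trainContext = ctx,
      hyperparams = obj$hyperparams,
      mcmc = if (is.null(obj$mcmc)) list() else obj$mcmc,
      seed = as.integer(obj$seed))
}
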