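#' Principal component model of a spectral set
#'
#' Column-mean-centred PCA computed by singular value decomposition.
#' Loadings are orthonormal row vectors (component x channel); scores are
#' the projections of the centred spectra; explained variance per
#' component is \eqn{100 \sigma_k^2 / \sum \sigma^2}.
#'
#' Sign convention: each loading is first oriented so that its
#' largest-magnitude element is positive; PC1 is then re-oriented, if
#' needed, so that its loading value at the channel nearest 1621 cm^-1 is
#' positive. On second-derivative Amide I data this puts electrical-mark
#' spectra (elevated beta-sheet) on the positive side of PC1.
#'
#' @slot center mean spectrum removed before decomposition
#' @slot loadings matrix, components x channels, orthonormal rows
#' @slot scores matrix, spectra x components
#' @slot explainedVarPct percent variance per component, non-increasing
#' @slot nComponents number of components retained
#' @slot wavenumbers channel wavenumbers
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 scores = "matrix", explainedVarPct = "numeric",
                 nComponents = "integer", wavenumbers = "numeric"))

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components, %d channels\n",
              object@nComponents, ncol(object@loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", head(object@explainedVarPct, 8L)),
            collapse = ", "), "\n")
})

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "PCAModel", function(x) x@wavenumbers)

#' Fit a PCA model
#'
#' @param set a [SpectraSet] (typically second-derivative Amide I data)
#' @param nComponents components to retain (default 8); must be at most
#'   \code{min(n - 1, channels)}
#' @param orientWavenumber wavenumber whose PC1 loading is forced positive
#'   (default 1621 cm^-1); \code{NA} to skip
#' @return a [PCAModel]
#' @export
pcaFit <- function(set, nComponents = 8L, orientWavenumber = 1621) {
  stopifnot(is(set, "SpectraSet"))
  X <- t(spectraMatrix(set))           # spectra x channels
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (nComponents > kmax)
    stop(sprintf("nComponents = %d exceeds min(n - 1, channels) = %d",
                 nComponents, kmax))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  evar <- 100 * sv$d^2 / sum(sv$d^2)
  P <- t(sv$v)                         # components x channels
  Tm <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  for (k in seq_len(nComponents)) {
    if (P[k, which.max(abs(P[k, ]))] < 0) {
      P[k, ] <- -P[k, ]; Tm[, k] <- -Tm[, k]
    }
  }
  if (!is.na(orientWavenumber)) {
    ch <- which.min(abs(wavenumbers(set) - orientWavenumber))
    if (P[1L, ch] < 0) {
      P[1L, ] <- -P[1L, ]; Tm[, 1L] <- -Tm[, 1L]
    }
  }
  rownames(P) <- colnames(Tm) <- paste0("PC", seq_len(nComponents))
  rownames(Tm) <- colnames(set)
  new("PCAModel", center = ctr, loadings = P, scores = Tm,
      explainedVarPct = evar[seq_len(nComponents)],
      nComponents = as.integer(nComponents),
      wavenumbers = wavenumbers(set))
}

#' Confidence ellipse of a 2-d score cloud
#'
#' Normal-theory ellipse from the sample mean and covariance of two score
#' columns: semi-axis lengths are \eqn{\sqrt{\lambda_i\,
#' \chi^2_2(level)}} along the covariance eigenvectors. For isotropic
#' unit-variance scores at level 0.95 both semi-axes equal
#' \eqn{\sqrt{5.991}}.
#'
#' @param scores numeric matrix or data.frame with two columns, >= 3 rows
#' @param level coverage probability in (0, 1), default 0.95
#' @return list with \code{center} (length 2), \code{semiAxes} (major,
#'   minor), \code{rotation} (radians, major-axis angle), \code{level}
#' @export
confidenceEllipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop("scores must have exactly 2 columns")
  if (nrow(scores) < 3L) stop("need at least 3 points")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  ctr <- colMeans(scores)
  S <- cov(scores)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2L] <= .Machine$double.eps * ev$values[1L])
    stop("degenerate covariance: score cloud is (near-)collinear")
  r <- sqrt(ev$values * qchisq(level, df = 2L))
  list(center = ctr, semiAxes = r,
       rotation = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L]),
       level = level)
}

#' Points on a confidence ellipse outline
#'
#' @param ellipse result of [confidenceEllipse()]
#' @param n number of outline points
#' @return n x 2 matrix of coordinates
#' @export
ellipseOutline <- function(ellipse, n = 181L) {
  th <- seq(0, 2 * pi, length.out = n)
  R <- matrix(c(cos(ellipse$rotation), sin(ellipse$rotation),
                -sin(ellipse$rotation), cos(ellipse$rotation)), 2L)
  pts <- cbind(ellipse$semiAxes[1L] * cos(th),
               ellipse$semiAxes[2L] * sin(th)) %*% t(R)
  sweep(pts, 2L, ellipse$center, "+")
}

#' Is each point inside a confidence ellipse?
#'
#' @param scores n x 2 matrix of points
#' @param ellipse result of [confidenceEllipse()]
#' @return logical vector
#' @export
insideEllipse <- function(scores, ellipse) {
  scores <- as.matrix(scores)
  d <- sweep(scores, 2L, ellipse$center)
  R <- matrix(c(cos(ellipse$rotation), sin(ellipse$rotation),
                -sin(ellipse$rotation), cos(ellipse$rotation)), 2L)
  u <- d %*% R
  (u[, 1L] / ellipse$semiAxes[1L])^2 + (u[, 2L] / ellipse$semiAxes[2L])^2 <= 1
}

#' Y-threshold classification rule
#'
#' The dummy-coded single response maps classes to numeric targets
#' (normal epidermis 1, electrical mark 2, normal dermis 3) and predicted
#' Y is cut at fixed thresholds: y < 1.5 is normal epidermis,
#' 1.5 <= y <= 2.5 is electrical mark (closed interval: boundary values
#' belong to the electrical class), y > 2.5 is normal dermis.
#'
#' @slot lower,upper class boundaries on predicted Y
#' @slot codes named numeric dummy codes per class
#' @export
setClass("ThresholdRule",
  representation(lower = "numeric", upper = "numeric", codes = "numeric"),
  validity = function(object) {
    if (object@lower >= object@upper)
      return("thresholds must satisfy lower < upper")
    TRUE
  })

#' @param lower,upper Y boundaries (defaults 1.5, 2.5)
#' @param codes named dummy codes
#' @return a \code{ThresholdRule}
#' @rdname ThresholdRule-class
#' @export
thresholdRule <- function(lower = 1.5, upper = 2.5,
    codes = c(normal_epidermis = 1, electrical_mark = 2,
              normal_dermis = 3)) {
  new("ThresholdRule", lower = lower, upper = upper, codes = codes)
}

#' Dummy-code class labels
#'
#' @param labels character class labels
#' @param rule a [ThresholdRule]
#' @return numeric response vector
#' @export
dummyCode <- function(labels, rule = thresholdRule()) {
  y <- unname(rule@codes[labels])
  if (anyNA(y))
    stop("labels outside the coding: ",
         paste(unique(labels[is.na(y)]), collapse = ", "))
  y
}

#' Classify predicted Y values
#'
#' @param yPred numeric predictions
#' @param rule a [ThresholdRule]
#' @return character class labels
#' @export
classifyY <- function(yPred, rule = thresholdRule()) {
  cls <- names(sort(rule@codes))
  out <- ifelse(yPred < rule@lower, cls[1L],
                ifelse(yPred <= rule@upper, cls[2L], cls[3L]))
  as.character(out)
}

#' Fitted PLS1 regression model
#'
#' One-block (single-response) partial least squares fitted by the
#' iterative NIPALS algorithm; predictors are mean-centred, the response
#' is the dummy-coded class. Prediction of the training X mean returns
#' the training y mean exactly.
#'
#' @slot xMean,yMean training means
#' @slot weights,xLoadings matrices, channels x factors
#' @slot yLoadings numeric, one per factor
#' @slot coef regression vector on centred X
#' @slot nFactors latent factors retained
#' @slot xVarPct percent of X variance captured per factor
#' @slot thresholds the [ThresholdRule] attached to the model
#' @slot wavenumbers channel wavenumbers
#' @export
setClass("PLSModel",
  representation(xMean = "numeric", yMean = "numeric", weights = "matrix",
                 xLoadings = "matrix", yLoadings = "numeric",
                 coef = "numeric", nFactors = "integer",
                 xVarPct = "numeric", thresholds = "ThresholdRule",
                 wavenumbers = "numeric"))

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent factors, %d channels\n",
              object@nFactors, length(object@coef)))
  cat("  X variance per factor (%):",
      paste(sprintf("%.1f", object@xVarPct), collapse = ", "), "\n")
})

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "PLSModel", function(x) x@wavenumbers)

## Core NIPALS PLS1 on plain matrices. Returns everything needed to build
## regression vectors for any factor count <= nFactors.
.pls1Nipals <- function(X, y, nFactors) {
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X); yMean <- mean(y)
  Xc <- sweep(X, 2L, xMean); yc <- y - yMean
  if (sd(y) == 0) stop("zero-variance response")
  W <- matrix(0, p, nFactors); P <- matrix(0, p, nFactors)
  q <- numeric(nFactors)
  ssX <- sum(Xc^2)
  xVar <- numeric(nFactors)
  Xd <- Xc; yd <- yc
  for (k in seq_len(nFactors)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { nFactors <- k - 1L; break }
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) { nFactors <- k - 1L; break }
    pk <- drop(crossprod(Xd, t)) / tt
    qk <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pk)
    yd <- yd - t * qk
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    xVar[k] <- 100 * tt * sum(pk^2) / ssX
  }
  if (nFactors == 0L) stop("degenerate deflation: no usable latent factor")
  W <- W[, seq_len(nFactors), drop = FALSE]
  P <- P[, seq_len(nFactors), drop = FALSE]
  q <- q[seq_len(nFactors)]
  list(xMean = xMean, yMean = yMean, W = W, P = P, q = q,
       nFactors = nFactors, xVar = xVar[seq_len(nFactors)])
}

## Regression vector using the first k factors: b = W (P'W)^-1 q.
.plsCoef <- function(fit, k) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[seq_len(k)]))
}

#' Fit a dummy-coded PLS1 model
#'
#' @param set a [SpectraSet] (preprocessed predictors)
#' @param y numeric response; defaults to dummy-coding the set's class
#'   labels with \code{rule}
#' @param nFactors latent factors to extract
#' @param rule the [ThresholdRule] stored with the model
#' @return a [PLSModel]
#' @export
pls1Fit <- function(set, y = NULL, nFactors = 2L, rule = thresholdRule()) {
  stopifnot(is(set, "SpectraSet"))
  X <- t(spectraMatrix(set))
  if (is.null(y)) y <- dummyCode(classLabels(set), rule)
  if (nrow(X) != length(y)) stop("rows of X must match length(y)")
  fit <- .pls1Nipals(X, y, nFactors)
  new("PLSModel", xMean = fit$xMean, yMean = fit$yMean, weights = fit$W,
      xLoadings = fit$P, yLoadings = fit$q, coef = .plsCoef(fit, fit$nFactors),
      nFactors = fit$nFactors, xVarPct = fit$xVar, thresholds = rule,
      wavenumbers = wavenumbers(set))
}

#' Predict Y for new spectra
#'
#' @param object a [PLSModel]
#' @param newdata a [SpectraSet] on the model's wavenumber grid, or a
#'   spectra x channels matrix
#' @return numeric vector of predicted Y values
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
  X <- if (is(newdata, "SpectraSet")) t(spectraMatrix(newdata)) else
    as.matrix(newdata)
  if (ncol(X) != length(object@xMean))
    stop("newdata channels do not match the model grid")
  drop(sweep(X, 2L, object@xMean) %*% object@coef) + object@yMean
})

#' Latent-factor scores for spectra
#'
#' @param model a [PLSModel]
#' @param newdata a [SpectraSet] or matrix (spectra x channels)
#' @return matrix of scores, spectra x factors
#' @export
plsScores <- function(model, newdata) {
  X <- if (is(newdata, "SpectraSet")) t(spectraMatrix(newdata)) else
    as.matrix(newdata)
  Xc <- sweep(X, 2L, model@xMean)
  R <- model@weights %*%
    solve(crossprod(model@xLoadings, model@weights))
  S <- Xc %*% R
  colnames(S) <- paste0("LV", seq_len(ncol(S)))
  S
}

#' Leave-one-out cross-validation result
#'
#' @slot rmsecv root-mean-square error of cross-validation per candidate
#'   factor count
#' @slot chosenFactors factor count at the first local minimum of rmsecv
#'   (ties resolved toward fewer factors)
#' @slot predictions held-out predictions, samples x factor counts
#' @export
setClass("CVResult",
  representation(rmsecv = "numeric", chosenFactors = "integer",
                 predictions = "matrix"))

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: chosen %d latent factors\n", object@chosenFactors))
  cat("  RMSECV:", paste(sprintf("%.4f", object@rmsecv), collapse = ", "),
      "\n")
})

#' Leave-one-out cross-validation of PLS1
#'
#' Each sample is predicted by a model refitted on the remaining n - 1
#' samples, for every candidate factor count from 1 to \code{maxFactors}.
#' The chosen factor count is the first local minimum of RMSECV (a value
#' no larger than its successor), which guards against overfitting
#' noise-driven later minima.
#'
#' @param set a [SpectraSet]
#' @param y response; defaults to dummy-coded labels
#' @param maxFactors largest factor count to try (default 10)
#' @param rule coding rule used when \code{y} is NULL
#' @return a [CVResult]
#' @export
plsLoocv <- function(set, y = NULL, maxFactors = 10L, rule = thresholdRule()) {
  stopifnot(is(set, "SpectraSet"))
  X <- t(spectraMatrix(set))
  if (is.null(y)) y <- dummyCode(classLabels(set), rule)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  if (sd(y) == 0) stop("zero-variance response")
  maxFactors <- min(maxFactors, n - 2L, ncol(X))
  pred <- matrix(NA_real_, n, maxFactors)
  for (i in seq_len(n)) {
    fit <- .pls1Nipals(X[-i, , drop = FALSE], y[-i], maxFactors)
    xc <- X[i, ] - fit$xMean
    for (k in seq_len(fit$nFactors))
      pred[i, k] <- sum(xc * .plsCoef(fit, k)) + fit$yMean
    if (fit$nFactors < maxFactors)
      pred[i, (fit$nFactors + 1L):maxFactors] <- pred[i, fit$nFactors]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  chosen <- maxFactors
  for (k in seq_len(maxFactors - 1L))
    if (rmsecv[k] <= rmsecv[k + 1L]) { chosen <- k; break }
  new("CVResult", rmsecv = rmsecv, chosenFactors = as.integer(chosen),
      predictions = pred)
}

#' Per-class accuracy table
#'
#' For each true class: how many spectra were classified correctly, how
#' many falsely, and the percent accuracy (reported to 0.1%).
#'
#' @param predicted character predicted labels
#' @param truth character true labels
#' @return data.frame with columns class, n, correct, false, accuracyPct
#' @export
accuracyTable <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!any(predicted %in% truth))
    stop("predicted and true label sets are disjoint")
  cls <- unique(truth)
  rows <- lapply(cls, function(cl) {
    idx <- truth == cl
    n <- sum(idx)
    ok <- sum(predicted[idx] == cl)
    data.frame(class = cl, n = n, correct = ok, false = n - ok,
               accuracyPct = round(100 * ok / n, 1L))
  })
  do.call(rbind, rows)
}
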