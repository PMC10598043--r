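# build the centred response and the standardized, full-rank design
.rdaPrepare <- function(y, x, hellinger = TRUE) {
  y <- as.matrix(y)
  if (hellinger) y <- sqrt(relativeAbundance(y))
  yc <- scale(y, center = TRUE, scale = FALSE)
  xdf <- as.data.frame(x)
  mm <- stats::model.matrix(~ ., data = xdf)[, -1, drop = FALSE]
  num <- apply(mm, 2, stats::sd) > 0
  mm <- mm[, num, drop = FALSE]
  mm <- scale(mm)
  qrX <- qr(mm)
  aliased <- character(0)
  if (qrX$rank < ncol(mm)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(mm)[-keep]
    warning("dropping aliased explanatory column(s): ",
            paste(aliased, collapse = ", "))
    mm <- mm[, keep, drop = FALSE]
    qrX <- qr(mm)
  }
  list(yc = yc, x = mm, qrX = qrX, aliased = aliased)
}

#' Redundancy analysis of a community table
#'
#' RDA: a PCA of the fitted values of the multivariate least-squares
#' regression of the (Hellinger-transformed, centred) community table on the
#' explanatory variables. Explanatory variables are z-standardized; factors
#' are expanded to treatment-coded indicators; collinear columns are dropped
#' with a warning. Constrained eigenvalues are the principal components of
#' the fitted values, unconstrained ones those of the residuals; their sum
#' equals the total variance, and `constrainedFraction` is the share of
#' variance explained (1 - RSS/TSS of the regression).
#'
#' @param y samples-by-OTUs community matrix (counts or proportions) or an
#'   `OtuExperiment`, rows aligned with `x`.
#' @param x data.frame of explanatory variables.
#' @param hellinger apply the Hellinger transformation (square root of
#'   relative abundances) before centring — the standard pre-treatment of
#'   species data for linear ordination (default TRUE).
#' @return an [RdaResult-class].
#' @export
rdaAnalysis <- function(y, x, hellinger = TRUE) {
  if (is(y, "OtuExperiment")) y <- otuCounts(y)
  n <- nrow(y)
  if (n <= ncol(as.data.frame(x)) + 1)
    stop("need n_samples > n_explanatory + 1")
  pr <- .rdaPrepare(y, x, hellinger)
  Q <- qr.Q(pr$qrX)
  fitted <- Q %*% crossprod(Q, pr$yc)
  resid <- pr$yc - fitted
  sf <- svd(fitted)
  sr <- svd(resid)
  tolEig <- 1e-12 * max(1, sum(pr$yc^2))
  eigC <- (sf$d^2 / (n - 1))
  eigC <- eigC[eigC > tolEig]
  eigU <- (sr$d^2 / (n - 1))
  eigU <- eigU[eigU > tolEig]
  tot <- sum(pr$yc^2) / (n - 1)
  k <- length(eigC)
  site <- sf$u[, seq_len(k), drop = FALSE] %*% diag(sf$d[seq_len(k)], k)
  dimnames(site) <- list(rownames(y), if (k) paste0("RDA", seq_len(k)))
  varScores <- if (k) stats::cor(pr$x, site) else
    matrix(0, ncol(pr$x), 0, dimnames = list(colnames(pr$x), NULL))
  new("RdaResult",
      constrainedEigenvalues = eigC, unconstrainedEigenvalues = eigU,
      constrainedFraction = sum(fitted^2) / sum(pr$yc^2),
      siteScores = site, variableScores = varScores,
      totalVariance = tot, aliased = pr$aliased)
}

setMethod("show", "RdaResult", function(object) {
  cat("RDA:", length(object@constrainedEigenvalues), "constrained axes,",
      "constrained fraction =", signif(object@constrainedFraction, 4), "\n")
})

#' Monte-Carlo permutation test of the RDA model
#'
#' Pseudo-F = (constrained variance / q) / (residual variance / (n - q - 1))
#' with q the rank of the explanatory design. The null permutes the rows of
#' the response; p = (1 + #\{F_null >= F_obs\}) / (1 + nPerm).
#'
#' @inheritParams rdaAnalysis
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return a [PermutationTestResult-class].
#' @export
rdaPermutationTest <- function(y, x, nPerm = 999L, seed = 1L,
                               hellinger = TRUE) {
  if (is(y, "OtuExperiment")) y <- otuCounts(y)
  n <- nrow(y)
  pr <- .rdaPrepare(y, x, hellinger)
  Q <- qr.Q(pr$qrX)
  q <- pr$qrX$rank
  tss <- sum(pr$yc^2)
  pseudoF <- function(yc) {
    ssc <- sum(crossprod(Q, yc)^2)
    (ssc / q) / ((tss - ssc) / (n - q - 1))
  }
  fObs <- pseudoF(pr$yc)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i)
    pseudoF(pr$yc[sample(n), , drop = FALSE]), numeric(1))
  p <- (1 + sum(null >= fObs)) / (1 + nPerm)
  new("PermutationTestResult", statistic = fObs, pValue = p,
      nPermutations = as.integer(nPerm), seed = as.integer(seed),
      method = "RDA pseudo-F")
}

#' Fit environmental variables onto ordination axes
#'
#' Each variable is regressed on the ordination coordinates; r-squared is the
#' fraction of its variance explained by the axes (invariant to rotation of
#' the axes), with p by permuting the variable's values, as in vector fitting
#' of environmental gradients onto an ordination.
#'
#' @param coords samples-by-axes coordinate matrix (from [rdaAnalysis()] or
#'   [nmdsOrdination()]).
#' @param variables data.frame of numeric variables, rows aligned.
#' @param nPerm permutations per variable (default 999).
#' @param seed integer seed.
#' @return data.frame with columns `variable`, `r2`, `p`; constant variables
#'   get NA (reported absent, with a warning).
#' @export
fitVariables <- function(coords, variables, nPerm = 999L, seed = 1L) {
  if (is(coords, "OrdinationResult")) coords <- ordinationScores(coords)
  if (is(coords, "RdaResult")) coords <- coords@siteScores
  coords <- as.matrix(coords)
  n <- nrow(coords)
  Q <- qr.Q(qr(scale(coords, scale = FALSE)))
  variables <- as.data.frame(variables)
  set.seed(seed)
  out <- lapply(names(variables), function(v) {
    val <- variables[[v]]
    if (stats::sd(val) == 0) {
      warning("variable '", v, "' is constant; r2 undefined")
      return(data.frame(variable = v, r2 = NA_real_, p = NA_real_))
    }
    vc <- val - mean(val)
    r2 <- sum(crossprod(Q, vc)^2) / sum(vc^2)
    null <- vapply(seq_len(nPerm), function(i) {
      vp <- vc[sample(n)]
      sum(crossprod(Q, vp)^2) / sum(vp^2)
    }, numeric(1))
    data.frame(variable = v, r2 = r2,
               p = (1 + sum(null >= r2)) / (1 + nPerm))
  })
  do.call(rbind, out)
}
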