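#' @rdname pValue
#' @export
setMethod("pValue", "PermutationTestResult", function(x) x@pValue)

#' @rdname statistic
#' @export
setMethod("statistic", "PermutationTestResult", function(x) x@statistic)

setMethod("show", "PermutationTestResult", function(object) {
  cat(object@method, ": statistic =", signif(object@statistic, 4),
      ", p =", signif(object@pValue, 4),
      " (", object@nPermutations, "permutations, seed",
      object@seed, ")\n")
})

# all permutations of 1..n (n small), one per column
.permMatrix <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  res <- matrix(1L, 1, 1)
  for (m in 2:n) {
    prev <- res
    res <- matrix(0L, m, ncol(prev) * m)
    k <- 0L
    for (j in seq_len(ncol(prev))) for (pos in seq_len(m)) {
      k <- k + 1L
      res[, k] <- append(prev[, j], m, after = pos - 1L)
    }
  }
  res
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all between-sample distances and contrasts mean between-group and
#' within-group ranks: R = (rB - rW) / (n(n-1)/4), in [-1, 1], with R = 1
#' when all within-group distances are smaller than all between-group ones.
#' Significance by random relabeling of samples with
#' p = (1 + #\{R_null >= R_obs\}) / (1 + nPerm), or, with `exact = TRUE`
#' (n <= 8), by full enumeration of all label permutations (identity
#' included) with p = #\{R_null >= R_obs\} / n!.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups grouping factor; every group needs >= 2 samples.
#' @param nPerm number of random relabelings (ignored when exact).
#' @param seed integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return a [PermutationTestResult-class].
#' @export
anosimTest <- function(d, groups, nPerm = 999L, seed = 1L, exact = FALSE) {
  m <- .asDistanceMatrix(d)
  n <- nrow(m)
  groups <- as.factor(as.character(groups))
  if (length(groups) != n) stop("groups must have one label per sample")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2))
    stop("singleton group(s): ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  pr <- which(lower.tri(m), arr.ind = TRUE)
  rk <- rank(m[lower.tri(m)])
  denom <- n * (n - 1) / 4
  rStat <- function(g) {
    w <- g[pr[, 1]] == g[pr[, 2]]
    (mean(rk[!w]) - mean(rk[w])) / denom
  }
  rObs <- rStat(groups)
  gi <- as.integer(groups)
  if (exact) {
    P <- .permMatrix(n)
    null <- apply(P, 2, function(ix) rStat(gi[ix]))
    p <- mean(null >= rObs)
    return(new("PermutationTestResult", statistic = rObs, pValue = p,
               nPermutations = ncol(P), seed = NA_integer_,
               method = "ANOSIM (exact enumeration)"))
  }
  set.seed(seed)
  P <- vapply(seq_len(nPerm), function(i) sample(gi), integer(n))
  W <- P[pr[, 1], , drop = FALSE] == P[pr[, 2], , drop = FALSE]
  nW <- colSums(W)
  sW <- colSums(rk * W)
  null <- ((sum(rk) - sW) / (length(rk) - nW) - sW / nW) / denom
  p <- (1 + sum(null >= rObs)) / (1 + nPerm)
  new("PermutationTestResult", statistic = rObs, pValue = p,
      nPermutations = as.integer(nPerm), seed = as.integer(seed),
      method = "ANOSIM")
}

#' Mantel test between two distance matrices
#'
#' Statistic r = correlation (Pearson by default, Spearman optionally)
#' between the unraveled lower triangles. The null permutes the rows and
#' columns of the second matrix simultaneously; which matrix is permuted is
#' irrelevant to the null. One-sided p (greater):
#' p = (1 + #\{r_null >= r_obs\}) / (1 + nPerm).
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples in
#'   the same order (checked by labels when present).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @return a [PermutationTestResult-class].
#' @export
mantelTest <- function(d1, d2, nPerm = 999L, seed = 1L,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m1 <- .asDistanceMatrix(d1, "d1")
  m2 <- .asDistanceMatrix(d2, "d2")
  if (nrow(m1) != nrow(m2)) stop("d1 and d2 must cover the same samples")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop("mismatched sample ids between d1 and d2")
  v1 <- m1[lower.tri(m1)]
  if (method == "spearman") v1 <- rank(v1)
  v2full <- function(mm) {
    v <- mm[lower.tri(mm)]
    if (method == "spearman") rank(v) else v
  }
  v2 <- v2full(m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("degenerate input: constant distance matrix")
  rObs <- stats::cor(v1, v2)
  set.seed(seed)
  n <- nrow(m2)
  null <- vapply(seq_len(nPerm), function(i) {
    ix <- sample(n)
    stats::cor(v1, v2full(m2[ix, ix]))
  }, numeric(1))
  p <- (1 + sum(null >= rObs)) / (1 + nPerm)
  new("PermutationTestResult", statistic = rObs, pValue = p,
      nPermutations = as.integer(nPerm), seed = as.integer(seed),
      method = paste0("Mantel (", method, ")"))
}
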