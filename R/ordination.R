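#' Non-metric multidimensional scaling
#'
#' Kruskal NMDS (stress-1, monotone regression on distance ranks) via
#' [vegan::monoMDS], run from a metric (PCoA) start plus `nStarts - 1` random
#' starts; the lowest-stress solution is returned, Procrustes-rotated to the
#' PCoA start so the orientation is stable across runs, and column-centred.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param k embedding dimension (default 2); must be < number of samples.
#' @param nStarts number of starts (default 20).
#' @param maxIter maximum iterations per start.
#' @param tol convergence tolerance (stress ratio) passed to monoMDS.
#' @param seed integer seed for the random starts.
#' @return an [OrdinationResult-class].
#' @export
nmdsOrdination <- function(d, k = 2L, nStarts = 20L, maxIter = 500L,
                           tol = 1e-7, seed = 1L) {
  m <- .asDistanceMatrix(d)
  n <- nrow(m)
  if (k >= n) stop("k must be < number of samples")
  dd <- stats::as.dist(m)
  set.seed(seed)
  pcoa <- stats::cmdscale(dd, k = k)
  best <- NULL
  for (s in seq_len(nStarts)) {
    init <- if (s == 1) pcoa else matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          maxit = maxIter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rot <- vegan::procrustes(pcoa, coords, symmetric = FALSE)
  coords <- rot$Yrot
  coords <- sweep(coords, 2, colMeans(coords))
  dimnames(coords) <- list(rownames(m), paste0("NMDS", seq_len(k)))
  new("OrdinationResult", coordinates = coords, stress = best$stress,
      k = as.integer(k), converged = best$icause != 1L,
      seed = as.integer(seed), nStarts = as.integer(nStarts))
}

#' @rdname ordinationScores
#' @export
setMethod("ordinationScores", "OrdinationResult", function(x) x@coordinates)

setMethod("show", "OrdinationResult", function(object) {
  cat("NMDS ordination: k =", object@k, ", stress =",
      signif(object@stress, 4), ",", nrow(object@coordinates), "samples",
      if (!object@converged) "(not converged)", "\n")
})
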