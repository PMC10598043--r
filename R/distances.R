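#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i). Computed on relative abundances
#' by default, isolating composition from sequencing depth; `relative =
#' FALSE` uses raw counts.
#'
#' @param x an `OtuExperiment` or samples-by-OTUs matrix with >= 2 samples.
#' @param relative compute on per-sample proportions (default TRUE).
#' @return a `dist` over samples, values in [0, 1].
#' @export
brayCurtis <- function(x, relative = TRUE) {
  m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (relative) m <- relativeAbundance(m) else if (any(rowSums(m) == 0))
    stop("zero-sum sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Three-dimensional spatial distance between samples
#'
#' Longitude and latitude are converted to metres by a local equirectangular
#' projection about the centroid (1 deg latitude = 111,320 m, 1 deg longitude
#' = 111,320 * cos(mean latitude) m); elevation enters directly in metres.
#' The result is the pairwise Euclidean distance in 3-D.
#'
#' @param meta per-sample metadata (`DataFrame`/data.frame) with finite
#'   columns `longitude_deg`, `latitude_deg`, `elevation_m`.
#' @return a `dist` over samples, metres.
#' @export
spatialDistance <- function(meta) {
  meta <- as.data.frame(meta)
  need <- c("longitude_deg", "latitude_deg", "elevation_m")
  if (!all(need %in% colnames(meta)))
    stop("metadata lacks coordinate column(s): ",
         paste(setdiff(need, colnames(meta)), collapse = ", "))
  bad <- !stats::complete.cases(meta[, need]) |
    !apply(is.finite(as.matrix(meta[, need])), 1, all)
  if (any(bad))
    stop("missing coordinate(s) for sample(s): ",
         paste(rownames(meta)[bad], collapse = ", "))
  latBar <- mean(meta$latitude_deg) * pi / 180
  xyz <- cbind(meta$longitude_deg * 111320 * cos(latBar),
               meta$latitude_deg * 111320,
               meta$elevation_m)
  rownames(xyz) <- rownames(meta)
  stats::dist(xyz)
}

#' Environmental distance between samples
#'
#' Soil physicochemical variables and plant diversity indices give Euclidean
#' distance on z-standardized variables (so distances are invariant to affine
#' rescaling of any raw variable); tree and shrub species importance vectors
#' give Bray-Curtis dissimilarity on the importance values.
#'
#' @param meta per-sample metadata as produced by [simulateCovariates()] or
#'   [readSampleMetadata()].
#' @param variableSet one of `"soil_vars"`, `"plant_diversity"`,
#'   `"tree_importance"`, `"shrub_importance"`.
#' @return a `dist` over samples, or NULL (with a warning) when the variable
#'   set is absent from the metadata.
#' @export
environmentDistance <- function(meta,
                                variableSet = c("soil_vars", "plant_diversity",
                                                "tree_importance",
                                                "shrub_importance")) {
  variableSet <- match.arg(variableSet)
  if (variableSet %in% c("tree_importance", "shrub_importance")) {
    if (!variableSet %in% colnames(meta) ||
        anyNA(meta[[variableSet]])) {
      warning("variable set '", variableSet, "' absent from metadata; skipping")
      return(NULL)
    }
    imp <- as.matrix(meta[[variableSet]])
    rownames(imp) <- rownames(meta)
    return(vegan::vegdist(imp, method = "bray"))
  }
  cols <- if (variableSet == "soil_vars") .SOIL_VARS
          else grep("^plant_", colnames(meta), value = TRUE)
  cols <- intersect(cols, colnames(meta))
  df <- as.data.frame(meta)[, cols, drop = FALSE]
  if (!length(cols) || anyNA(df)) {
    warning("variable set '", variableSet, "' absent or incomplete; skipping")
    return(NULL)
  }
  z <- scale(as.matrix(df))
  constant <- attr(z, "scaled:scale") == 0
  z <- z[, !constant, drop = FALSE]
  if (!ncol(z)) {
    warning("all '", variableSet, "' variables constant; skipping")
    return(NULL)
  }
  d <- stats::dist(z)
  attr(d, "Labels") <- rownames(meta)
  d
}
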