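#' Construct an OtuExperiment
#'
#' @param counts integer matrix of read counts. Orientation is declared, not
#'   guessed: `orientation = "otus_as_rows"` (default, the Bioconductor/QIIME
#'   convention) or `"samples_as_rows"`.
#' @param sampleData optional `DataFrame`/`data.frame` of per-sample metadata,
#'   one row per sample (matched to sample ids by rownames or a `sample_id`
#'   column).
#' @param orientation orientation of `counts`.
#' @return an [OtuExperiment-class] with OTUs as rows and samples as columns.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L), 2, dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' oe <- OtuExperiment(m)
#' otuCounts(oe)[1:2, ]
#' @export
OtuExperiment <- function(counts, sampleData = NULL,
                          orientation = c("otus_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (orientation == "samples_as_rows") counts <- t(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    sd <- S4Vectors::DataFrame(sampleData)
    if ("sample_id" %in% colnames(sd)) rownames(sd) <- sd$sample_id
    if (is.null(rownames(sd)) || !all(colnames(counts) %in% rownames(sd)))
      stop("sampleData must cover every sample id in the count table")
    cd <- sd[colnames(counts), , drop = FALSE]
  }
  new("OtuExperiment",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd))
}

#' Read counts of an OtuExperiment
#'
#' @param x an `OtuExperiment`.
#' @param orientation orientation of the returned matrix; the canonical
#'   analysis orientation is `"samples_as_rows"` (default).
#' @return integer matrix.
#' @rdname otuCounts
#' @export
setMethod("otuCounts", "OtuExperiment",
  function(x, orientation = c("samples_as_rows", "otus_as_rows")) {
    orientation <- match.arg(orientation)
    m <- SummarizedExperiment::assay(x, "counts")
    if (orientation == "samples_as_rows") t(m) else m
  })

#' Sample metadata of an OtuExperiment
#'
#' @param x an `OtuExperiment`.
#' @return the `colData` `DataFrame`.
#' @rdname sampleData
#' @export
setMethod("sampleData", "OtuExperiment", function(x) SummarizedExperiment::colData(x))

#' Relative abundance table
#'
#' Converts read counts to per-sample proportions: `fractions[i, j] =
#' counts[i, j] / rowSums(counts)[i]` in the samples-by-OTUs orientation.
#' Every sample (row) then sums to 1; all abundance-gradient thresholds act on
#' this quantity.
#'
#' @param x an `OtuExperiment` or a samples-by-OTUs count matrix.
#' @return numeric matrix of proportions, samples as rows.
#' @examples
#' m <- matrix(c(2L, 2L, 0L, 5L), 2, byrow = TRUE,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' relativeAbundance(OtuExperiment(m))
#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "OtuExperiment", function(x) {
  relativeAbundance(otuCounts(x))
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "matrix", function(x) {
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("zero-sum sample(s): ", paste(bad, collapse = ", "))
  }
  x / rs
})

setMethod("show", "OtuExperiment", function(object) {
  cat("OtuExperiment:", nrow(object), "OTUs x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("soil_layer" %in% colnames(cd))
    cat("  layers:", paste(unique(cd$soil_layer), collapse = ", "), "\n")
  if ("stand_type" %in% colnames(cd)) {
    tb <- table(cd$stand_type)
    cat("  stand types:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  }
  cat("  total reads:", sum(SummarizedExperiment::assay(object, "counts")), "\n")
})

#' Subset an OtuExperiment to one soil layer
#'
#' @param x an `OtuExperiment` whose `colData` has a `soil_layer` column.
#' @param layer `"topsoil"` or `"subsoil"`.
#' @param dropEmpty drop OTUs with zero reads in the layer.
#' @return an `OtuExperiment`.
#' @export
layerSubset <- function(x, layer = c("topsoil", "subsoil"), dropEmpty = FALSE) {
  layer <- match.arg(layer)
  cd <- SummarizedExperiment::colData(x)
  if (!"soil_layer" %in% colnames(cd))
    stop("colData lacks a 'soil_layer' column")
  out <- x[, cd$soil_layer == layer]
  if (dropEmpty)
    out <- out[rowSums(SummarizedExperiment::assay(out, "counts")) > 0, ]
  out
}

#' Aggregate samples into resource states
#'
#' Sums counts within states before niche-breadth analysis. With
#' `stateDefinition = "sample"` (the default resource-state convention: one
#' quadrat = one state) the table is returned unchanged; with `"stand_type"`
#' samples are pooled by stand type, preserving total reads.
#'
#' @param x an `OtuExperiment`.
#' @param stateDefinition `"sample"` or `"stand_type"`.
#' @return an `OtuExperiment` over states; state order is fixed and recorded
#'   in `metadata(x)$state_order`.
#' @export
aggregateStates <- function(x, stateDefinition = c("sample", "stand_type")) {
  stateDefinition <- match.arg(stateDefinition)
  if (stateDefinition == "sample") {
    S4Vectors::metadata(x)$state_order <- colnames(x)
    return(x)
  }
  cd <- SummarizedExperiment::colData(x)
  if (!"stand_type" %in% colnames(cd))
    stop("every sample needs a stand_type label to aggregate by stand")
  if (any(is.na(cd$stand_type)))
    stop("sample(s) missing a stand_type label: ",
         paste(colnames(x)[is.na(cd$stand_type)], collapse = ", "))
  states <- intersect(.STAND_TYPES, unique(as.character(cd$stand_type)))
  m <- SummarizedExperiment::assay(x, "counts")
  agg <- vapply(states, function(s)
    rowSums(m[, cd$stand_type == s, drop = FALSE]), numeric(nrow(m)))
  out <- OtuExperiment(agg, sampleData = S4Vectors::DataFrame(
    stand_type = states, row.names = states))
  S4Vectors::metadata(out)$state_order <- states
  out
}
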