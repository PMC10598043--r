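#' Read a classic OTU table
#'
#' Reads a tab-separated OTU table with a header row of ids and a leading id
#' column. Classic QIIME-style tables put OTUs on rows; the orientation is
#' declared explicitly so the returned object is always canonical. A BIOM
#' file (JSON or HDF5) can be read through the same operation via
#' `format = "biom"` (requires the biomformat package).
#'
#' Counts must parse as non-negative integers; a non-numeric or negative cell
#' is an error naming the offending row and column, as is a duplicated id.
#'
#' @param path file path.
#' @param orientation orientation of the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return an [OtuExperiment-class].
#' @export
readOtuTable <- function(path, orientation = c("otus_as_rows", "samples_as_rows"),
                         format = c("tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    return(OtuExperiment(m, orientation = "otus_as_rows"))
  }
  lines <- readLines(path)
  # leading comment block: metadata lines, optionally ending in a
  # QIIME-style "#OTU ID" header row (the last commented line with a tab)
  top <- which(cumsum(!grepl("^#", lines)) == 0)
  hdr <- NULL
  if (length(top) && grepl("\t", lines[max(top)]))
    hdr <- sub("^#", "", lines[max(top)])
  body <- lines[setdiff(seq_along(lines), top)]
  raw <- utils::read.delim(text = paste(c(hdr, body), collapse = "\n"),
                           header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated id in leading column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(raw)[-1]))
    stop("duplicated id in header: ",
         paste(unique(colnames(raw)[-1][duplicated(colnames(raw)[-1])]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body),
                                 dimnames = list(ids, colnames(raw)[-1])))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at row '%s', column '%s': '%s'",
                 ids[bad[1]], colnames(num)[bad[2]], body[bad[1], bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s'",
                 rownames(num)[bad[1]], colnames(num)[bad[2]]))
  }
  if (any(num != round(num))) {
    bad <- which(num != round(num), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("non-integer count at row '%s', column '%s'; ",
                        "relative-abundance input must be converted to counts first"),
                 rownames(num)[bad[1]], colnames(num)[bad[2]]))
  }
  OtuExperiment(num, orientation = orientation)
}

#' Write an OTU table as TSV
#'
#' Writes the table OTUs-as-rows with a leading `#OTU ID` column and a header
#' comment recording the package version and any parameters supplied, so the
#' file round-trips bit-identically through [readOtuTable()].
#'
#' @param x an `OtuExperiment`.
#' @param path output path.
#' @param params optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path, params = list()) {
  m <- otuCounts(x, orientation = "otus_as_rows")
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
  .writeTsvWithHeader(df, path, params)
}

.writeTsvWithHeader <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("NicheGradients"))
  writeLines(paste0("# NicheGradients ", ver), con)
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), character(1)), sep = "=")
    writeLines(paste0("# ", paste(kv, collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV with required columns `sample_id`, `stand_type`, `soil_layer`
#' and optional covariate columns (coordinates, soil physicochemical
#' variables, plant diversity indices, species importance values). Vocabulary
#' columns are checked against the fixed sets (stand types S, CF, MF, BF;
#' layers topsoil, subsoil). Missing optional covariates stay absent (NA) and
#' downstream analyses that need them are skipped with a warning, never
#' silently imputed.
#'
#' @param path file path.
#' @return a `DataFrame`, one row per sample, rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "stand_type", "soil_layer")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  badStand <- setdiff(unique(df$stand_type), .STAND_TYPES)
  if (length(badStand))
    stop("unknown stand_type '", paste(badStand, collapse = "', '"),
         "'; allowed values: ", paste(.STAND_TYPES, collapse = ", "))
  badLayer <- setdiff(unique(df$soil_layer), .SOIL_LAYERS)
  if (length(badLayer))
    stop("unknown soil_layer '", paste(badLayer, collapse = "', '"),
         "'; allowed values: ", paste(.SOIL_LAYERS, collapse = ", "))
  for (cc in c("longitude_deg", "latitude_deg", "elevation_m"))
    if (cc %in% colnames(df) && any(!is.finite(df[[cc]])))
      stop("non-finite ", cc, " for sample(s): ",
           paste(df$sample_id[!is.finite(df[[cc]])], collapse = ", "))
  out <- S4Vectors::DataFrame(df, row.names = df$sample_id, check.names = FALSE)
  out$stand_type <- factor(out$stand_type, levels = .STAND_TYPES)
  out$soil_layer <- factor(out$soil_layer, levels = .SOIL_LAYERS)
  out
}
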