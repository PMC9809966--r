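#' Check channels of an event matrix against an expected channel set
#'
#' @param found channel names present in the data.
#' @param expected expected channel names (e.g. \code{defaultChannels()}).
#' @param alias optional named character vector mapping instrument channel
#'   names (names) to canonical names (values).
#' @return the (possibly alias-renamed) channel vector, invisibly; errors
#'   listing missing channels otherwise.
#' @keywords internal
.checkChannels <- function(found, expected, alias = NULL) {
  if (!is.null(alias)) {
    hit <- found %in% names(alias)
    found[hit] <- unname(alias[found[hit]])
  }
  missing <- setdiff(expected, found)
  if (length(missing))
    stop("channel mismatch: missing channel(s) ",
         paste(missing, collapse = ", "))
  found
}

#' Read flow-cytometry events
#'
#' Reads one acquisition from an FCS 3.0/3.1 file or from a TSV whose
#' header row names the channels. Events are returned in file order.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"fcs"} or \code{"tsv"}.
#' @param expected_channels optional channel set the file must contain
#'   (error listing absent channels otherwise); use
#'   \code{defaultChannels()} for the study's 23-parameter panel.
#' @param alias optional named character vector renaming instrument channel
#'   variants to canonical names before the check.
#' @param sample_id,vessel,timepoint,role,species sample metadata (see
#'   \code{\link{EventTable}}).
#' @param dilution_factor dilution applied before acquisition (>= 1).
#' @param acquired_volume_ul acquired volume in microlitres; for FCS input
#'   the $VOL keyword is used when present and this argument is missing.
#' @return An \linkS4class{EventTable}.
#' @export
readEvents <- function(path, format = c("auto", "fcs", "tsv"),
                       expected_channels = NULL, alias = NULL,
                       sample_id = basename(path), vessel = NA_character_,
                       timepoint = NA_real_, dilution_factor = 1,
                       acquired_volume_ul = NA_real_, role = "unknown",
                       species = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read events: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "tsv"
  if (format == "fcs") {
    parsed <- readFCS(path)
    m <- parsed$exprs
    if (is.na(acquired_volume_ul) && !is.na(parsed$volume_ul))
      acquired_volume_ul <- parsed$volume_ul
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  }
  if (!is.null(expected_channels))
    colnames(m) <- .checkChannels(colnames(m), expected_channels, alias)
  EventTable(m, sample_id = sample_id, vessel = vessel,
             timepoint = timepoint, dilution_factor = dilution_factor,
             acquired_volume_ul = acquired_volume_ul, role = role,
             species = species)
}

#' Write flow-cytometry events
#'
#' @param events an \linkS4class{EventTable}.
#' @param path output file.
#' @param format \code{"auto"} (by extension), \code{"fcs"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path, format = c("auto", "fcs", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "tsv"
  if (format == "fcs") {
    writeFCS(eventMatrix(events), path,
             volume_ul = sampleMeta(events)$acquired_volume_ul)
  } else {
    df <- as.data.frame(eventMatrix(events), check.names = FALSE)
    df[] <- lapply(df, function(x) sprintf("%.17g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.metaCols <- c("sample_id", "vessel", "timepoint", "replicate")

#' Read a samples x variables table from TSV
#'
#' The canonical tabular format: one header row; leading metadata columns
#' \code{sample_id}, \code{vessel}, \code{timepoint}, \code{replicate}
#' (any present are used); remaining columns are variables. Sample order is
#' preserved.
#'
#' @param path TSV file.
#' @param kind table kind (\code{"counts"}, \code{"relative"},
#'   \code{"absolute"}, \code{"concentration"}); value constraints are
#'   validated on read.
#' @return A \linkS4class{SampleTable}.
#' @export
readSampleTable <- function(path, kind) {
  if (!file.exists(path)) stop("cannot read table: file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  present <- intersect(.metaCols, names(df))
  meta <- if (length(present)) df[, present, drop = FALSE] else NULL
  vals <- df[, setdiff(names(df), present), drop = FALSE]
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at row %d, column '%s' of %s",
                 idx[1], colnames(m)[idx[2]], path))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row %d, column '%s' of %s",
                 idx[1], colnames(m)[idx[2]], path))
  }
  if (!is.null(meta) && "sample_id" %in% names(meta)) {
    rownames(m) <- meta$sample_id
  }
  SampleTable(m, kind = kind, meta = meta)
}

#' Write a samples x variables table to TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles exactly; row and column order are preserved.
#'
#' @param table a \linkS4class{SampleTable}.
#' @param path output TSV file.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(table, path) {
  meta <- sampleMeta(table)
  vals <- tableValues(table)
  out <- data.frame(meta[, intersect(.metaCols, names(meta)), drop = FALSE],
                    as.data.frame(vals, check.names = FALSE),
                    check.names = FALSE)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
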