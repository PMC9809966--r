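#' @import methods
NULL

#' Default flow-cytometry channel set
#'
#' The 23 scatter and fluorescence parameters recorded per event on the
#' CytoFLEX S instrument used throughout this package: area (-A) and height
#' (-H) for forward/side scatter and each fluorescence detector, plus the
#' forward-scatter signal width.
#'
#' @return Character vector of 23 channel names.
#' @export
#' @examples
#' defaultChannels()
defaultChannels <- function() {
  c("FSC-A", "FSC-H", "SSC-A", "SSC-H", "FL1-A", "FL1-H",
    "FL2-orange-A", "FL2-orange-H", "FL3-red-A", "FL3-red-H",
    "FL4-A", "FL4-H", "APC-A750-A", "APC-A750H", "VSSC-A", "VSSC-H",
    "KO525-A", "KO252-H", "mCherry-A", "mCherry-H", "PI-A", "PI-H",
    "FSC-Width")
}

.validChannels <- function(ch) {
  if (length(ch) == 0L) return("channel set must be non-empty")
  if (anyDuplicated(ch)) return("channel names must be unique")
  if (any(!nzchar(ch))) return("channel names must be non-empty strings")
  TRUE
}

#' EventTable: flow-cytometry events with sample metadata
#'
#' Holds one acquisition: an events x channels matrix of non-negative
#' scatter/fluorescence values plus the sample-level metadata needed for
#' volumetric quantification (dilution factor and acquired volume) and for
#' bookkeeping (vessel, timepoint, sample role).
#'
#' @slot exprs numeric matrix, events x channels; column names are the
#'   channel names.
#' @slot meta named list with elements \code{sample_id}, \code{vessel},
#'   \code{timepoint} (hours), \code{dilution_factor} (>= 1),
#'   \code{acquired_volume_ul} (microlitres, > 0 or NA when unknown),
#'   \code{role} (one of \code{"monoculture"}, \code{"blank"},
#'   \code{"community"}) and \code{species} (for monocultures).
#'
#' @export
setClass("EventTable",
  slots = c(exprs = "matrix", meta = "list"),
  validity = function(object) {
    m <- object@exprs
    if (!is.numeric(m)) return("event matrix must be numeric")
    ok <- .validChannels(colnames(m))
    if (!isTRUE(ok)) return(ok)
    if (anyNA(m)) return("event matrix must not contain missing values")
    if (nrow(m) > 0 && min(m) < 0) return("event values must be non-negative")
    md <- object@meta
    need <- c("sample_id", "vessel", "timepoint", "dilution_factor",
              "acquired_volume_ul", "role", "species")
    miss <- setdiff(need, names(md))
    if (length(miss)) return(paste("missing metadata fields:",
                                   paste(miss, collapse = ", ")))
    if (!is.na(md$dilution_factor) && md$dilution_factor < 1)
      return("dilution_factor must be >= 1")
    if (!is.na(md$acquired_volume_ul) && md$acquired_volume_ul <= 0)
      return("acquired_volume_ul must be > 0")
    if (!md$role %in% c("monoculture", "blank", "community", "unknown"))
      return("role must be monoculture, blank, community or unknown")
    TRUE
  })

#' Construct an EventTable
#'
#' @param exprs numeric matrix of events x channels; column names are taken
#'   as channel names.
#' @param sample_id,vessel,timepoint sample identity; timepoint in hours.
#' @param dilution_factor dimensionless dilution applied before acquisition
#'   (>= 1; the study diluted samples 100x in PBS).
#' @param acquired_volume_ul acquired sample volume in microlitres, needed
#'   for volumetric counting; NA when unknown.
#' @param role sample role: \code{"monoculture"}, \code{"blank"} or
#'   \code{"community"}.
#' @param species species label for monocultures, NA otherwise.
#' @return An \linkS4class{EventTable}.
#' @export
EventTable <- function(exprs, sample_id = NA_character_,
                       vessel = NA_character_, timepoint = NA_real_,
                       dilution_factor = 1, acquired_volume_ul = NA_real_,
                       role = "unknown", species = NA_character_) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  new("EventTable", exprs = exprs,
      meta = list(sample_id = as.character(sample_id),
                  vessel = as.character(vessel),
                  timepoint = as.numeric(timepoint),
                  dilution_factor = as.numeric(dilution_factor),
                  acquired_volume_ul = as.numeric(acquired_volume_ul),
                  role = as.character(role),
                  species = as.character(species)))
}

#' SampleTable: samples x variables matrix with metadata
#'
#' The common container for counts, relative abundances, absolute abundances
#' (cells/ml) and metabolite concentrations. Rows are samples (vessel x
#' timepoint x technical replicate), columns are taxa or metabolites.
#'
#' @slot values numeric matrix, samples x variables; row names are sample
#'   identifiers.
#' @slot meta data.frame aligned with rows; columns \code{sample_id},
#'   \code{vessel}, \code{timepoint}, \code{replicate}.
#' @slot kind one of \code{"counts"}, \code{"relative"}, \code{"absolute"},
#'   \code{"concentration"}. For \code{"relative"}, non-zero rows must sum
#'   to 1 within 1e-9; for \code{"counts"}, values must be non-negative
#'   integers.
#'
#' @export
setClass("SampleTable",
  slots = c(values = "matrix", meta = "data.frame", kind = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      return("variable (column) names must be present and unique")
    if (anyNA(v)) return("values must not contain missing entries")
    if (nrow(v) > 0 && min(v) < 0) {
      idx <- which(v < 0, arr.ind = TRUE)[1, ]
      return(sprintf("negative value at sample '%s', variable '%s'",
                     rownames(v)[idx[1]], colnames(v)[idx[2]]))
    }
    if (length(object@kind) != 1L ||
        !object@kind %in% c("counts", "relative", "absolute", "concentration"))
      return("kind must be counts, relative, absolute or concentration")
    if (object@kind == "counts" && nrow(v) > 0 &&
        max(abs(v - round(v))) > 1e-9) {
      idx <- which(abs(v - round(v)) > 1e-9, arr.ind = TRUE)[1, ]
      return(sprintf("non-integer count at sample '%s', variable '%s'",
                     rownames(v)[idx[1]], colnames(v)[idx[2]]))
    }
    if (object@kind == "relative" && nrow(v) > 0) {
      rs <- rowSums(v)
      bad <- which(rs > 0 & abs(rs - 1) > 1e-9)
      if (length(bad))
        return(sprintf("relative abundances of sample '%s' sum to %.12g, not 1",
                       rownames(v)[bad[1]], rs[bad[1]]))
    }
    if (nrow(object@meta) != nrow(v))
      return("meta must have one row per sample")
    TRUE
  })

#' Construct a SampleTable
#'
#' @param values numeric matrix (samples x variables) with row and column
#'   names, or a data.frame coercible to one.
#' @param kind table kind: \code{"counts"}, \code{"relative"},
#'   \code{"absolute"} or \code{"concentration"}.
#' @param meta optional data.frame with columns \code{sample_id},
#'   \code{vessel}, \code{timepoint}, \code{replicate}; parsed from row
#'   names of the form \code{vessel_timepoint_replicate} when omitted.
#' @return A \linkS4class{SampleTable}.
#' @export
SampleTable <- function(values, kind, meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(meta)) {
    meta <- data.frame(sample_id = rownames(values),
                       vessel = NA_character_, timepoint = NA_real_,
                       replicate = NA_integer_,
                       stringsAsFactors = FALSE)
    parts <- strsplit(rownames(values), "_", fixed = TRUE)
    if (all(lengths(parts) >= 3)) {
      meta$vessel <- vapply(parts, `[`, "", 1L)
      meta$timepoint <- suppressWarnings(
        as.numeric(vapply(parts, `[`, "", 2L)))
      meta$replicate <- suppressWarnings(
        as.integer(vapply(parts, `[`, "", 3L)))
    }
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta)) meta$sample_id <- rownames(values)
  }
  rownames(meta) <- NULL
  new("SampleTable", values = values, meta = meta, kind = kind)
}

#' GateModel: classifier ensemble separating cells from debris
#'
#' A small ensemble of binary random-forest classifiers trained on
#' monoculture (cell) versus blank (debris/background) events. Events are
#' retained when at least a configurable number of members vote "cell".
#'
#' @slot members list of fitted ranger models.
#' @slot channels channel names the members were trained on.
#' @slot heldOutAccuracy numeric, per-member accuracy on its held-out split.
#' @slot trainSizes named list: events used per class.
#' @export
setClass("GateModel",
  slots = c(members = "list", channels = "character",
            heldOutAccuracy = "numeric", trainSizes = "list"),
  validity = function(object) {
    if (length(object@members) < 1L) return("at least one member required")
    if (length(object@heldOutAccuracy) != length(object@members))
      return("one held-out accuracy per member required")
    TRUE
  })

#' SpeciesEnsemble: voting ensemble for species assignment
#'
#' A set of multiclass random-forest classifiers trained on independent
#' random draws from gated monoculture data. Community events are assigned
#' to a species only when at least \code{voteThreshold} members agree;
#' otherwise they are labelled \code{"unknown"}.
#'
#' @slot members list of fitted ranger models.
#' @slot speciesLabels ordered species labels.
#' @slot voteThreshold minimum agreeing votes for assignment (default 7
#'   of 10).
#' @slot heldOutAccuracy per-member accuracy on its held-out test split.
#' @slot channels channel names used for training.
#' @slot nTrain,nTest per-member training and test events per species.
#' @export
setClass("SpeciesEnsemble",
  slots = c(members = "list", speciesLabels = "character",
            voteThreshold = "integer", heldOutAccuracy = "numeric",
            channels = "character", nTrain = "integer", nTest = "integer"),
  validity = function(object) {
    k <- length(object@members)
    if (k < 1L) return("at least one member required")
    if (object@voteThreshold < 1L || object@voteThreshold > k)
      return("voteThreshold must be between 1 and the number of members")
    if (length(object@speciesLabels) < 2L)
      return("at least two species required")
    if (length(object@heldOutAccuracy) != k)
      return("one held-out accuracy per member required")
    TRUE
  })

#' ClassifiedCounts: per-species event counts with an unknown class
#'
#' @slot counts named numeric vector of per-species event counts.
#' @slot unknown number of events without a sufficient vote majority.
#' @slot labels optional per-event label vector (species or "unknown").
#' @slot meta sample metadata list carried over from the classified
#'   EventTable.
#' @export
setClass("ClassifiedCounts",
  slots = c(counts = "numeric", unknown = "numeric", labels = "character",
            meta = "list"),
  validity = function(object) {
    if (is.null(names(object@counts))) return("counts must be named")
    if (any(object@counts < 0) || object@unknown < 0)
      return("counts must be non-negative")
    if (length(object@labels) &&
        length(object@labels) != sum(object@counts) + object@unknown)
      return("labels length must equal total event count")
    TRUE
  })

#' CVTable: coefficient-of-variation matrix (timepoints x variables)
#'
#' One coefficient of variation per timepoint and variable, computed across
#' replicate vessels. Cells are NA when fewer than two vessels had a value
#' or the mean across vessels was zero.
#'
#' @slot values numeric matrix; row names are timepoints (hours), column
#'   names are variables (taxa or metabolites).
#' @slot method provenance label, e.g. \code{"HPLC"},
#'   \code{"cellscanner_rel"}, \code{"seq_rel"}.
#' @slot ddof degrees-of-freedom correction used for the standard deviation
#'   (1 = sample SD, 0 = population SD).
#' @export
setClass("CVTable",
  slots = c(values = "matrix", method = "character", ddof = "integer"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (any(v < 0, na.rm = TRUE)) return("CV values must be >= 0")
    if (!object@ddof %in% c(0L, 1L)) return("ddof must be 0 or 1")
    TRUE
  })

#' OrdinationResult: principal-coordinates embedding
#'
#' @slot coordinates samples x axes score matrix (axes with positive
#'   eigenvalues only).
#' @slot eigenvalues all eigenvalues in decreasing order (negative ones
#'   reported, their axes dropped from \code{coordinates}).
#' @slot proportionExplained fraction of the positive eigenvalue sum per
#'   retained axis.
#' @export
setClass("OrdinationResult",
  slots = c(coordinates = "matrix", eigenvalues = "numeric",
            proportionExplained = "numeric"))
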