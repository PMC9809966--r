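#' Accessors
#'
#' Small accessor generics for the package's S4 containers: the event
#' matrix, channel names, event count and sample metadata of an
#' \linkS4class{EventTable}; the value matrix, metadata and kind of a
#' \linkS4class{SampleTable}; the CV matrix of a \linkS4class{CVTable}.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))
#' @rdname accessors
#' @export
setMethod("eventMatrix", "EventTable", function(x) x@exprs)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EventTable", function(x) colnames(x@exprs))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@exprs))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setMethod("sampleMeta", "EventTable", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("sampleMeta", "SampleTable", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("sampleMeta", "ClassifiedCounts", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("tableValues", function(x) standardGeneric("tableValues"))
#' @rdname accessors
#' @export
setMethod("tableValues", "SampleTable", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("tableValues", "CVTable", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("tableKind", function(x) standardGeneric("tableKind"))
#' @rdname accessors
#' @export
setMethod("tableKind", "SampleTable", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))
#' @rdname accessors
#' @export
setMethod("speciesCounts", "ClassifiedCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("unknownCount", function(x) standardGeneric("unknownCount"))
#' @rdname accessors
#' @export
setMethod("unknownCount", "ClassifiedCounts", function(x) x@unknown)

#' @rdname accessors
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))
#' @rdname accessors
#' @export
setMethod("eventLabels", "ClassifiedCounts", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))
#' @rdname accessors
#' @export
setMethod("speciesLabels", "SpeciesEnsemble", function(x) x@speciesLabels)

#' @rdname accessors
#' @export
setGeneric("voteThreshold", function(x) standardGeneric("voteThreshold"))
#' @rdname accessors
#' @export
setMethod("voteThreshold", "SpeciesEnsemble", function(x) x@voteThreshold)

#' @rdname accessors
#' @export
setGeneric("heldOutAccuracy", function(x) standardGeneric("heldOutAccuracy"))
#' @rdname accessors
#' @export
setMethod("heldOutAccuracy", "SpeciesEnsemble", function(x) x@heldOutAccuracy)
#' @rdname accessors
#' @export
setMethod("heldOutAccuracy", "GateModel", function(x) x@heldOutAccuracy)

#' @rdname accessors
#' @export
setGeneric("ordCoordinates", function(x) standardGeneric("ordCoordinates"))
#' @rdname accessors
#' @export
setMethod("ordCoordinates", "OrdinationResult", function(x) x@coordinates)

#' @rdname accessors
#' @export
setGeneric("ordEigenvalues", function(x) standardGeneric("ordEigenvalues"))
#' @rdname accessors
#' @export
setMethod("ordEigenvalues", "OrdinationResult", function(x) x@eigenvalues)

setMethod("show", "EventTable", function(object) {
  md <- object@meta
  cat(sprintf("EventTable: %d events x %d channels\n",
              nrow(object@exprs), ncol(object@exprs)))
  cat(sprintf("  sample: %s (vessel %s, %s h, role %s)\n",
              md$sample_id, md$vessel, format(md$timepoint), md$role))
  cat(sprintf("  dilution %sx, acquired volume %s ul\n",
              format(md$dilution_factor), format(md$acquired_volume_ul)))
})

setMethod("show", "SampleTable", function(object) {
  cat(sprintf("SampleTable (%s): %d samples x %d variables\n",
              object@kind, nrow(object@values), ncol(object@values)))
  cat("  variables:", paste(utils::head(colnames(object@values), 8),
                            collapse = ", "),
      if (ncol(object@values) > 8) "..." else "", "\n")
})

setMethod("show", "GateModel", function(object) {
  cat(sprintf("GateModel: %d members, held-out accuracy %.3f-%.3f\n",
              length(object@members), min(object@heldOutAccuracy),
              max(object@heldOutAccuracy)))
})

setMethod("show", "SpeciesEnsemble", function(object) {
  cat(sprintf(
    "SpeciesEnsemble: %d members, %d species (%s), vote threshold %d\n",
    length(object@members), length(object@speciesLabels),
    paste(object@speciesLabels, collapse = ", "), object@voteThreshold))
  cat(sprintf("  held-out accuracy: %.3f-%.3f (train %d / test %d per species)\n",
              min(object@heldOutAccuracy), max(object@heldOutAccuracy),
              object@nTrain, object@nTest))
})

setMethod("show", "ClassifiedCounts", function(object) {
  tot <- sum(object@counts) + object@unknown
  cat(sprintf("ClassifiedCounts: %d events (%d unknown)\n",
              tot, object@unknown))
  print(object@counts)
})

setMethod("show", "CVTable", function(object) {
  cat(sprintf("CVTable [%s, ddof=%d]: %d timepoints x %d variables\n",
              object@method, object@ddof, nrow(object@values),
              ncol(object@values)))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples, %d retained axes\n",
              nrow(object@coordinates), ncol(object@coordinates)))
  pe <- object@proportionExplained[seq_len(min(
    2L, length(object@proportionExplained)))]
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * pe), collapse = ", "), "\n")
})
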