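# From raw counts to comparable abundances: volumetric cell densities,
# contaminant filtering, 16S copy-number correction, relative and absolute
# abundance tables.

#' Volumetric cell density
#'
#' cells/ml = (events / acquired volume in ul) * dilution factor * 1000.
#'
#' @param n_events number of gated events.
#' @param acquired_volume_ul acquired volume in microlitres (> 0).
#' @param dilution_factor dilution applied before acquisition (>= 1; the
#'   study diluted samples 100x in PBS).
#' @return cell density in cells per millilitre.
#' @export
#' @examples
#' volumetricCount(2000, 20, 100)  # 1e7 cells/ml
volumetricCount <- function(n_events, acquired_volume_ul,
                            dilution_factor = 1) {
  if (is.na(acquired_volume_ul) || acquired_volume_ul <= 0)
    stop("acquired_volume_ul must be > 0")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  (n_events / acquired_volume_ul) * dilution_factor * 1000
}

#' Read a species -> 16S copy-number table
#'
#' Two-column TSV (\code{species}, \code{copy_number}); values must be
#' positive. The copy numbers shipped in
#' \code{inst/extdata/copy_numbers_synthetic.tsv} are synthetic
#' placeholders for the study species and should be replaced with
#' strain-exact values from rrnDB for real analyses.
#'
#' @param path TSV file path.
#' @return named numeric vector (species -> copy number).
#' @export
readCopyNumbers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "copy_number") %in% names(df)))
    stop("copy-number table needs columns 'species' and 'copy_number'")
  cn <- stats::setNames(as.numeric(df$copy_number), df$species)
  if (anyNA(cn) || any(cn <= 0))
    stop("copy numbers must be positive")
  cn
}

#' Filter contaminant taxa from a count table
#'
#' In a defined community, taxa that are not community members are assumed
#' to be contaminants introduced by the sequencing pipeline and are removed
#' -- unless they were identified (non-zero count) in more than one sample
#' across the experiment, in which case they are retained as genuine
#' (the persistent-contaminant case). Member taxa are always retained,
#' even when absent everywhere. Idempotent.
#'
#' @param counts a \linkS4class{SampleTable} of kind \code{"counts"}.
#' @param members character vector of community member taxa.
#' @return filtered \linkS4class{SampleTable} (column subset; order
#'   preserved).
#' @export
filterContaminants <- function(counts, members) {
  stopifnot(tableKind(counts) == "counts")
  v <- tableValues(counts)
  n_samples_present <- colSums(v > 0)
  keep <- colnames(v) %in% members | n_samples_present >= 2L
  SampleTable(v[, keep, drop = FALSE], kind = "counts",
              meta = sampleMeta(counts))
}

#' 16S copy-number correction
#'
#' Divides each taxon's counts by its 16S rRNA gene copy number and
#' renormalises each sample to sum to 1, de-biasing composition for
#' operon-count differences. Scale-invariant per sample. All-zero samples
#' cannot be normalised; they are dropped from the output with a warning
#' (their ids are recorded in the \code{"dropped_samples"} attribute).
#'
#' @param counts a \linkS4class{SampleTable} of kind \code{"counts"}.
#' @param copies named numeric vector (species -> copy number > 0); every
#'   taxon in \code{counts} must be present.
#' @return a \linkS4class{SampleTable} of kind \code{"relative"}.
#' @export
#' @examples
#' tab <- SampleTable(matrix(c(100, 100), 1, dimnames = list("s1", c("A", "B"))),
#'                    kind = "counts")
#' tableValues(correctCopyNumber(tab, c(A = 5, B = 2)))  # 2/7, 5/7
correctCopyNumber <- function(counts, copies) {
  stopifnot(tableKind(counts) == "counts")
  v <- tableValues(counts)
  missing <- setdiff(colnames(v), names(copies))
  if (length(missing))
    stop("missing copy number for taxon: ",
         paste(missing, collapse = ", "))
  cps <- copies[colnames(v)]
  if (any(cps <= 0)) stop("copy numbers must be positive")
  corrected <- sweep(v, 2L, cps, "/")
  rs <- rowSums(corrected)
  dropped <- rownames(v)[rs == 0]
  if (length(dropped))
    warning("dropping all-zero sample(s): ", paste(dropped, collapse = ", "))
  keep <- rs > 0
  rel <- corrected[keep, , drop = FALSE] / rs[keep]
  out <- SampleTable(rel, kind = "relative",
                     meta = sampleMeta(counts)[keep, , drop = FALSE])
  attr(out, "dropped_samples") <- dropped
  out
}

#' Scale relative abundances to absolute abundances
#'
#' Multiplies each sample's relative abundances by its total cell density
#' from flow cytometry; per-sample row sums then equal the totals.
#'
#' @param rel a \linkS4class{SampleTable} of kind \code{"relative"}.
#' @param totals named numeric vector of total cell densities (cells/ml),
#'   named by sample id; every sample in \code{rel} must have a total.
#' @return a \linkS4class{SampleTable} of kind \code{"absolute"} (cells/ml).
#' @export
toAbsolute <- function(rel, totals) {
  stopifnot(tableKind(rel) == "relative")
  v <- tableValues(rel)
  ids <- rownames(v)
  missing <- setdiff(ids, names(totals))
  if (length(missing))
    stop("missing total cell count for sample: ",
         paste(missing, collapse = ", "))
  tt <- totals[ids]
  if (any(is.na(tt) | tt < 0)) stop("totals must be non-negative")
  SampleTable(v * tt, kind = "absolute", meta = sampleMeta(rel))
}

#' Classified event counts to abundance rows
#'
#' Converts one sample's \linkS4class{ClassifiedCounts} into relative
#' abundances -- with the unknown class as its own category, and with
#' unknowns excluded and the species renormalised -- plus an absolute
#' variant scaling the including-unknown proportions by the sample's total
#' cell density.
#'
#' @param counts a \linkS4class{ClassifiedCounts}.
#' @param total_cells_per_ml the sample's total cell density (cells/ml).
#' @return list with \code{rel_with_unknown}, \code{rel_without_unknown}
#'   (NULL, flagged via \code{missing_reason}, when every event was
#'   unknown), \code{abs_with_unknown} and \code{missing_reason} (NA when
#'   the sample is usable). Zero gated events flag the sample as missing.
#' @export
classifiedToAbundance <- function(counts, total_cells_per_ml = NA_real_) {
  sp <- speciesCounts(counts)
  unk <- unknownCount(counts)
  total <- sum(sp) + unk
  if (total == 0)
    return(list(rel_with_unknown = NULL, rel_without_unknown = NULL,
                abs_with_unknown = NULL,
                missing_reason = "zero gated events"))
  with_unknown <- c(sp, unknown = unk) / total
  without_unknown <- if (sum(sp) > 0) sp / sum(sp) else NULL
  list(rel_with_unknown = with_unknown,
       rel_without_unknown = without_unknown,
       abs_with_unknown = if (!is.na(total_cells_per_ml))
         with_unknown * total_cells_per_ml else NULL,
       missing_reason = if (sum(sp) == 0) "all events unknown" else
         NA_character_)
}
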