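#' Coefficient of variation
#'
#' CV = sd/mean, the scale-free dispersion measure used to compare
#' across-vessel variability of metabolite concentrations and species
#' abundances between quantification methods.
#'
#' @param values numeric vector (at least two non-missing values for a
#'   defined result).
#' @param ddof degrees-of-freedom correction: 1 (default, sample SD) or 0
#'   (population SD).
#' @return CV as a single number; NA (with a warning for a zero mean) when
#'   undefined.
#' @export
#' @examples
#' coefficientOfVariation(c(2, 4, 6))  # 0.5
coefficientOfVariation <- function(values, ddof = 1L) {
  stopifnot(ddof %in% c(0L, 1L))
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) {
    warning("zero mean; coefficient of variation undefined")
    return(NA_real_)
  }
  s <- stats::sd(x)
  if (ddof == 0L) s <- s * sqrt((n - 1) / n)
  s / m
}

#' Coefficient-of-variation table across vessels
#'
#' For each timepoint x variable cell, computes the CV of the values
#' observed across replicate vessels. A cell is NA when fewer than two
#' vessels contributed a value, or the across-vessel mean is zero.
#'
#' @param data a \linkS4class{SampleTable} whose metadata carries
#'   \code{vessel} and \code{timepoint}; if several technical replicates
#'   are present, filter to one replicate first (see \code{replicate}).
#' @param ddof degrees-of-freedom correction for the SD (default 1).
#' @param method provenance label stored in the result (e.g. "HPLC",
#'   "cellscanner_rel", "seq_rel").
#' @param replicate optional technical replicate id to restrict to.
#' @param na_zero_rows treat all-zero sample rows as missing (drop them
#'   from every cell) rather than as observed zeros; default FALSE.
#' @return A \linkS4class{CVTable} (timepoints x variables).
#' @export
cvTable <- function(data, ddof = 1L, method = NA_character_,
                    replicate = NULL, na_zero_rows = FALSE) {
  meta <- sampleMeta(data)
  vals <- tableValues(data)
  if (!all(c("vessel", "timepoint") %in% names(meta)))
    stop("sample metadata must provide vessel and timepoint")
  keep <- rep(TRUE, nrow(vals))
  if (!is.null(replicate) && "replicate" %in% names(meta))
    keep <- keep & meta$replicate == replicate
  if (na_zero_rows) keep <- keep & rowSums(vals) > 0
  vals <- vals[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  tps <- sort(unique(meta$timepoint))
  out <- matrix(NA_real_, length(tps), ncol(vals),
                dimnames = list(as.character(tps), colnames(vals)))
  for (i in seq_along(tps)) {
    rows <- meta$timepoint == tps[i]
    for (j in seq_len(ncol(vals))) {
      x <- vals[rows, j]
      x <- x[!is.na(x)]
      if (length(x) >= 2 && mean(x) != 0)
        out[i, j] <- suppressWarnings(coefficientOfVariation(x, ddof))
    }
  }
  new("CVTable", values = out, method = as.character(method),
      ddof = as.integer(ddof))
}

#' Aggregate a CV table
#'
#' Row (per-timepoint), column (per-variable) and grand means of a CV
#' table, ignoring missing cells — the machine analogue of the "Average per
#' timepoint" / "Average per strain or metabolite" margins of printed CV
#' tables.
#'
#' @param table a \linkS4class{CVTable} or a plain numeric matrix of CV
#'   values (timepoints x variables, NA for missing).
#' @param exclude variables (columns) to drop before averaging, e.g.
#'   contaminant or inconsistently detected taxa.
#' @return list with \code{row_means} (per timepoint), \code{col_means}
#'   (per variable) and \code{grand_mean} (mean over all non-missing
#'   cells). Aggregates over all-missing rows/columns are NA.
#' @export
aggregateCV <- function(table, exclude = character(0)) {
  v <- if (is(table, "CVTable")) tableValues(table) else as.matrix(table)
  if (length(v) == 0) stop("empty CV table")
  if (length(exclude))
    v <- v[, setdiff(colnames(v), exclude), drop = FALSE]
  rm_ <- rowMeans(v, na.rm = TRUE)
  cm <- colMeans(v, na.rm = TRUE)
  rm_[!is.finite(rm_)] <- NA_real_
  cm[!is.finite(cm)] <- NA_real_
  gm <- mean(v, na.rm = TRUE)
  if (!is.finite(gm)) gm <- NA_real_
  list(row_means = rm_, col_means = cm, grand_mean = gm)
}

#' Compare CV distributions of two methods
#'
#' Pairs the CV cells of two methods on their shared (timepoint, variable)
#' cells and runs the paired Wilcoxon signed-rank test, reporting whether
#' the first method's CVs exceed the second's — the comparison behind the
#' finding that sequencing variability exceeds cytometry variability.
#'
#' @param cv_a,cv_b \linkS4class{CVTable}s (or numeric matrices) to compare;
#'   the one-sided alternative is "cv_a exceeds cv_b".
#' @param min_cells minimum number of shared non-missing cells (default 5).
#' @return list with the shared cell ids, both CV vectors,
#'   \code{mean_ratio} (mean of cv_a / mean of cv_b), \code{p_two_sided},
#'   \code{p_one_sided} (greater), and the underlying test results.
#' @export
compareMethodsCV <- function(cv_a, cv_b, min_cells = 5L) {
  va <- if (is(cv_a, "CVTable")) tableValues(cv_a) else as.matrix(cv_a)
  vb <- if (is(cv_b, "CVTable")) tableValues(cv_b) else as.matrix(cv_b)
  rows <- intersect(rownames(va), rownames(vb))
  cols <- intersect(colnames(va), colnames(vb))
  if (!length(rows) || !length(cols))
    stop("the two CV tables share no (timepoint, variable) cells")
  a <- as.vector(va[rows, cols, drop = FALSE])
  b <- as.vector(vb[rows, cols, drop = FALSE])
  cells <- as.vector(outer(rows, cols, paste, sep = ":"))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_cells)
    stop("fewer than ", min_cells, " shared non-missing CV cells")
  a <- a[ok]; b <- b[ok]; cells <- cells[ok]
  two <- pairedWilcoxon(a, b, alternative = "two.sided")
  one <- pairedWilcoxon(a, b, alternative = "greater")
  list(cells = cells, cv_a = a, cv_b = b,
       mean_ratio = mean(a) / mean(b),
       p_two_sided = two$p.value, p_one_sided = one$p.value,
       test_two_sided = two, test_greater = one)
}

#' Population heterogeneity from channel ranges
#'
#' Quantifies within-sample heterogeneity of a gated acquisition as the
#' per-channel range (max - min over events), aggregated over the channels
#' by their mean (default) or their sum. The two aggregations differ only
#' by the factor "number of channels"; outputs are labelled with the
#' variant used.
#'
#' @param events gated \linkS4class{EventTable}.
#' @param aggregation \code{"mean"} or \code{"sum"} over channels.
#' @return list with \code{value} (channel units), \code{aggregation} and
#'   \code{sample_id}; value is NA for an empty input.
#' @export
heterogeneity <- function(events, aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  m <- eventMatrix(events)
  if (nrow(m) == 0)
    return(list(value = NA_real_, aggregation = aggregation,
                sample_id = sampleMeta(events)$sample_id))
  rng <- apply(m, 2L, function(x) max(x) - min(x))
  val <- if (aggregation == "mean") mean(rng) else sum(rng)
  list(value = val, aggregation = aggregation,
       sample_id = sampleMeta(events)$sample_id)
}

#' Correlation between two abundance series
#'
#' Method-agreement correlation (e.g. sequencing versus cytometry
#' abundances of one species over all samples).
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r}, \code{p} (two-sided) and \code{n}; NA with a
#'   warning when a series is constant.
#' @export
methodCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
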