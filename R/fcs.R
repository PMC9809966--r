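# Minimal FCS 3.0/3.1 list-mode reader/writer.
# Supports $DATATYPE F (float32), D (float64) and I (8/16/32/64-bit
# unsigned integers), $MODE L, and both common byte orders (1,2,3,4 and
# 4,3,2,1). Spillover/compensation and transformation keywords are carried
# in the keyword list but never applied: downstream classification works on
# raw channel values.

.fcsParseText <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1L, 1L)
  body <- substring(txt, 2L)
  # a doubled delimiter escapes a literal delimiter inside a value; split
  # and re-join empty tokens accordingly
  tokens <- strsplit(body, delim, fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[i]
    while (i < length(tokens) && tokens[i + 1L] == "" &&
           i + 1L < length(tokens)) {
      tok <- paste0(tok, delim, tokens[i + 2L])
      i <- i + 2L
    }
    out <- c(out, tok)
    i <- i + 1L
  }
  if (length(out) %% 2L == 1L) out <- out[-length(out)]
  keys <- out[seq(1L, length(out), by = 2L)]
  vals <- out[seq(2L, length(out), by = 2L)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

.fcsKeyword <- function(kw, name, default = NULL) {
  v <- kw[[toupper(name)]]
  if (is.null(v)) default else v
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses header, TEXT and DATA segments of a list-mode FCS file and
#' returns the event matrix with channel names taken from the short-name
#' keywords ($PnN).
#'
#' @param path path to the FCS file.
#' @return list with \code{exprs} (events x channels matrix),
#'   \code{keywords} (named list of all TEXT keywords) and
#'   \code{volume_ul} (acquired volume in microlitres from the $VOL
#'   keyword, which FCS stores in nanolitres; NA when absent).
#' @export
readFCS <- function(path) {
  if (!file.exists(path)) stop("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version or corrupt file: ", path,
         " (header '", substr(header, 1, 6), "')")
  offs <- suppressWarnings(as.numeric(c(
    substr(header, 11L, 18L), substr(header, 19L, 26L),
    substr(header, 27L, 34L), substr(header, 35L, 42L))))
  if (anyNA(offs[1:2])) stop("corrupt FCS header in ", path)
  seek(con, offs[1])
  kw <- .fcsParseText(readBin(con, "raw", n = offs[2] - offs[1] + 1L))

  data_beg <- as.numeric(.fcsKeyword(kw, "$BEGINDATA", offs[3]))
  data_end <- as.numeric(.fcsKeyword(kw, "$ENDDATA", offs[4]))
  if (is.na(data_beg) || data_beg == 0) data_beg <- offs[3]
  if (is.na(data_end) || data_end == 0) data_end <- offs[4]

  npar <- as.integer(.fcsKeyword(kw, "$PAR"))
  ntot <- as.integer(.fcsKeyword(kw, "$TOT"))
  dtype <- .fcsKeyword(kw, "$DATATYPE", "F")
  mode <- .fcsKeyword(kw, "$MODE", "L")
  if (!identical(mode, "L")) stop("only list-mode ($MODE L) FCS supported")
  byteord <- .fcsKeyword(kw, "$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  chn <- vapply(seq_len(npar), function(i) {
    v <- .fcsKeyword(kw, sprintf("$P%dN", i))
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))

  seek(con, data_beg)
  nvals <- npar * ntot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = nvals, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = nvals, size = 8L, endian = endian),
    I = {
      bits <- as.integer(.fcsKeyword(kw, "$P1B", "32"))
      size <- bits %/% 8L
      if (!size %in% c(1L, 2L, 4L, 8L))
        stop("unsupported $PnB bit width: ", bits)
      if (size == 8L)
        readBin(con, "numeric", n = nvals, size = 8L, endian = endian)
      else
        readBin(con, "integer", n = nvals, size = size, endian = endian,
                signed = size == 4L)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(vals) < nvals)
    stop("truncated DATA segment in ", path)
  m <- matrix(as.numeric(vals), nrow = ntot, ncol = npar, byrow = TRUE,
              dimnames = list(NULL, chn))
  vol <- suppressWarnings(as.numeric(.fcsKeyword(kw, "$VOL", NA)))
  list(exprs = m, keywords = kw, volume_ul = vol / 1000)
}

#' Write an FCS 3.1 file
#'
#' Writes an events x channels matrix as a little-endian float32 list-mode
#' FCS 3.1 file; used mainly to produce synthetic acquisitions.
#'
#' @param exprs numeric events x channels matrix with channel names as
#'   column names.
#' @param path output path.
#' @param volume_ul acquired volume in microlitres, stored as the $VOL
#'   keyword (nanolitres); omitted when NA.
#' @param extra_keywords optional named character vector of additional TEXT
#'   keywords.
#' @return \code{path}, invisibly.
#' @export
writeFCS <- function(exprs, path, volume_ul = NA_real_,
                     extra_keywords = character(0)) {
  exprs <- as.matrix(exprs)
  npar <- ncol(exprs)
  ntot <- nrow(exprs)
  if (is.null(colnames(exprs))) stop("channel names required")
  kw <- c("$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
          "$NEXTDATA" = "0")
  rng <- as.character(max(262144, ceiling(max(exprs, 0) + 1)))
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- colnames(exprs)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- rng
  }
  if (!is.na(volume_ul)) kw["$VOL"] <- format(volume_ul * 1000, digits = 12)
  if (length(extra_keywords)) kw[names(extra_keywords)] <- extra_keywords
  data_bytes <- npar * ntot * 4L

  build_text <- function(beg_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = as.character(beg_data),
             "$ENDDATA" = as.character(end_data))
    paste0("/", paste0(names(kw2), "/", unname(kw2), "/", collapse = ""))
  }
  # iterate because the data offsets appear inside the TEXT segment
  text_beg <- 58L
  txt <- build_text(0, 0)
  for (i in 1:3) {
    text_end <- text_beg + nchar(txt, type = "bytes") - 1L
    data_beg <- text_end + 1L
    data_end <- data_beg + data_bytes - 1L
    txt2 <- build_text(data_beg, data_end)
    if (nchar(txt2, type = "bytes") == nchar(txt, type = "bytes")) {
      txt <- txt2
      break
    }
    txt <- txt2
  }
  text_end <- text_beg + nchar(txt, type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + data_bytes - 1L

  fmt8 <- function(x) formatC(x, width = 8L)
  header <- paste0("FCS3.1    ", fmt8(text_beg), fmt8(text_end),
                   if (data_end <= 99999999) fmt8(data_beg) else fmt8(0),
                   if (data_end <= 99999999) fmt8(data_end) else fmt8(0),
                   fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(exprs)), con, size = 4L, endian = "little")
  invisible(path)
}
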