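#' Read cytometry events from FCS or CSV
#'
#' CSV files must carry a header row of channel names; FCS files are parsed
#' by a minimal FCS 3.0/3.1 reader (list mode, float/double data, TEXT and
#' DATA segments, `$PnN`/`$PnS` channel naming).
#'
#' @param path file to read.
#' @param format `"csv"` or `"fcs"`; default guesses from the extension.
#' @param sample_id sample id to attach; defaults to the file name.
#' @return a raw [event_table()].
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (is.null(sample_id)) sample_id <- basename(path)
  if (file.size(path) == 0)
    stop("I/O error reading '", path, "': empty file (0 bytes)")
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    if (!ncol(df)) stop("I/O error reading '", path, "': no columns")
    if (anyDuplicated(names(df)))
      stop("duplicate channel names in ", path)
    m <- as.matrix(df)
    storage.mode(m) <- "double"
    event_table(m, sample_id)
  } else {
    read_fcs(path, sample_id)
  }
}

#' Write an event table as CSV
#'
#' @param t an [event_table()].
#' @param path output file.
#' @export
write_events_csv <- function(t, path) {
  stopifnot_event_table(t)
  write.csv(as.data.frame(t$values), path, row.names = FALSE)
  invisible(path)
}

#' Write an event table as FCS 3.1
#'
#' Minimal list-mode writer (32-bit float data, little-endian).  Intended
#' for synthetic cohorts and round-trip testing rather than as a general
#' cytometer-grade exporter.
#'
#' @param t a raw [event_table()].
#' @param path output file.
#' @export
write_fcs <- function(t, path) {
  stopifnot_event_table(t)
  v <- t$values
  n <- nrow(v); p <- ncol(v)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (j in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", j), colnames(v)[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(max(1, ceiling(max(abs(v[, j]), 1))),
                                        scientific = FALSE))
  }
  delim <- "/"
  build_text <- function(bd, ed) {
    kk <- kw
    kk[kk == "%BD%"] <- sprintf("%010d", bd)
    kk[kk == "%ED%"] <- sprintf("%010d", ed)
    paste0(delim, paste(kk, collapse = delim), delim)
  }
  header_len <- 58L  # "FCS3.1    " + 6 offset fields of 8 chars
  text0 <- build_text(0L, 0L)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  text <- build_text(data_begin, data_end)
  stopifnot(nchar(text) == nchar(text0))  # fixed-width offsets keep length stable
  off <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", off(text_begin), off(text_end),
                   if (data_end <= 99999999) paste0(off(data_begin), off(data_end))
                   else paste0(off(0), off(0)),
                   off(0), off(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(v)), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs <- function(path, sample_id = basename(path)) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header) < 58L || !grepl("^FCS3\\.[01]", header))
    stop("I/O error reading '", path, "': not an FCS 3.x file (bad header at byte 0)")
  offs <- suppressWarnings(as.integer(substring(header,
                                                seq(11, 51, by = 8),
                                                seq(18, 58, by = 8))))
  text_begin <- offs[1]; text_end <- offs[2]
  if (is.na(text_begin) || is.na(text_end) || text_end <= text_begin ||
      text_end >= sz)
    stop("I/O error reading '", path, "': truncated TEXT segment (offsets ",
         text_begin, "-", text_end, ")")
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("I/O error reading '", path, "': empty TEXT segment")
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, toupper(trimws(keys)))
  need <- function(k) {
    if (is.na(kw[k])) stop("I/O error reading '", path, "': missing keyword ", k)
    kw[[k]]
  }
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "' (only F and D)")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4")) "little" else "big"
  ch <- character(p)
  for (j in seq_len(p)) {
    nm <- kw[sprintf("$P%dN", j)]
    alt <- kw[sprintf("$P%dS", j)]
    ch[j] <- if (!is.na(nm) && nzchar(nm)) nm else alt
  }
  if (anyDuplicated(ch)) stop("duplicate channel names in ", path)
  data_begin <- as.integer(kw["$BEGINDATA"])
  if (is.na(data_begin) || data_begin == 0L) data_begin <- offs[3]
  word <- if (dtype == "F") 4L else 8L
  if (is.na(data_begin) || data_begin + word * n * p - 1 >= sz + 1)
    stop("I/O error reading '", path, "': truncated DATA segment at byte ",
         data_begin)
  seek(con, data_begin)
  raw_vals <- readBin(con, "double", n = n * p, size = word, endian = endian)
  m <- matrix(raw_vals, nrow = n, ncol = p, byrow = TRUE,
              dimnames = list(NULL, ch))
  event_table(m, sample_id)
}
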