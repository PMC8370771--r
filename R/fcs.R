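# Minimal FCS 3.1 export/import (float LIST-mode, little endian), for
# interoperability with conventional flow-cytometry tools. Only the subset
# of the standard needed for feature tables is implemented.

#' Write an event feature table as an FCS 3.1 file
#'
#' Emits LIST-mode single-precision data with one parameter per feature
#' column, little-endian byte order, and linear (`0,0`) amplification
#' keywords.
#'
#' @param table event feature tibble.
#' @param path output path.
#' @param features columns to export; default: all numeric feature columns.
#' @return invisibly, `path`.
#' @export
write_fcs <- function(table, path, features = NULL) {
  features <- features %||% feature_columns(table)
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("FCS export cannot contain missing values")
  n <- nrow(X); p <- ncol(X)
  delim <- "/"
  clean <- gsub("/", "_", features, fixed = TRUE)
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%%BD%%", "$ENDDATA", "%%ED%%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
  for (j in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", j), clean[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(ceiling(max(X[, j], 1)), scientific = FALSE))
  }
  text_of <- function(bd, ed) {
    body <- gsub("%%ED%%", sprintf("%012d", ed),
                 gsub("%%BD%%", sprintf("%012d", bd),
                      paste0(delim, paste(kw, collapse = delim), delim)))
    body
  }
  header_len <- 58L
  text <- text_of(0, 0)
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * n * p - 1L
  text <- text_of(data_begin, data_end)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(X)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.x feature table written by [write_fcs()]
#'
#' Supports float LIST-mode data in either byte order; sufficient for
#' round-tripping the pipeline's own exports and similar simple files.
#'
#' @param path FCS file path.
#' @return tibble with one column per parameter; keywords in attribute
#'   `keywords`.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3")) stop("not an FCS 3.x file")
  off <- function(i) as.integer(substr(header, 11 + 8 * (i - 1), 10 + 8 * i))
  tb <- off(1); te <- off(2); db <- off(3); de <- off(4)
  text <- rawToChar(raw[(tb + 1):(te + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substr(text, 2, nchar(text)), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- setNames(vals, keys)
  if (kw[["$DATATYPE"]] != "F") stop("only float ($DATATYPE F) data supported")
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  if (db == 0) db <- as.integer(kw[["$BEGINDATA"]])
  if (de == 0) de <- as.integer(kw[["$ENDDATA"]])
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  vec <- readBin(raw[(db + 1):(de + 1)], "numeric", n * p, size = 4L,
                 endian = endian)
  M <- matrix(vec, nrow = n, ncol = p, byrow = TRUE)
  colnames(M) <- vapply(seq_len(p), function(j) kw[[sprintf("$P%dN", j)]],
                        character(1))
  out <- tibble::as_tibble(M)
  attr(out, "keywords") <- kw
  out
}
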