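# FASTA input and matrix output.

#' Read sequences from a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' multi-line sequences are concatenated; blank lines are tolerated;
#' sequences are uppercased. Duplicate ids or empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, names = ids,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  if (is.null(headers) || any(is.na(headers) | !nzchar(trimws(headers))))
    stop("FASTA record with empty header in ", path)
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence record(s) in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a similarity matrix to disk
#'
#' Two formats: `"tsv"` writes a header line of sequence ids followed by
#' one line per row i holding the id and its j < i lower-triangle values
#' at 6 decimal places (row 1 has the id only); `"phylip-lower"` writes
#' the sequence count on the first line, then one line per sequence with
#' the id padded to 10 characters and the lower-triangle values.
#'
#' @param matrix A `sim_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip-lower"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "phylip-lower")) {
  stopifnot(inherits(matrix, "sim_matrix"))
  format <- match.arg(format)
  n <- matrix$n_sequences
  ids <- matrix$sequence_ids
  row_vals <- function(i) {
    if (i < 2L) character(0)
    else sprintf("%.6f", matrix$values[.row_offset(i) + 1:(i - 1L)])
  }
  lines <- if (format == "tsv") {
    c(paste(ids, collapse = "\t"),
      vapply(seq_len(n), function(i)
        paste(c(ids[i], row_vals(i)), collapse = "\t"), ""))
  } else {
    c(as.character(n),
      vapply(seq_len(n), function(i)
        paste(c(formatC(ids[i], width = 10L, flag = "-"), row_vals(i)),
              collapse = " "), ""))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write matrix to '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a TSV similarity matrix
#'
#' Inverse of `write_matrix(format = "tsv")`, exact to the written
#' 6-decimal precision.
#'
#' @param path Path to a TSV matrix file.
#' @return A `sim_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed matrix file: ", path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(ids)
  if (length(lines) != n + 1L)
    stop("matrix file has ", length(lines) - 1L, " rows, expected ", n)
  values <- numeric(0)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (fields[1] != ids[i] || length(fields) != i)
      stop("malformed matrix row ", i, " in ", path)
    if (i > 1L) values <- c(values, as.numeric(fields[-1]))
  }
  .new_sim_matrix(values, ids)
}
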