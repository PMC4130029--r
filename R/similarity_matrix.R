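# All-pairs similarity matrix, sequential and master-worker.
#
# F(X,Y) = F(Y,X), so only the strict lower triangle is computed: entry
# (i, j) for 1 <= j < i <= n, n(n-1)/2 values in total. The parallel
# scheme is static cyclic row distribution: row i goes to worker
# ((i - 1) mod p) + 1; each worker packs its rows into one flat result
# vector which the master unpacks into the matrix. Both paths call the
# same kmer_similarity(), so results are bit-identical by construction.

.row_offset <- function(i) ((i - 1L) * (i - 2L)) %/% 2L  # start of row i in packed storage

.new_sim_matrix <- function(values, ids) {
  n <- length(ids)
  stopifnot(length(values) == n * (n - 1L) / 2L)
  structure(list(n_sequences = n, sequence_ids = ids, values = values),
            class = "sim_matrix")
}

#' Look up one entry of a similarity matrix
#'
#' @param matrix A `sim_matrix`.
#' @param i,j 1-based sequence indices, `i != j`; order does not matter.
#' @return The similarity F(i, j).
#' @export
sim_value <- function(matrix, i, j) {
  stopifnot(inherits(matrix, "sim_matrix"))
  if (i == j) stop("diagonal entries are not stored")
  if (i < j) { tmp <- i; i <- j; j <- tmp }
  if (i > matrix$n_sequences || j < 1L) stop("index out of range")
  matrix$values[.row_offset(i) + j]
}

#' Expand a `sim_matrix` to a full symmetric matrix
#' @param x A `sim_matrix`.
#' @param diag Value placed on the diagonal (default `NA`).
#' @param ... Ignored.
#' @return A base symmetric numeric matrix with id dimnames.
#' @method as.matrix sim_matrix
#' @export
as.matrix.sim_matrix <- function(x, diag = NA_real_, ...) {
  n <- x$n_sequences
  m <- matrix(diag, n, n, dimnames = list(x$sequence_ids, x$sequence_ids))
  for (i in seq_len(n)[-1]) {
    js <- seq_len(i - 1L)
    m[i, js] <- x$values[.row_offset(i) + js]
    m[js, i] <- m[i, js]
  }
  m
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("Similarity matrix over", x$n_sequences, "sequences (",
      length(x$values), "pairwise values )\n")
  if (length(x$values))
    cat("  range:", format(min(x$values), digits = 4), "-",
        format(max(x$values), digits = 4), "\n")
  invisible(x)
}

.ids_of <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- paste0("seq", seq_along(sequences))
  ids
}

#' Compute the all-pairs similarity matrix sequentially
#'
#' Double loop over the strict lower triangle: each unordered pair is
#' scored exactly once with [kmer_similarity()].
#'
#' @param sequences Character vector (optionally named) of >= 2 residue
#'   strings; names become sequence ids.
#' @param k Word length.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return A `sim_matrix` holding the n(n-1)/2 lower-triangle values.
#' @export
compute_matrix_sequential <- function(sequences, k, alphabet) {
  alphabet <- as_alphabet(alphabet)
  sequences <- .seq_vector(sequences)
  n <- length(sequences)
  if (n < 2L) stop("need at least two sequences")
  values <- numeric(n * (n - 1L) / 2L)
  pos <- 0L
  for (i in 2:n) {
    for (j in 1:(i - 1L)) {
      pos <- pos + 1L
      values[pos] <- kmer_similarity(sequences[[i]], sequences[[j]],
                                     k, alphabet)
    }
  }
  .new_sim_matrix(values, .ids_of(sequences))
}

# keep names when coercing list input
.seq_vector <- function(x) {
  out <- vapply(x, as.character, "")
  names(out) <- names(x)
  out
}

#' Cyclic assignment of matrix rows to workers
#'
#' Row i (1-based) goes to worker ((i - 1) mod p) + 1, where p is the
#' worker count: with 7 rows and 3 workers, worker 1 owns rows 1, 4, 7,
#' worker 2 rows 2, 5 and worker 3 rows 3, 6. All n rows are assigned;
#' row 1 carries zero pairs. Workers with id > n_rows get empty lists.
#'
#' @param n_rows Number of matrix rows (= number of sequences), >= 1.
#' @param n_workers Number of workers p, >= 1.
#' @return A `row_assignment`: list with `n_rows`, `n_workers`, and
#'   `rows_of` (list mapping worker id to its ascending row indices).
#' @examples
#' assign_rows(7, 3)$rows_of  # list(c(1,4,7), c(2,5), c(3,6))
#' @export
assign_rows <- function(n_rows, n_workers) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != floor(n_rows))
    stop("'n_rows' must be a positive integer")
  if (!is.numeric(n_workers) || length(n_workers) != 1L || n_workers < 1 ||
      n_workers != floor(n_workers))
    stop("'n_workers' must be a positive integer")
  n_rows <- as.integer(n_rows); n_workers <- as.integer(n_workers)
  rows_of <- lapply(seq_len(n_workers), function(w) {
    if (w > n_rows) integer(0)
    else seq.int(w, n_rows, by = n_workers)
  })
  structure(list(n_rows = n_rows, n_workers = n_workers, rows_of = rows_of),
            class = "row_assignment")
}

#' Compute one worker's packed result vector
#'
#' The worker scores every pair (i, j), j < i, for each of its assigned
#' rows i, rows ascending and columns ascending, and concatenates the
#' values into a single flat vector -- the one message it returns to the
#' master. Row 1, if assigned, contributes nothing.
#'
#' @param sequences Character vector of all sequences (every worker holds
#'   the full set, mirroring the master's broadcast).
#' @param assignment A `row_assignment` for `length(sequences)` rows.
#' @param worker_id Worker id in `1..n_workers`.
#' @param k Word length.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @return A `worker_result`: list with `worker_id`, `rows`, and `values`
#'   (length = sum over assigned rows i of (i - 1)).
#' @export
compute_worker_rows <- function(sequences, assignment, worker_id, k, alphabet) {
  stopifnot(inherits(assignment, "row_assignment"))
  alphabet <- as_alphabet(alphabet)
  sequences <- .seq_vector(sequences)
  if (length(sequences) != assignment$n_rows)
    stop("assignment covers ", assignment$n_rows, " rows but ",
         length(sequences), " sequences were given")
  if (!is.numeric(worker_id) || length(worker_id) != 1L ||
      worker_id < 1 || worker_id > assignment$n_workers ||
      worker_id != floor(worker_id))
    stop("'worker_id' must be in 1..", assignment$n_workers)
  worker_id <- as.integer(worker_id)
  rows <- assignment$rows_of[[worker_id]]
  values <- numeric(sum(rows - 1L))
  pos <- 0L
  for (i in rows) {
    if (i < 2L) next
    for (j in 1:(i - 1L)) {
      pos <- pos + 1L
      values[pos] <- kmer_similarity(sequences[[i]], sequences[[j]],
                                     k, alphabet)
    }
  }
  structure(list(worker_id = worker_id, rows = rows, values = values),
            class = "worker_result")
}

#' Assemble the similarity matrix from worker result vectors
#'
#' The master unpacks each worker's flat vector back into its rows, using
#' the assignment to know which rows (hence which lengths) each worker
#' owns, and fills the lower triangle.
#'
#' @param result_vectors List of `worker_result` objects, one per worker
#'   (any order).
#' @param assignment The `row_assignment` the workers ran under.
#' @param sequence_ids Optional character vector of sequence labels.
#' @return A `sim_matrix` identical to the sequential result.
#' @export
assemble_matrix <- function(result_vectors, assignment, sequence_ids = NULL) {
  stopifnot(inherits(assignment, "row_assignment"))
  n <- assignment$n_rows
  if (is.null(sequence_ids)) sequence_ids <- paste0("seq", seq_len(n))
  if (length(sequence_ids) != n)
    stop("'sequence_ids' must have length ", n)
  got <- vapply(result_vectors, function(r) {
    if (!inherits(r, "worker_result")) stop("result_vectors must be worker_result objects")
    r$worker_id
  }, 0L)
  values <- rep(NA_real_, n * (n - 1L) / 2L)
  for (w in seq_len(assignment$n_workers)) {
    idx <- which(got == w)
    if (length(idx) != 1L)
      stop("missing or duplicated result vector for worker ", w)
    res <- result_vectors[[idx]]
    rows <- assignment$rows_of[[w]]
    expected <- sum(rows - 1L)
    if (length(res$values) != expected)
      stop("worker ", w, " returned ", length(res$values),
           " values, expected ", expected)
    pos <- 0L
    for (i in rows) {
      if (i < 2L) next
      values[.row_offset(i) + 1:(i - 1L)] <- res$values[pos + 1:(i - 1L)]
      pos <- pos + i - 1L
    }
  }
  if (anyNA(values)) stop("assembled matrix has unfilled entries")
  .new_sim_matrix(values, sequence_ids)
}

#' Compute the similarity matrix with the master-worker scheme
#'
#' Rows are distributed cyclically over `n_workers` workers; each worker
#' computes its rows and returns one packed result vector; the master
#' assembles the matrix. The output is identical to
#' [compute_matrix_sequential()] for every worker count and backend:
#' every F value is an integer count divided by an integer denominator,
#' computed by the same code path.
#'
#' Backends: `"serial"` runs the workers one after another in-process
#' (deterministic, no dependencies -- the default, and what the test
#' suite exercises); `"process"` runs each worker in a forked child via
#' \code{parallel::mclapply}, one result object per worker.
#' `"serial-emulation"` is accepted as an alias of `"serial"`.
#'
#' @param sequences Character vector (optionally named) of >= 2 residue
#'   strings.
#' @param k Word length.
#' @param alphabet A `kmer_alphabet` object or alphabet name.
#' @param n_workers Number of workers, >= 1.
#' @param backend `"serial"` or `"process"`.
#' @return A `sim_matrix`.
#' @export
compute_matrix_parallel <- function(sequences, k, alphabet, n_workers = 1L,
                                    backend = c("serial", "process",
                                                "serial-emulation")) {
  backend <- match.arg(backend)
  if (backend == "serial-emulation") backend <- "serial"
  alphabet <- as_alphabet(alphabet)
  sequences <- .seq_vector(sequences)
  n <- length(sequences)
  if (n < 2L) stop("need at least two sequences")
  if (!is.numeric(n_workers) || length(n_workers) != 1L || n_workers < 1 ||
      n_workers != floor(n_workers))
    stop("'n_workers' must be a positive integer")
  n_workers <- as.integer(n_workers)
  assignment <- assign_rows(n, n_workers)
  run_worker <- function(w) {
    tryCatch(
      compute_worker_rows(sequences, assignment, w, k, alphabet),
      error = function(e) stop("worker ", w, " failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  results <- if (backend == "serial") {
    lapply(seq_len(n_workers), run_worker)
  } else {
    out <- parallel::mclapply(seq_len(n_workers), run_worker,
                              mc.cores = min(n_workers,
                                             max(1L, parallel::detectCores())))
    bad <- vapply(out, inherits, TRUE, what = "try-error")
    if (any(bad)) stop(attr(out[[which(bad)[1]]], "condition")$message)
    out
  }
  assemble_matrix(results, assignment, .ids_of(sequences))
}
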