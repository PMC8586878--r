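#' Read a Matrix Market file
#'
#' Reads a coordinate-format `.mtx` file (field `real` or `integer`,
#' symmetry `general`) into a canonical [csr_matrix()].  The file's 1-based
#' indices are converted to the package's internal 0-based indices at this
#' boundary.  `pattern` and `complex` fields are rejected; negative entries
#' fail validation.
#'
#' @param path path to the `.mtx` file.
#' @return a canonical `csr_matrix`.
#' @export
read_mtx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- tolower(readLines(path, n = 1L))
  if (!grepl("^%%matrixmarket", header))
    stop("not a Matrix Market file: ", path, call. = FALSE)
  if (grepl("pattern|complex", header))
    stop("unsupported Matrix Market field type (pattern/complex)",
         call. = FALSE)
  x <- Matrix::readMM(path)
  dtype <- if (grepl("integer", header)) "integer" else "double"
  as_csr(x, dtype = dtype)
}

#' Write a Matrix Market file
#'
#' Writes the matrix in coordinate format (`real` or `integer` per the
#' matrix's value kind), 1-based, row-major sorted.  Real values are printed
#' with 17 significant digits, so a read/write round trip is lossless at
#' double precision.
#'
#' @param m a canonical `csr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mtx <- function(m, path) {
  stopifnot(inherits(m, "csr_matrix"))
  integerish <- m$dtype_kind == "integer" && all(m$data == floor(m$data))
  field <- if (integerish) "integer" else "real"
  lines <- c(
    sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
    sprintf("%d %d %d", m$n_rows, m$n_cols, length(m$data)))
  if (length(m$data)) {
    row <- rep.int(seq_len(m$n_rows), diff(m$indptr))
    vals <- if (integerish) sprintf("%d", as.integer(m$data))
            else sprintf("%.17g", m$data)
    lines <- c(lines, sprintf("%d %d %s", row, m$indices + 1L, vals))
  }
  writeLines(lines, path)
  invisible(path)
}

.bin_types <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  int8   = list(what = "integer", size = 1L, signed = TRUE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  int64  = list(what = "integer", size = 8L, signed = TRUE),
  float32 = list(what = "double", size = 4L, signed = TRUE),
  float64 = list(what = "double", size = 8L, signed = TRUE))

read_bin_array <- function(path, dtype, n) {
  t <- .bin_types[[dtype]]
  if (is.null(t)) stop("unknown binary dtype: ", dtype, call. = FALSE)
  out <- readBin(path, what = t$what, n = n + 1L, size = t$size,
                 signed = t$signed, endian = "little")
  if (length(out) != n)
    stop("binary array ", path, " has ", length(out),
         " elements, expected ", n, call. = FALSE)
  as.double(out)
}

#' Read a raw CSR triple
#'
#' Reads a sparse matrix stored as three flat little-endian binary arrays —
#' `data`, `indices` (0-based) and `indptr` — plus a JSON sidecar declaring
#' the shape and element types, e.g.
#' `{"n_rows": 3, "n_cols": 3, "nnz": 2, "data_dtype": "uint16",
#'   "indices_dtype": "int32", "indptr_dtype": "int64"}`.
#' Narrow element types (e.g. 16-bit counts) are widened to double on read.
#'
#' @param data_path,indices_path,indptr_path paths to the three arrays.
#' @param meta_path path to the JSON sidecar.
#' @return a canonical `csr_matrix`.
#' @export
read_csr_binary <- function(data_path, indices_path, indptr_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need <- c("n_rows", "n_cols", "nnz", "data_dtype", "indices_dtype",
            "indptr_dtype")
  if (!all(need %in% names(meta)))
    stop("sidecar is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  nnz <- as.integer(meta$nnz)
  dat <- read_bin_array(data_path, meta$data_dtype, nnz)
  ind <- read_bin_array(indices_path, meta$indices_dtype, nnz)
  ptr <- read_bin_array(indptr_path, meta$indptr_dtype,
                        as.integer(meta$n_rows) + 1L)
  if (ptr[length(ptr)] != nnz)
    stop("indptr does not match the declared nnz", call. = FALSE)
  csr_matrix(data = dat, indices = as.integer(ind), indptr = as.integer(ptr),
             n_rows = meta$n_rows, n_cols = meta$n_cols,
             dtype = if (grepl("^float", meta$data_dtype)) "double" else "integer")
}

#' Write a raw CSR triple
#'
#' Companion writer to [read_csr_binary()]: writes `<prefix>.data.bin`,
#' `<prefix>.indices.bin`, `<prefix>.indptr.bin` and `<prefix>.json`.
#'
#' @param m a canonical `csr_matrix`.
#' @param prefix output path prefix.
#' @param data_dtype,indices_dtype,indptr_dtype element types (see
#'   [read_csr_binary()]).
#' @return named character vector of the four paths, invisibly.
#' @export
write_csr_binary <- function(m, prefix, data_dtype = "float64",
                             indices_dtype = "int32", indptr_dtype = "int32") {
  stopifnot(inherits(m, "csr_matrix"))
  write_arr <- function(path, x, dtype) {
    t <- .bin_types[[dtype]]
    if (is.null(t)) stop("unknown binary dtype: ", dtype, call. = FALSE)
    storage <- if (t$what == "integer") as.integer(x) else as.double(x)
    writeBin(storage, path, size = t$size, endian = "little")
  }
  paths <- c(data = paste0(prefix, ".data.bin"),
             indices = paste0(prefix, ".indices.bin"),
             indptr = paste0(prefix, ".indptr.bin"),
             meta = paste0(prefix, ".json"))
  write_arr(paths[["data"]], m$data, data_dtype)
  write_arr(paths[["indices"]], m$indices, indices_dtype)
  write_arr(paths[["indptr"]], m$indptr, indptr_dtype)
  jsonlite::write_json(
    list(n_rows = m$n_rows, n_cols = m$n_cols, nnz = length(m$data),
         data_dtype = data_dtype, indices_dtype = indices_dtype,
         indptr_dtype = indptr_dtype),
    paths[["meta"]], auto_unbox = TRUE)
  invisible(paths)
}

#' Read per-row labels
#'
#' One label per line (TSV with a single column); when `n_rows` is given the
#' count must match.
#'
#' @param path label file.
#' @param n_rows optional expected length.
#' @return character vector of labels.
#' @export
read_labels <- function(path, n_rows = NULL) {
  labs <- readLines(path)
  labs <- labs[nzchar(trimws(labs))]
  if (!is.null(n_rows) && length(labs) != n_rows)
    stop("label file has ", length(labs), " labels but the matrix has ",
         n_rows, " rows", call. = FALSE)
  trimws(labs)
}

#' Write cluster assignments
#'
#' Tab-separated file with a header and one line per row:
#' `row_id`, `cluster_id`, `cost`.
#'
#' @param result an `skm_result` or `sparse_kmeans` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(result, path) {
  assign <- if (inherits(result, "sparse_kmeans")) result$cluster else result$assign
  cost <- result$cost
  df <- data.frame(row_id = seq_along(assign), cluster_id = assign,
                   cost = cost)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster assignments
#'
#' Reads a file written by [write_assignments()].
#'
#' @param path assignments TSV.
#' @return data frame with `row_id`, `cluster_id`, `cost`.
#' @export
read_assignments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}
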