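#' Labeled distance matrices
#'
#' Genetic, geographic and linguistic distances all share one container: a
#' square, symmetric, nonnegative matrix with a zero diagonal and population
#' labels as dimnames, of class `dist_matrix`.
#'
#' @param values Square numeric matrix.
#' @param labels Population labels; defaults to `rownames(values)`.
#' @return A validated `dist_matrix` (a base matrix subclass).
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) != ncol(values)) stop_strpop("distance matrix must be square")
  if (is.null(labels) || length(labels) != nrow(values)) {
    stop_strpop("labels must match matrix dimension")
  }
  if (anyDuplicated(labels)) stop_strpop("duplicate labels in distance matrix")
  dimnames(values) <- list(labels, labels)
  if (any(is.na(values))) stop_strpop("NA values in distance matrix")
  if (any(values < 0)) stop_strpop("negative values in distance matrix")
  if (max(abs(values - t(values))) > 1e-12) {
    stop_strpop("distance matrix is not symmetric (tolerance 1e-12)")
  }
  if (any(diag(values) != 0)) stop_strpop("distance matrix diagonal must be exactly zero")
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d labels\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname dist_matrix
#' @param path File path for a square labeled CSV (first column = labels,
#'   header = labels).
#' @export
read_dist_matrix <- function(path) {
  if (!file.exists(path)) stop_strpop("file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(df))
}

#' @rdname dist_matrix
#' @param x A `dist_matrix`.
#' @export
write_dist_matrix <- function(x, path) {
  stopifnot(inherits(x, "dist_matrix"))
  utils::write.csv(as.data.frame(unclass(x)), path, quote = FALSE)
  invisible(path)
}
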