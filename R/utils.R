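# Internal helpers shared across modules.

#' @noRd
stop_strpop <- function(..., class = "strpop_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Order allele labels numerically where they parse as numbers (microvariant
# labels such as "9.3" parse fine), falling back to lexicographic order for
# non-numeric labels, which sort after all numeric ones. Deterministic for
# any label set.
#' @noRd
order_alleles <- function(labels) {
  num <- suppressWarnings(as.numeric(labels))
  order(is.na(num), num, labels)
}

#' @noRd
sort_alleles <- function(labels) labels[order_alleles(labels)]

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' @noRd
lower_tri <- function(m) m[lower.tri(m)]

#' @noRd
is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
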