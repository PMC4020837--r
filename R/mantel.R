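#' Mantel test of matrix correlation
#'
#' Pearson correlation between the `n(n-1)/2` unordered off-diagonal pairs of
#' two aligned distance matrices, with significance from simultaneous
#' row/column permutation of the second matrix. The statistic is invariant
#' under separate positive affine rescaling of either matrix. Default is the
#' one-tailed (positive) test, the directional form isolation-by-distance
#' hypotheses call for; `alternative = "two.sided"` uses `|r|`.
#'
#' `p = (#{permuted statistics meeting the tail rule} + 1) / (n_permutations + 1)`,
#' so the smallest attainable p is `1/(n_permutations + 1)`.
#'
#' @param a,b [dist_matrix()] objects with identical labels in identical
#'   order, `n >= 4`.
#' @param n_permutations Number of permutations (default 9999).
#' @param seed RNG seed, recorded in the result; fixed seed gives
#'   bit-reproducible p-values.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list of class `mantel_result`: `r`, `p_value`,
#'   `variance_explained` (`r^2`), `n_permutations`, `seed`, `kind`,
#'   `alternative`, `degenerate`.
#' @export
mantel_test <- function(a, b, n_permutations = 9999L, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_aligned(a, b)
  n <- nrow(a)
  if (n < 4L) stop_strpop("Mantel test needs n >= 4")
  if (!is_count(n_permutations, 1L)) stop_strpop("n_permutations must be >= 1")
  lt <- lower.tri(a)
  va <- a[lt]; vb <- b[lt]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    return(mantel_result(NA_real_, NA_real_, n_permutations, seed, "simple",
                         alternative, degenerate = TRUE))
  }
  r <- stats::cor(va, vb)
  hits <- with_seed(seed, {
    h <- 0L
    for (k in seq_len(n_permutations)) {
      idx <- sample.int(n)
      rp <- stats::cor(va, b[idx, idx][lt])
      ok <- if (alternative == "greater") rp >= r - 1e-12 else abs(rp) >= abs(r) - 1e-12
      if (ok) h <- h + 1L
    }
    h
  })
  mantel_result(r, (hits + 1) / (n_permutations + 1), n_permutations, seed,
                "simple", alternative)
}

#' Partial Mantel test
#'
#' Partial correlation of `a` and `b` controlling for `c`, computed from the
#' three pairwise Mantel correlations:
#' `r_ab.c = (r_ab - r_ac r_bc) / sqrt((1 - r_ac^2)(1 - r_bc^2))`.
#' Significance by permuting `a`'s labels and recomputing the full partial
#' statistic (Smouse-Long-Sokal family); `method = "residual"` instead
#' permutes the residuals of `a` regressed on `c` against those of `b` on
#' `c`.
#'
#' @param a,b,c Aligned [dist_matrix()] objects; `c` is the controlled
#'   matrix. `|r_ac|` or `|r_bc|` at 1 is a degeneracy error.
#' @param controlled Label recorded for the controlled matrix.
#' @param method Permutation scheme (see above).
#' @inheritParams mantel_test
#' @return A `mantel_result` with `kind = "partial"`.
#' @export
partial_mantel_test <- function(a, b, c, n_permutations = 9999L, seed = NULL,
                                alternative = c("greater", "two.sided"),
                                controlled = "c",
                                method = c("permute_raw", "residual")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  check_aligned(a, b); check_aligned(a, c)
  n <- nrow(a)
  if (n < 4L) stop_strpop("partial Mantel test needs n >= 4")
  lt <- lower.tri(a)
  va <- a[lt]; vb <- b[lt]; vc <- c[lt]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0 || stats::sd(vc) == 0) {
    return(mantel_result(NA_real_, NA_real_, n_permutations, seed, "partial",
                         alternative, controlled = controlled, degenerate = TRUE))
  }
  pcor <- function(x, y, z) {
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    den <- (1 - rxz^2) * (1 - ryz^2)
    if (den <= 1e-12) stop_strpop("partial Mantel degenerate: a controlling correlation is 1 in magnitude")
    (rxy - rxz * ryz) / sqrt(den)
  }
  if (method == "residual") {
    ra <- stats::residuals(stats::lm(va ~ vc))
    rb <- stats::residuals(stats::lm(vb ~ vc))
  }
  r <- pcor(va, vb, vc)
  hits <- with_seed(seed, {
    h <- 0L
    for (k in seq_len(n_permutations)) {
      idx <- sample.int(n)
      if (method == "permute_raw") {
        vap <- a[idx, idx][lt]
        rp <- pcor(vap, vb, vc)
      } else {
        # permute residual vector of a over pair positions induced by idx
        vap <- a[idx, idx][lt]
        rap <- stats::residuals(stats::lm(vap ~ vc))
        rp <- stats::cor(rap, rb)
      }
      ok <- if (alternative == "greater") rp >= r - 1e-12 else abs(rp) >= abs(r) - 1e-12
      if (ok) h <- h + 1L
    }
    h
  })
  res <- mantel_result(r, (hits + 1) / (n_permutations + 1), n_permutations,
                       seed, "partial", alternative, controlled = controlled)
  res$method <- method
  res
}

#' @noRd
check_aligned <- function(a, b) {
  if (!inherits(a, "dist_matrix") || !inherits(b, "dist_matrix")) {
    stop_strpop("inputs must be dist_matrix objects")
  }
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b))) {
    stop_strpop("label mismatch between distance matrices: ",
                paste(utils::head(setdiff(union(rownames(a), rownames(b)),
                                          intersect(rownames(a), rownames(b))), 3L),
                      collapse = ", "))
  }
  invisible(TRUE)
}

#' @noRd
mantel_result <- function(r, p, n_permutations, seed, kind, alternative,
                          controlled = NULL, degenerate = FALSE) {
  structure(list(r = r, p_value = p,
                 variance_explained = if (is.na(r)) NA_real_ else r^2,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, kind = kind, alternative = alternative,
                 controlled = controlled, degenerate = degenerate),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<mantel_result> degenerate (constant matrix)\n")
    return(invisible(x))
  }
  lab <- if (x$kind == "partial") sprintf("partial (controlling %s)", x$controlled) else "simple"
  cat(sprintf("<mantel_result> %s: r = %.4f, p = %.4g (%d permutations, %s), r^2 = %.4f\n",
              lab, x$r, x$p_value, x$n_permutations, x$alternative,
              x$variance_explained))
  invisible(x)
}
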