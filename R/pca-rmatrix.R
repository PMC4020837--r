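#' PCA on the locus-averaged covariance matrix of allele frequencies
#'
#' Allele frequencies are compositional (they sum to one within each locus),
#' so a population x (locus, allele) data matrix is rank deficient ("effect
#' of closure"). This PCA therefore works per locus: the population x allele
#' frequency sub-matrix is centered by column (allele) means, its population
#' x population covariance contribution formed, and the contributions are
#' averaged over loci before eigendecomposition. Scores are eigenvector
#' projections scaled by the root eigenvalue; each component is oriented so
#' that its largest-magnitude score is positive.
#'
#' @param panel A [freq_panel()] with >= 3 populations.
#' @param n_components Number of components to retain (default: all with
#'   positive eigenvalue, at most `n - 1`).
#' @return list of class `pca_result`: `scores` (populations x components),
#'   `variance_ratio`, `eigenvalues`, `component_count`, `degenerate` flag.
#' @export
covariance_pca <- function(panel, n_components = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  pops <- panel$populations
  n <- length(pops)
  if (n < 3L) stop_strpop("need >= 3 populations")
  if (!is.null(n_components) && n_components > n) {
    stop_strpop("fewer populations (", n, ") than requested components (",
                n_components, ")")
  }
  C <- matrix(0, n, n, dimnames = list(pops, pops))
  L <- 0L
  for (l in panel$loci) {
    m <- locus_freq_matrix(panel, l)
    if (nrow(m) < n) stop_strpop("locus ", l, " not typed in all populations")
    m <- m[pops, , drop = FALSE]
    mc <- sweep(m, 2L, colMeans(m))
    C <- C + mc %*% t(mc)
    L <- L + 1L
  }
  C <- C / L
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  if (total < 1e-12) {
    return(structure(list(scores = NULL, variance_ratio = NULL,
                          eigenvalues = eig$values, component_count = 0L,
                          degenerate = TRUE), class = "pca_result"))
  }
  k <- n_components %||% sum(ev > total * 1e-12)
  k <- min(k, n)
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    if (vec[which.max(abs(vec[, i])), i] < 0) vec[, i] <- -vec[, i]
  }
  scores <- sweep(vec, 2L, sqrt(ev[seq_len(k)]), "*")
  dimnames(scores) <- list(pops, paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 variance_ratio = ev[seq_len(k)] / total,
                 eigenvalues = eig$values, component_count = k,
                 degenerate = FALSE), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<pca_result> degenerate (zero total variance)\n")
  } else {
    cat(sprintf("<pca_result> %d components; variance ratios: %s\n",
                x$component_count,
                paste(sprintf("%.2f%%", 100 * x$variance_ratio), collapse = ", ")))
  }
  invisible(x)
}

#' Harpending-Ward R matrix
#'
#' The scaled covariance matrix of population allele frequencies about their
#' weighted centroid:
#' `R_ij = (1/L') * sum_{loci, alleles} (p_i - pbar)(p_j - pbar) / (pbar (1 - pbar))`
#' with `pbar` the weighted centroid frequency of the allele and `L'` the
#' number of (locus, allele) terms with `0 < pbar < 1` (alleles fixed at the
#' centroid carry no information and are skipped). The diagonal `r_ii` is
#' each population's genetic distance from the gene-frequency centroid. The
#' weighted row sums of R are zero, and R is positive semidefinite.
#'
#' @param panel A [freq_panel()] with >= 2 populations, all typed at every
#'   locus used.
#' @param weights `"by_n"` (proportional to mean gene-copy counts, the
#'   sample-size proxy for population-size weights) or `"equal"`.
#' @return list of class `rmatrix_result`: `r` (matrix), `r_ii`, `h_i`
#'   (per-population average heterozygosity), `h_t` (overall mean
#'   heterozygosity), `weights`, `n_terms`.
#' @export
r_matrix <- function(panel, weights = c("by_n", "equal")) {
  stopifnot(inherits(panel, "freq_panel"))
  weights <- match.arg(weights)
  pops <- panel$populations
  if (length(pops) < 2L) stop_strpop("need >= 2 populations")
  w <- if (weights == "by_n") rowMeans(panel$n_copies) else rep(1, length(pops))
  w <- w / sum(w)
  names(w) <- pops
  R <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  n_terms <- 0L
  for (l in panel$loci) {
    m <- locus_freq_matrix(panel, l)
    if (nrow(m) < length(pops)) stop_strpop("locus ", l, " not typed in all populations")
    m <- m[pops, , drop = FALSE]
    pbar <- colSums(w * m)
    for (a in seq_len(ncol(m))) {
      if (pbar[a] <= 1e-12 || pbar[a] >= 1 - 1e-12) next
      dev <- m[, a] - pbar[a]
      R <- R + outer(dev, dev) / (pbar[a] * (1 - pbar[a]))
      n_terms <- n_terms + 1L
    }
  }
  if (n_terms == 0L) stop_strpop("no informative (locus, allele) terms: all alleles fixed at the centroid")
  R <- R / n_terms
  ps <- panel_stats(panel, weights = if (weights == "by_n") "by_n" else "equal")
  structure(list(r = R, r_ii = diag(R), h_i = ps$h_i, h_t = ps$h_t,
                 weights = w, n_terms = n_terms),
            class = "rmatrix_result")
}

#' @export
print.rmatrix_result <- function(x, ...) {
  cat(sprintf("<rmatrix_result> %d populations, %d (locus, allele) terms, H_t = %.4f\n",
              nrow(x$r), x$n_terms, x$h_t))
  invisible(x)
}

#' R-matrix gene-flow regression
#'
#' Under the Harpending-Ward model, a population's expected heterozygosity is
#' a linear function of its distance from the centroid:
#' `E[H_i] = H_t * (1 - r_ii)`. Populations above the theoretical line have
#' received more than the average external gene flow; populations below it
#' are relatively isolated. An ordinary least-squares fit of `h_i` on `r_ii`
#' is reported alongside for comparison.
#'
#' @param rm An [r_matrix()] result.
#' @return list of class `rmatrix_regression`: `table` (population, r_ii,
#'   h_i, expected_h, residual, classification), `h_t`, `ols` (intercept,
#'   slope).
#' @export
rmatrix_regression <- function(rm) {
  stopifnot(inherits(rm, "rmatrix_result"))
  expected <- rm$h_t * (1 - rm$r_ii)
  residual <- rm$h_i - expected
  tab <- data.frame(
    population = names(rm$r_ii), r_ii = as.numeric(rm$r_ii),
    h_i = as.numeric(rm$h_i), expected_h = as.numeric(expected),
    residual = as.numeric(residual),
    classification = ifelse(residual >= 0, "above", "below"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  fit <- stats::lm(h_i ~ r_ii, data = tab)
  structure(list(table = tab, h_t = rm$h_t,
                 ols = stats::setNames(stats::coef(fit), c("intercept", "slope"))),
            class = "rmatrix_regression")
}

#' @export
print.rmatrix_regression <- function(x, ...) {
  cat(sprintf("<rmatrix_regression> H_t = %.4f; theoretical line H = H_t (1 - r_ii)\n",
              x$h_t))
  print(x$table, ...)
  invisible(x)
}
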