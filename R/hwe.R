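# Hardy-Weinberg exact testing (Levene conditional distribution).
#
# Under the null, conditional on the allele counts c_1..c_k in a sample of n
# diploid genotypes, the probability of a genotype-count table {n_ij} is
#
#   P(table) = n! * prod_i c_i! / (2n)! * 2^H / prod_{i<=j} n_ij!
#
# with H the number of heterozygous individuals. The exact p-value sums the
# probabilities of all tables no more probable than the observed one.

#' @noRd
parse_genotype_counts <- function(genotype_counts) {
  if (length(genotype_counts) == 0L) stop_strpop("empty genotype count map")
  if (is.null(names(genotype_counts))) stop_strpop("genotype counts must be named 'a1/a2'")
  if (any(genotype_counts < 0) || any(genotype_counts != floor(genotype_counts))) {
    stop_strpop("genotype counts must be nonnegative integers")
  }
  parts <- strsplit(names(genotype_counts), "/", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop_strpop("genotype keys must be 'allele1/allele2'")
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  alleles <- sort_alleles(unique(c(a1, a2)))
  k <- length(alleles)
  tab <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  for (i in seq_along(genotype_counts)) {
    r <- sort(c(match(a1[i], alleles), match(a2[i], alleles)))
    tab[r[1L], r[2L]] <- tab[r[1L], r[2L]] + as.integer(genotype_counts[i])
  }
  tab
}

# log Levene probability of an upper-triangular genotype count table given
# its allele-count margins (margin-dependent constant omitted; only
# differences matter within a fixed margin).
#' @noRd
log_levene_kernel <- function(tab) {
  het <- sum(tab[upper.tri(tab)])
  het * log(2) - sum(lgamma(tab[upper.tri(tab, diag = TRUE)] + 1))
}

#' @noRd
allele_margins <- function(tab) {
  # upper-triangular table: allele i's copies = 2 n_ii + sum of its het counts
  rowSums(tab + t(tab))
}

# Enumerate all genotype tables with the given allele-count margins,
# calling fn(log_kernel) for each. Recursion over heterozygote counts;
# homozygote counts are then forced.
#' @noRd
enumerate_tables <- function(margins, fn) {
  k <- length(margins)
  tab <- matrix(0L, k, k)
  pairs <- which(upper.tri(tab), arr.ind = TRUE)
  rec <- function(idx, rem) {
    if (idx > nrow(pairs)) {
      if (any(rem %% 2L != 0L)) return(invisible())
      diag(tab) <<- as.integer(rem / 2L)
      fn(log_levene_kernel(tab))
      return(invisible())
    }
    i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
    for (nij in 0:min(rem[i], rem[j])) {
      tab[i, j] <<- nij
      rem2 <- rem
      rem2[i] <- rem2[i] - nij
      rem2[j] <- rem2[j] - nij
      rec(idx + 1L, rem2)
    }
    tab[i, j] <<- 0L
    invisible()
  }
  rec(1L, margins)
  invisible()
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: the p-value is the probability, under the Levene
#' distribution of genotype tables given the observed allele counts, of a
#' table no more probable than the observed one. Small problems (at most
#' `max_enum_alleles` alleles and `max_enum_copies` gene copies) are solved
#' by full enumeration; larger ones by Monte Carlo permutation of gene
#' copies. A monomorphic locus returns p = 1.
#'
#' @param genotype_counts Named count vector keyed `"a1/a2"`.
#' @param mode `"auto"` picks enumeration when feasible; `"enumeration"`
#'   errors if the problem exceeds the complexity bound; `"monte_carlo"`
#'   forces permutation.
#' @param reps Monte Carlo replicates.
#' @param seed Seed for the Monte Carlo mode (recorded in the result).
#' @param max_enum_alleles,max_enum_copies Enumeration feasibility bounds.
#' @return list with `p_value`, `method` (`"enumeration"` or
#'   `"monte_carlo"`), `reps`, `seed`.
#' @examples
#' hwe_exact_test(c("A/A" = 5, "B/B" = 5))           # all homozygous
#' hwe_exact_test(c("A/A" = 3, "A/B" = 5, "B/B" = 2))
#' @export
hwe_exact_test <- function(genotype_counts,
                           mode = c("auto", "enumeration", "monte_carlo"),
                           reps = 1e5, seed = NULL,
                           max_enum_alleles = 3L, max_enum_copies = 200L) {
  mode <- match.arg(mode)
  tab <- parse_genotype_counts(genotype_counts)
  margins <- allele_margins(tab)
  k <- sum(margins > 0)
  n_copies <- sum(margins)
  if (k <= 1L) {
    return(list(p_value = 1, method = "enumeration", reps = NA_integer_, seed = seed))
  }
  feasible <- k <= max_enum_alleles && n_copies <= max_enum_copies
  if (mode == "enumeration" && !feasible) {
    stop_strpop("enumeration infeasible for ", k, " alleles / ", n_copies,
                " copies; use mode = 'monte_carlo'")
  }
  use_enum <- mode == "enumeration" || (mode == "auto" && feasible)
  keep <- margins > 0
  tab <- tab[keep, keep, drop = FALSE]
  margins <- margins[keep]
  obs <- log_levene_kernel(tab)
  eps <- 1e-9
  if (use_enum) {
    logs <- new.env()
    logs$num <- -Inf; logs$den <- -Inf
    lse <- function(a, b) if (a == -Inf) b else if (b == -Inf) a else max(a, b) + log1p(exp(-abs(a - b)))
    enumerate_tables(margins, function(lk) {
      logs$den <- lse(logs$den, lk)
      if (lk <= obs + eps) logs$num <- lse(logs$num, lk)
    })
    p <- exp(logs$num - logs$den)
    return(list(p_value = min(p, 1), method = "enumeration",
                reps = NA_integer_, seed = seed))
  }
  # Monte Carlo: shuffle the 2n gene copies, pair consecutive copies
  copies <- rep(seq_along(margins), margins)
  kk <- length(margins)
  hits <- with_seed(seed, {
    h <- 0L
    for (r in seq_len(reps)) {
      perm <- sample(copies)
      a <- perm[c(TRUE, FALSE)]
      b <- perm[c(FALSE, TRUE)]
      lo <- pmin(a, b); hi <- pmax(a, b)
      counts <- tabulate((lo - 1L) * kk + hi, nbins = kk * kk)
      idx <- which(counts > 0L)
      row <- (idx - 1L) %/% kk + 1L
      col <- (idx - 1L) %% kk + 1L
      lk <- sum(counts[idx[row != col]]) * log(2) - sum(lgamma(counts[idx] + 1))
      if (lk <= obs + eps) h <- h + 1L
    }
    h
  })
  list(p_value = (hits + 1) / (reps + 1), method = "monte_carlo",
       reps = as.integer(reps), seed = seed)
}
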