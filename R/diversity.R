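#' Gene diversity (unbiased expected heterozygosity)
#'
#' Nei's unbiased gene diversity `h = n/(n-1) * (1 - sum(x_i^2))`, with `x_i`
#' the allele frequencies and `n` the number of gene copies the estimate is
#' based on.
#'
#' @param freqs Named numeric vector of allele frequencies summing to 1.
#' @param n Number of gene copies (>= 2).
#' @param unbiased If `FALSE`, returns the plain `1 - sum(x^2)` (used e.g. in
#'   the Gst decomposition where the Nei 1973 quantities are uncorrected).
#' @return Gene diversity in `[0, 1]` (can marginally exceed the naive value
#'   because of the `n/(n-1)` correction).
#' @examples
#' gene_diversity(c(A = 0.5, B = 0.5), n = 100)  # 100/99 * 0.5
#' @export
gene_diversity <- function(freqs, n, unbiased = TRUE) {
  if (!is_count(n, min = 2L)) stop_strpop("n must be an integer >= 2")
  if (length(freqs) == 0L) stop_strpop("empty frequency vector")
  if (abs(sum(freqs) - 1) > 1e-6) stop_strpop("frequencies must sum to 1")
  h <- 1 - sum(freqs^2)
  if (unbiased) h <- n / (n - 1) * h
  h
}

#' Probability of matching (PM)
#'
#' The probability that two individuals drawn at random share a genotype:
#' `PM = sum(f_g^2)` over genotype classes `g`.
#'
#' @param genotype_freqs Named numeric vector of genotype frequencies
#'   summing to 1.
#' @return PM in `(0, 1]`.
#' @export
matching_probability <- function(genotype_freqs) {
  if (length(genotype_freqs) == 0L) stop_strpop("empty genotype frequency map")
  if (abs(sum(genotype_freqs) - 1) > 1e-6) stop_strpop("genotype frequencies must sum to 1")
  sum(genotype_freqs^2)
}

#' Power of exclusion (PE)
#'
#' Brenner's forensic power-of-exclusion formula on observed heterozygosity:
#' `PE = h^2 * (1 - 2 * h * H^2)` with `h` the observed heterozygote and
#' `H = 1 - h` the observed homozygote proportion.
#'
#' @param obs_het,obs_hom Observed heterozygote/homozygote proportions in
#'   `[0, 1]`, summing to 1.
#' @return PE in `[0, 1]`.
#' @examples
#' power_of_exclusion(0.8, 0.2)  # 0.59904
#' @export
power_of_exclusion <- function(obs_het, obs_hom = 1 - obs_het) {
  if (obs_het < 0 || obs_het > 1 || obs_hom < 0 || obs_hom > 1) {
    stop_strpop("proportions must lie in [0, 1]")
  }
  if (abs(obs_het + obs_hom - 1) > 1e-9) stop_strpop("obs_het + obs_hom must equal 1")
  obs_het^2 * (1 - 2 * obs_het * obs_hom^2)
}

# HWE-expected genotype frequencies from allele frequencies, as a named
# vector keyed "a1/a2" with a1 <= a2 in allele order.
#' @noRd
expected_genotype_freqs <- function(freqs) {
  a <- names(freqs)
  k <- length(a)
  out <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    g <- paste(a[i], a[j], sep = "/")
    out[g] <- if (i == j) freqs[[i]]^2 else 2 * freqs[[i]] * freqs[[j]]
  }
  out
}

# Observed genotype counts for one population x locus, keyed "a1/a2" with the
# two alleles in canonical allele order.
#' @noRd
observed_genotype_counts <- function(g, population, locus) {
  rows <- g$population == population
  a1 <- g[[paste0(locus, "_1")]][rows]
  a2 <- g[[paste0(locus, "_2")]][rows]
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- a1[keep]; a2 <- a2[keep]
  if (length(a1) == 0L) return(integer(0))
  lv <- sort_alleles(unique(c(a1, a2)))
  r1 <- match(a1, lv); r2 <- match(a2, lv)
  lo <- pmin(r1, r2); hi <- pmax(r1, r2)
  key <- paste(lv[lo], lv[hi], sep = "/")
  tab <- table(key)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-locus diversity, forensic and HWE statistics
#'
#' Computes, for every (population, locus) cell, the gene-copy count, number
#' of observed alleles, unbiased gene diversity, observed heterozygosity,
#' matching probability (PM), power of exclusion (PE) and a Hardy-Weinberg
#' exact-test p-value. From a [genotype_table()] the PM/PE use observed
#' genotype proportions (`pm_mode = "observed"`); from a frequencies-only
#' [freq_panel()] they use HWE-expected genotype proportions
#' (`pm_mode = "expected"`) and no HWE test is possible.
#'
#' @param x A `genotype_table` or a `freq_panel`.
#' @param hwe Run the HWE exact test per cell (genotype input only).
#' @param hwe_reps Monte Carlo replicates when enumeration is infeasible.
#' @param seed Seed for Monte Carlo HWE tests.
#' @return data.frame with one row per (population, locus).
#' @export
locus_stats <- function(x, hwe = TRUE, hwe_reps = 1e5, seed = NULL) {
  if (inherits(x, "genotype_table")) return(locus_stats_genotypes(x, hwe, hwe_reps, seed))
  if (inherits(x, "freq_panel")) return(locus_stats_panel(x))
  stop_strpop("x must be a genotype_table or freq_panel")
}

#' @noRd
locus_stats_genotypes <- function(g, hwe, hwe_reps, seed) {
  panel <- suppressMessages(allele_frequencies(g))
  rows <- list()
  for (p in panel$populations) for (l in panel$loci) {
    f <- panel$freq[[p]][[l]]
    if (is.null(f)) next
    n <- panel$n_copies[p, l]
    counts <- observed_genotype_counts(g, p, l)
    n_ind <- sum(counts)
    gfreq <- counts / n_ind
    het <- sum(gfreq[vapply(strsplit(names(gfreq), "/", fixed = TRUE),
                            function(z) z[1] != z[2], logical(1))])
    hp <- NA_real_; hm <- NA_character_
    if (hwe) {
      ht <- hwe_exact_test(counts, reps = hwe_reps, seed = seed)
      hp <- ht$p_value; hm <- ht$method
    }
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, n_copies = n, n_alleles = length(f),
      gene_diversity = gene_diversity(f, n), obs_het = het,
      pm = matching_probability(gfreq), pm_mode = "observed",
      epp = power_of_exclusion(het), hwe_p = hp, hwe_method = hm,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' @noRd
locus_stats_panel <- function(panel) {
  rows <- list()
  for (p in panel$populations) for (l in panel$loci) {
    f <- panel$freq[[p]][[l]]
    if (is.null(f)) next
    n <- panel$n_copies[p, l]
    gf <- expected_genotype_freqs(f)
    het <- 1 - sum(f^2)  # expected heterozygosity stands in for observed
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, n_copies = n, n_alleles = length(f),
      gene_diversity = gene_diversity(f, n), obs_het = het,
      pm = matching_probability(gf), pm_mode = "expected",
      epp = power_of_exclusion(het), hwe_p = NA_real_, hwe_method = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Combine per-locus statistics across a marker panel
#'
#' Per population: mean gene diversity, total allele count, combined power of
#' exclusion `1 - prod(1 - PE_l)` and combined matching probability
#' `prod(PM_l)`. Adding a locus never increases the combined PM and never
#' decreases the combined PE.
#'
#' @param per_locus data.frame as returned by [locus_stats()].
#' @return data.frame with one row per population.
#' @export
combine_panel <- function(per_locus) {
  stopifnot(is.data.frame(per_locus), nrow(per_locus) >= 1L)
  need <- c("population", "gene_diversity", "n_alleles", "epp", "pm")
  if (!all(need %in% names(per_locus))) {
    stop_strpop("per_locus must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(per_locus, per_locus$population), function(d) {
    data.frame(
      population = d$population[1L],
      n_loci = nrow(d),
      mean_gene_diversity = mean(d$gene_diversity),
      total_alleles = sum(d$n_alleles),
      combined_epp = 1 - prod(1 - d$epp),
      combined_pm = prod(d$pm),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out[unique(per_locus$population)])
  rownames(res) <- NULL
  res
}

#' Nei's coefficient of gene differentiation (Gst)
#'
#' `Gst = (H_T - H_S) / H_T` with `H_S` the (weighted) mean within-population
#' expected heterozygosity and `H_T` the expected heterozygosity of the
#' weighted mean allele frequencies. Following the Nei (1973) convention,
#' `H_S` and `H_T` are computed per locus, averaged across loci, and the
#' ratio formed from the averages; `average = "per_locus_ratio"` instead
#' averages the per-locus ratios.
#'
#' @param panel A [freq_panel()].
#' @param weights `"equal"` or `"by_n"` (proportional to gene-copy counts).
#' @param average Averaging order across loci (see above).
#' @return Gst in `[0, 1]`.
#' @export
gst <- function(panel, weights = c("equal", "by_n"),
                average = c("nei1973", "per_locus_ratio")) {
  stopifnot(inherits(panel, "freq_panel"))
  weights <- match.arg(weights)
  average <- match.arg(average)
  if (length(panel$populations) < 2L) stop_strpop("gst needs >= 2 populations")
  hs <- ht <- numeric(0)
  for (l in panel$loci) {
    m <- locus_freq_matrix(panel, l)
    if (nrow(m) < 2L) next
    w <- if (weights == "by_n") panel$n_copies[rownames(m), l] else rep(1, nrow(m))
    w <- w / sum(w)
    hs_l <- sum(w * (1 - rowSums(m^2)))
    xbar <- colSums(w * m)
    ht_l <- 1 - sum(xbar^2)
    hs <- c(hs, hs_l); ht <- c(ht, ht_l)
  }
  if (length(ht) == 0L || mean(ht) <= 0) {
    stop_strpop("Gst undefined: total expected heterozygosity is zero")
  }
  if (average == "nei1973") {
    (mean(ht) - mean(hs)) / mean(ht)
  } else {
    keep <- ht > 0
    mean((ht[keep] - hs[keep]) / ht[keep])
  }
}

#' Panel-level heterozygosity summary for the R-matrix model
#'
#' `h_i` is each population's average heterozygosity: the unbiased expected
#' heterozygosity `n/(n-1)(1 - sum x^2)` averaged over loci. `h_t` is the
#' overall mean heterozygosity, the weighted mean of `h_i`.
#'
#' @inheritParams gst
#' @return list with `h_i` (named vector), `h_t`, `weights` (named vector),
#'   `gst`.
#' @export
panel_stats <- function(panel, weights = c("by_n", "equal")) {
  stopifnot(inherits(panel, "freq_panel"))
  weights <- match.arg(weights)
  h_i <- vapply(panel$populations, function(p) {
    hs <- vapply(panel$loci, function(l) {
      f <- panel$freq[[p]][[l]]
      if (is.null(f)) return(NA_real_)
      gene_diversity(f, panel$n_copies[p, l])
    }, numeric(1))
    mean(hs, na.rm = TRUE)
  }, numeric(1))
  w <- if (weights == "by_n") rowMeans(panel$n_copies) else rep(1, length(h_i))
  w <- w / sum(w)
  names(w) <- panel$populations
  list(h_i = h_i, h_t = sum(w * h_i), weights = w,
       gst = gst(panel, weights = if (weights == "by_n") "by_n" else "equal"))
}
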