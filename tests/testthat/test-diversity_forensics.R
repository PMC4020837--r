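test_that("gene diversity matches the unbiased formula", {
  expect_equal(gene_diversity(c(A = 1.0), 100), 0)
  expect_equal(gene_diversity(c(A = 0.5, B = 0.5), 100), 100 / 99 * 0.5)
  expect_error(gene_diversity(c(A = 1), 1), "n must be")

  set.seed(11)
  for (i in 1:10) {
    x <- rgamma(5, 1); x <- x / sum(x)
    names(x) <- letters[1:5]
    oracle <- 200 / 199 * (1 - x[1]^2 - x[2]^2 - x[3]^2 - x[4]^2 - x[5]^2)
    expect_equal(gene_diversity(x, 200), unname(oracle), tolerance = 1e-12)
    # invariant under allele relabeling
    expect_equal(gene_diversity(setNames(x, rev(names(x))), 200),
                 gene_diversity(x, 200))
  }
  # strictly decreases as one frequency tends to 1
  hs <- vapply(c(0.5, 0.7, 0.9, 0.99), function(p) {
    gene_diversity(c(A = p, B = 1 - p), 100)
  }, 1)
  expect_true(all(diff(hs) < 0))
})

test_that("matching probability equals the pairwise match fraction", {
  expect_equal(matching_probability(c(g1 = 1)), 1)
  expect_equal(matching_probability(c(g1 = 0.5, g2 = 0.5)), 0.5)
  expect_error(matching_probability(numeric(0)), "empty")

  # 50-individual synthetic locus: PM == brute-force ordered-pair match
  # fraction (with replacement)
  set.seed(3)
  geno <- paste(sample(8:11, 50, TRUE), sample(8:11, 50, TRUE), sep = "/")
  geno <- vapply(strsplit(geno, "/"), function(z) paste(sort(z), collapse = "/"), "")
  match_frac <- mean(outer(geno, geno, "=="))
  f <- table(geno) / length(geno)
  expect_equal(matching_probability(as.numeric(f)), match_frac, tolerance = 1e-12)
})

test_that("power of exclusion follows Brenner's formula", {
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(power_of_exclusion(1, 0), 1)
  expect_equal(power_of_exclusion(0.8, 0.2), 0.59904)
  expect_error(power_of_exclusion(1.2, -0.2), "\\[0, 1\\]")
})

test_that("panel combination follows the product formulas and is monotone", {
  one <- data.frame(population = "P", locus = "L1", gene_diversity = 0.5,
                    n_alleles = 5L, epp = 0.9, pm = 0.1)
  got <- combine_panel(one)
  expect_equal(got$combined_epp, 0.9)
  expect_equal(got$combined_pm, 0.1)

  two <- rbind(one, within(one, { locus <- "L2"; epp <- 0.5; pm <- 0.2 }))
  two$epp <- c(0.5, 0.5)
  expect_equal(combine_panel(two)$combined_epp, 0.75)

  # log-space product oracle on nine loci
  set.seed(21)
  nine <- data.frame(population = "P", locus = paste0("L", 1:9),
                     gene_diversity = runif(9), n_alleles = 5L,
                     epp = runif(9), pm = runif(9))
  got9 <- combine_panel(nine)
  expect_equal(got9$combined_pm, exp(sum(log(nine$pm))), tolerance = 1e-12)
  expect_equal(got9$combined_epp, 1 - exp(sum(log(1 - nine$epp))), tolerance = 1e-12)

  # appending a locus never increases PM, never decreases EPP
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(population = "P", locus = paste0("L", 1:6),
                    gene_diversity = runif(6), n_alleles = 4L,
                    epp = runif(6), pm = runif(6))
    a <- combine_panel(d[1:5, ])
    b <- combine_panel(d)
    expect_lte(b$combined_pm, a$combined_pm)
    expect_gte(b$combined_epp, a$combined_epp)
  }
})

test_that("HWE enumeration matches an independently coded 2-allele oracle", {
  expect_equal(hwe_exact_test(c("A/A" = 10))$p_value, 1)

  got <- hwe_exact_test(c("A/A" = 5, "B/B" = 5))
  expect_equal(got$method, "enumeration")
  expect_equal(got$p_value, oracle_hwe2(5, 0, 5), tolerance = 1e-9)

  mc <- hwe_exact_test(c("A/A" = 5, "B/B" = 5), mode = "monte_carlo",
                       reps = 1e5, seed = 1)
  se <- sqrt(got$p_value * (1 - got$p_value) / 1e5)
  expect_lt(abs(mc$p_value - got$p_value), 3 * se + 2 / 1e5)

  tab3 <- c("A/A" = 3, "A/B" = 5, "B/B" = 2, "A/C" = 1, "C/C" = 2)
  e3 <- hwe_exact_test(tab3)
  expect_equal(e3$method, "enumeration")
  m3 <- hwe_exact_test(tab3, mode = "monte_carlo", reps = 5e4, seed = 2)
  se3 <- sqrt(e3$p_value * (1 - e3$p_value) / 5e4)
  expect_lt(abs(m3$p_value - e3$p_value), 3 * se3 + 4 / 5e4)

  expect_error(hwe_exact_test(c("A/A" = 500, "B/B" = 500, "A/B" = 200),
                              mode = "enumeration"), "monte_carlo")
})

test_that("HWE enumeration agrees with the oracle across all n = 8 two-allele tables", {
  for (nAB in 0:8) for (nAA in 0:(8 - nAB)) {
    nBB <- 8 - nAB - nAA
    counts <- c("A/A" = nAA, "A/B" = nAB, "B/B" = nBB)
    counts <- counts[counts > 0]
    if (length(counts) == 0L) next
    got <- hwe_exact_test(counts)$p_value
    expect_equal(got, oracle_hwe2(nAA, nAB, nBB), tolerance = 1e-9,
                 info = sprintf("table (%d,%d,%d)", nAA, nAB, nBB))
  }
})

test_that("HWE monte carlo tracks enumeration on a sweep of n = 8 tables", {
  for (nAB in c(0, 2, 4, 8)) {
    nAA <- (8 - nAB) %/% 2
    nBB <- 8 - nAB - nAA
    counts <- c("A/A" = nAA, "A/B" = nAB, "B/B" = nBB)
    counts <- counts[counts > 0]
    pe <- hwe_exact_test(counts)$p_value
    pm <- hwe_exact_test(counts, mode = "monte_carlo", reps = 3000,
                         seed = nAB + 1)$p_value
    se <- sqrt(pe * (1 - pe) / 3000)
    expect_lt(abs(pm - pe), 3 * se + 2 / 3000)
  }
})

test_that("Gst behaves at the boundaries and stays in [0, 1]", {
  f <- list(L1 = c(A = 0.3, B = 0.7))
  same <- freq_panel(c("P1", "P2"), "L1", list(P1 = f, P2 = f),
                     matrix(100L, 2, 1))
  expect_equal(gst(same), 0)

  fixed <- freq_panel(c("P1", "P2"), "L1",
                      list(P1 = list(L1 = c(A = 1)), P2 = list(L1 = c(B = 1))),
                      matrix(100L, 2, 1))
  expect_equal(gst(fixed), 1)

  mono <- freq_panel(c("P1", "P2"), "L1",
                     list(P1 = list(L1 = c(A = 1)), P2 = list(L1 = c(A = 1))),
                     matrix(100L, 2, 1))
  expect_error(gst(mono), "undefined")

  for (seed in 1:6) {
    panel <- random_panel(n_pops = 4, n_loci = 3, seed = seed)
    g <- gst(panel)
    expect_gte(g, 0)
    expect_lte(g, 1)
    expect_gt(g, 0)  # random panels are never exactly identical
  }
})

test_that("locus_stats supports observed and expected PM modes", {
  gt <- make_gt(list(P1 = list("A/A", "A/B", "B/B", "A/B")), loci = "L1")
  obs <- locus_stats(gt, hwe = FALSE)
  expect_equal(obs$pm_mode, "observed")
  expect_equal(obs$obs_het, 0.5)
  expect_equal(obs$pm, (1 / 4)^2 + (2 / 4)^2 + (1 / 4)^2)
  expect_equal(obs$epp, power_of_exclusion(0.5))

  panel <- allele_frequencies(gt)
  exp_mode <- locus_stats(panel)
  expect_equal(exp_mode$pm_mode, "expected")
  # HWE-expected PM at p = q = 0.5: (0.25^2 + 0.5^2 + 0.25^2)
  expect_equal(exp_mode$pm, 0.375)

  hw <- locus_stats(gt, hwe = TRUE, seed = 1)
  expect_true(hw$hwe_method %in% c("enumeration", "monte_carlo"))
  expect_true(hw$hwe_p > 0 && hw$hwe_p <= 1)
})
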