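test_that("covariance PCA flags degeneracy and matches an eigensolver oracle", {
  f <- list(L1 = c(A = 0.4, B = 0.6), L2 = c(A = 0.2, B = 0.8))
  same <- freq_panel(paste0("P", 1:4), c("L1", "L2"),
                     setNames(rep(list(f), 4), paste0("P", 1:4)),
                     matrix(100L, 4, 2))
  res <- covariance_pca(same)
  expect_true(res$degenerate)
  expect_equal(res$component_count, 0L)

  panel <- random_panel(n_pops = 6, n_loci = 4, seed = 31)
  res2 <- covariance_pca(panel)
  expect_false(res2$degenerate)
  expect_true(all(diff(res2$variance_ratio) <= 1e-12))
  expect_lte(sum(res2$variance_ratio), 1 + 1e-9)

  # independent oracle: assemble the averaged covariance directly, eigen it
  C <- matrix(0, 6, 6)
  for (l in panel$loci) {
    alleles <- sort(unique(unlist(lapply(panel$populations,
                                         function(p) names(panel$freq[[p]][[l]])))))
    X <- t(vapply(panel$populations, function(p) {
      v <- setNames(numeric(length(alleles)), alleles)
      v[names(panel$freq[[p]][[l]])] <- panel$freq[[p]][[l]]
      v
    }, numeric(length(alleles))))
    Xc <- scale(X, center = TRUE, scale = FALSE)
    C <- C + Xc %*% t(Xc)
  }
  C <- C / length(panel$loci)
  ev <- eigen(C, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  expect_equal(res2$variance_ratio,
               (ev / sum(ev))[seq_len(res2$component_count)], tolerance = 1e-9)

  expect_error(covariance_pca(panel, n_components = 10), "fewer populations")
})

test_that("PCA separates two synthetic clusters on the first component", {
  set.seed(77)
  anc1 <- lapply(1:6, function(l) { x <- rgamma(6, 1); setNames(x / sum(x), as.character(1:6)) })
  anc2 <- lapply(1:6, function(l) { x <- rgamma(6, 1); setNames(x / sum(x), as.character(1:6)) })
  g1 <- simulate_panel(sim_config(n_populations = 3, n_loci = 6, sample_sizes = 80,
                                  drift_f = 0.01, ancestral_freqs = anc1,
                                  population_names = paste0("A", 1:3), seed = 1))
  g2 <- simulate_panel(sim_config(n_populations = 3, n_loci = 6, sample_sizes = 80,
                                  drift_f = 0.01, ancestral_freqs = anc2,
                                  population_names = paste0("B", 1:3), seed = 2))
  g <- genotype_table(rbind(as.data.frame(g1), as.data.frame(g2)))
  res <- covariance_pca(allele_frequencies(g))
  pc1 <- res$scores[, 1]
  expect_true(all(sign(pc1[paste0("A", 1:3)]) == sign(pc1["A1"])))
  expect_true(all(sign(pc1[paste0("B", 1:3)]) == -sign(pc1["A1"])))
})

test_that("PCA variance ratios are invariant to population order", {
  panel <- random_panel(n_pops = 5, n_loci = 3, seed = 8)
  perm <- c(3, 1, 5, 2, 4)
  pp <- panel$populations[perm]
  panel2 <- freq_panel(pp, panel$loci, panel$freq[pp],
                       panel$n_copies[pp, , drop = FALSE])
  r1 <- covariance_pca(panel)
  r2 <- covariance_pca(panel2)
  expect_equal(r1$variance_ratio, r2$variance_ratio, tolerance = 1e-9)
  # scores agree up to row permutation and component sign
  for (k in seq_len(min(3, r1$component_count))) {
    a <- r1$scores[panel2$populations, k]
    b <- r2$scores[, k]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
})

test_that("R matrix matches the hand-computed biallelic example", {
  panel <- freq_panel(
    c("P1", "P2"), "L1",
    list(P1 = list(L1 = c(A = 0.6, B = 0.4)),
         P2 = list(L1 = c(A = 0.4, B = 0.6))),
    matrix(100L, 2, 1)
  )
  rm <- r_matrix(panel, weights = "equal")
  expect_equal(unname(rm$r_ii), c(0.04, 0.04), tolerance = 1e-12)
  expect_equal(rm$r[1, 2], -0.04, tolerance = 1e-12)
})

test_that("R matrix is centered, PSD, and zero for identical populations", {
  f <- list(L1 = c(A = 0.3, B = 0.7), L2 = c(A = 0.5, B = 0.5))
  same <- freq_panel(paste0("P", 1:3), c("L1", "L2"),
                     setNames(rep(list(f), 3), paste0("P", 1:3)),
                     matrix(60L, 3, 2))
  rs <- r_matrix(same)
  expect_true(all(abs(rs$r) < 1e-12))

  for (seed in 1:6) {
    panel <- random_panel(n_pops = 5, n_loci = 4, seed = seed,
                          n_copies = 50 + 10 * seed)
    for (w in c("by_n", "equal")) {
      rm <- r_matrix(panel, weights = w)
      expect_lt(max(abs(rm$weights %*% rm$r)), 1e-9)      # centroid property
      expect_gte(min(eigen(rm$r, symmetric = TRUE)$values), -1e-9)  # PSD
      expect_true(all(rm$r_ii >= 0))
    }
  }

  mono <- freq_panel(c("P1", "P2"), "L1",
                     list(P1 = list(L1 = c(A = 1)), P2 = list(L1 = c(A = 1))),
                     matrix(100L, 2, 1))
  expect_error(r_matrix(mono), "no informative")
})

test_that("R-matrix regression uses the theoretical line H_t (1 - r_ii)", {
  panel <- random_panel(n_pops = 5, n_loci = 4, seed = 19)
  rm <- r_matrix(panel)
  rr <- rmatrix_regression(rm)
  expect_equal(rr$table$expected_h, rm$h_t * (1 - rr$table$r_ii), tolerance = 1e-12)
  expect_equal(rr$table$residual, rr$table$h_i - rr$table$expected_h, tolerance = 1e-12)
  expect_true(all(rr$table$classification %in% c("above", "below")))
  # a population exactly at the centroid would have expected_h = h_t
  expect_equal(rm$h_t * (1 - 0), rm$h_t)
  # weighted residuals are near zero on average: h_t is the weighted mean h_i
  expect_lt(abs(sum(rm$weights * rr$table$residual) -
                  rm$h_t * sum(rm$weights * rr$table$r_ii)), 1e-9)
})

test_that("weighted mean r_ii tracks Gst across drift levels", {
  fs <- c(0.01, 0.05, 0.1)
  stats <- t(vapply(fs, function(F) {
    v <- vapply(1:8, function(r) {
      cfg <- sim_config(n_populations = 5, n_loci = 6, sample_sizes = 60,
                        drift_f = F, seed = round(10000 * F) + r)
      panel <- allele_frequencies(simulate_panel(cfg))
      rm <- r_matrix(panel)
      c(sum(rm$weights * rm$r_ii), gst(panel))
    }, c(rbar = 1, gst = 1))
    rowMeans(v)
  }, c(rbar = 1, gst = 1)))
  expect_equal(cor(stats[, "rbar"], stats[, "gst"], method = "spearman"), 1)
  expect_true(all(diff(stats[, "rbar"]) > 0))
})
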