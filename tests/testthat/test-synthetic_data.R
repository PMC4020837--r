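test_that("sim_config validates its parameters", {
  expect_error(sim_config(drift_f = 0), "drift_f")
  expect_error(sim_config(migrant_fraction = 1), "migrant_fraction")
  expect_error(sim_config(n_populations = 3, sample_sizes = 1), "sample_sizes")
  expect_error(sim_config(dirichlet_alpha = -1), "dirichlet_alpha")
  cfg <- sim_config()
  expect_equal(cfg$n_populations, 13L)
  expect_equal(cfg$n_loci, 9L)
  expect_equal(cfg$sample_sizes, as.integer(nwc_population_meta()$chromosomes / 2))
})

test_that("a fixed seed reproduces the genotype table bit-exactly", {
  cfg <- sim_config(n_populations = 3, n_loci = 4, sample_sizes = 15, seed = 5)
  g1 <- simulate_panel(cfg)
  g2 <- simulate_panel(cfg)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  g3 <- simulate_panel(cfg, seed = 6)
  expect_false(identical(as.data.frame(g1), as.data.frame(g3)))
})

test_that("degenerate Dirichlet parameters are rejected", {
  bad_anc <- lapply(1:2, function(l) c(a = 0.5, b = 0.5, c = 0))
  expect_error(sim_config(n_populations = 2, n_loci = 2,
                          ancestral_freqs = bad_anc), "positive")
  expect_error(strpop:::rdirichlet1(c(1, 0)), "Dirichlet")
})

test_that("the no-drift limit produces essentially identical populations", {
  # measured on the generator's realized frequencies: estimated frequencies
  # carry a sampling-noise floor of ~(k-1)/(4 n) per locus that the drift
  # parameter cannot remove (see the methods vignette)
  q <- c()
  for (r in 1:20) {
    cfg <- sim_config(drift_f = 1e-6, seed = 1000 + r)
    g <- simulate_panel(cfg)
    truth <- attr(g, "truth")
    pf <- truth$pop_freqs
    pops <- names(pf)
    for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
      q <- c(q, da_distance(pf[[i]], pf[[j]]))
    }
  }
  expect_lte(stats::quantile(q, 0.99), 0.01)
})

test_that("admixture pulls the receiving population toward the source", {
  mf <- c(0, 0, 0.4, 0)
  cfg <- sim_config(n_populations = 4, n_loci = 6, sample_sizes = 50,
                    drift_f = 0.02, migrant_fraction = mf, source_f = 0.3,
                    seed = 88)
  g <- simulate_panel(cfg)
  truth <- attr(g, "truth")
  expect_false(is.null(truth$source_freqs))
  d_src <- vapply(seq_len(4), function(i) {
    da_distance(truth$pop_freqs[[i]], truth$source_freqs)
  }, 1)
  expect_true(all(d_src[3] < d_src[-3]))
})

test_that("within-population genotypes are at Hardy-Weinberg at the nominal rate", {
  # 150 (population, locus) cells, Monte Carlo at 1000 reps (scaled down from
  # the nominal 500-cell sweep to stay inside the suite's time budget)
  ps <- c()
  r <- 0
  while (length(ps) < 150) {
    r <- r + 1
    cfg <- sim_config(n_populations = 5, n_loci = 6, sample_sizes = 40,
                      drift_f = 0.05, seed = 20000 + r)
    g <- simulate_panel(cfg)
    for (p in gt_populations(g)) for (l in gt_loci(g)) {
      counts <- strpop:::observed_genotype_counts(g, p, l)
      ps <- c(ps, hwe_exact_test(counts, reps = 1000,
                                 seed = length(ps) + 1)$p_value)
    }
  }
  ps <- ps[1:150]
  frac <- mean(ps <= 0.05)
  bounds <- stats::qbinom(c(0.005, 0.995), 150, 0.05) / 150
  expect_gte(frac, bounds[1] - 1e-12)
  expect_lte(frac, bounds[2] + 1e-12)
})

test_that("two divergent blocks are recovered with high bootstrap support", {
  set.seed(6001)
  anc1 <- lapply(1:9, function(l) { x <- rgamma(8, 1) + 1e-6; setNames(x / sum(x), as.character(6:13)) })
  anc2 <- lapply(1:9, function(l) { x <- rgamma(8, 1) + 1e-6; setNames(x / sum(x), as.character(6:13)) })
  g1 <- simulate_panel(sim_config(n_populations = 4, n_loci = 9, sample_sizes = 60,
                                  drift_f = 0.01, ancestral_freqs = anc1,
                                  population_names = paste0("A", 1:4), seed = 7001))
  g2 <- simulate_panel(sim_config(n_populations = 4, n_loci = 9, sample_sizes = 60,
                                  drift_f = 0.01, ancestral_freqs = anc2,
                                  population_names = paste0("B", 1:4), seed = 8001))
  g <- genotype_table(rbind(as.data.frame(g1), as.data.frame(g2)))
  bt <- bootstrap_tree(allele_frequencies(g), reps = 200, seed = 1)
  sup <- attr(bt, "bootstrap")$support
  key <- paste(paste0("B", 1:4), collapse = "|")  # side without tip A1
  expect_true(key %in% names(sup))
  expect_gte(sup[[key]], 95)
})

test_that("isolation-by-distance simulation carries (only) the intended signal", {
  meta <- nwc_population_meta()
  co <- meta[, c("longitude", "latitude")]
  geo <- geographic_distances(meta)

  expect_error(simulate_ibd_panel(sim_config(n_populations = 13)), "coordinates")

  # slope 0: no geographic signal; p behaves like a null p-value
  p0 <- vapply(1:10, function(r) {
    cfg <- sim_config(n_populations = 13, n_loci = 9, sample_sizes = 50,
                      drift_f = 0.05, coordinates = co, ibd_slope = 0,
                      seed = 5000 + r)
    d <- pairwise_da(allele_frequencies(simulate_ibd_panel(cfg)))
    mantel_test(d, geo, n_permutations = 199, seed = r)$p_value
  }, 1)
  expect_lte(sum(p0 <= 0.05), stats::qbinom(0.995, 10, 0.05))

  # strong slope: decisive signal (power check scaled to 10 replicates here;
  # the full 50-replicate version runs in the acceptance suite)
  p1 <- vapply(1:10, function(r) {
    cfg <- sim_config(n_populations = 13, n_loci = 9, sample_sizes = 100,
                      drift_f = 0.05, coordinates = co, ibd_slope = 2,
                      seed = 4000 + r)
    d <- pairwise_da(allele_frequencies(simulate_ibd_panel(cfg)))
    mantel_test(d, geo, n_permutations = 999, seed = r)$p_value
  }, 1)
  expect_gte(mean(p1 <= 0.01), 0.9)

  # specificity: language labels independent of geography give a partial
  # correlation centered on zero (signed mean; see decisions on |r|)
  rs <- vapply(1:20, function(r) {
    cfg <- sim_config(n_populations = 13, n_loci = 9, sample_sizes = 60,
                      drift_f = 0.05, coordinates = co, ibd_slope = 2,
                      seed = 9000 + r)
    d <- pairwise_da(allele_frequencies(simulate_ibd_panel(cfg)))
    m2 <- meta
    set.seed(r)
    m2$phylum <- sample(c("P1", "P2"), 13, replace = TRUE)
    m2$family <- sample(c("F1", "F2", "F3"), 13, replace = TRUE)
    m2$language <- paste0("lang", 1:13)
    lan <- linguistic_distances(m2)
    partial_mantel_test(d, lan, geo, n_permutations = 9, seed = r)$r
  }, 1)
  expect_lte(abs(mean(rs)), 0.1)
})
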