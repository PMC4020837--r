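#' Simulation configuration for synthetic STR panels
#'
#' The generator is a multi-allelic Balding-Nichols model: per locus,
#' population allele frequencies are drawn from
#' `Dirichlet(ancestral * (1 - F) / F)`, so `F` controls the Wright-like
#' drift of each population away from the shared ancestral frequencies;
#' genotypes are then two independent copies per individual (within-
#' population Hardy-Weinberg). Defaults mirror the motivating study's scale:
#' 13 populations, 9 loci, 6-12 alleles per locus, and the study's
#' per-population chromosome counts as sample sizes.
#'
#' @param n_populations,n_loci Panel dimensions.
#' @param alleles_per_locus Integer (recycled) or per-locus vector; `NULL`
#'   draws each locus's allele count uniformly from 6:12 at simulation time.
#' @param ancestral_freqs Optional list of per-locus named frequency vectors;
#'   `NULL` draws each from a symmetric `Dirichlet(dirichlet_alpha)`.
#' @param dirichlet_alpha Concentration of the ancestral draw (default 1).
#' @param drift_f Per-population F in (0, 1), scalar or length
#'   `n_populations`.
#' @param coordinates Optional data.frame with `longitude`, `latitude` (one
#'   row per population) for isolation-by-distance simulation.
#' @param ibd_slope Strength of the spatially correlated drift component in
#'   [simulate_ibd_panel()] (0 = none), as a multiple of the independent
#'   drift scale.
#' @param migrant_fraction Per-population admixture proportion in `[0, 1)`
#'   from a designated external source population (scalar or vector).
#' @param source_f Drift of the external source population from the
#'   ancestral frequencies.
#' @param sample_sizes Individuals per population (>= 2), scalar or vector.
#'   `NULL` uses the packaged study chromosome counts / 2.
#' @param population_names Labels; `NULL` uses the packaged study names when
#'   `n_populations == 13`, else `Pop01`, `Pop02`, ...
#' @param seed Default seed used by the simulators.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 13L, n_loci = 9L,
                       alleles_per_locus = NULL, ancestral_freqs = NULL,
                       dirichlet_alpha = 1, drift_f = 0.05,
                       coordinates = NULL, ibd_slope = 0,
                       migrant_fraction = 0, source_f = 0.1,
                       sample_sizes = NULL, population_names = NULL,
                       seed = NULL) {
  if (!is_count(n_populations, 2L)) stop_strpop("n_populations must be >= 2")
  if (!is_count(n_loci, 1L)) stop_strpop("n_loci must be >= 1")
  drift_f <- rep_len(drift_f, n_populations)
  if (any(drift_f <= 0 | drift_f >= 1)) stop_strpop("drift_f must lie in (0, 1)")
  migrant_fraction <- rep_len(migrant_fraction, n_populations)
  if (any(migrant_fraction < 0 | migrant_fraction >= 1)) {
    stop_strpop("migrant_fraction must lie in [0, 1)")
  }
  if (source_f <= 0 || source_f >= 1) stop_strpop("source_f must lie in (0, 1)")
  if (dirichlet_alpha <= 0) stop_strpop("dirichlet_alpha must be > 0")
  if (is.null(population_names)) {
    population_names <- if (n_populations == 13L) nwc_population_meta()$name
                        else sprintf("Pop%02d", seq_len(n_populations))
  }
  stopifnot(length(population_names) == n_populations)
  if (is.null(sample_sizes)) {
    sample_sizes <- if (n_populations == 13L) {
      as.integer(nwc_population_meta()$chromosomes / 2)
    } else rep(50L, n_populations)
  }
  sample_sizes <- rep_len(as.integer(sample_sizes), n_populations)
  if (any(sample_sizes < 2L)) stop_strpop("sample_sizes must be >= 2")
  if (!is.null(alleles_per_locus)) {
    alleles_per_locus <- rep_len(as.integer(alleles_per_locus), n_loci)
    if (any(alleles_per_locus < 2L)) stop_strpop("alleles_per_locus must be >= 2")
  }
  if (!is.null(coordinates)) {
    stopifnot(is.data.frame(coordinates),
              all(c("longitude", "latitude") %in% names(coordinates)),
              nrow(coordinates) == n_populations)
  }
  if (!is.null(ancestral_freqs)) {
    stopifnot(is.list(ancestral_freqs), length(ancestral_freqs) == n_loci)
    for (f in ancestral_freqs) {
      if (any(f <= 0)) stop_strpop("ancestral frequencies must be positive")
      if (abs(sum(f) - 1) > 1e-9) stop_strpop("ancestral frequencies must sum to 1")
    }
  }
  structure(list(n_populations = as.integer(n_populations),
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = alleles_per_locus,
                 ancestral_freqs = ancestral_freqs,
                 dirichlet_alpha = dirichlet_alpha, drift_f = drift_f,
                 coordinates = coordinates, ibd_slope = ibd_slope,
                 migrant_fraction = migrant_fraction, source_f = source_f,
                 sample_sizes = sample_sizes,
                 population_names = population_names, seed = seed),
            class = "sim_config")
}

#' @noRd
rdirichlet1 <- function(alpha) {
  if (any(alpha <= 0)) stop_strpop("degenerate Dirichlet parameter (component <= 0)")
  g <- stats::rgamma(length(alpha), shape = alpha)
  while (sum(g) == 0) g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' @noRd
draw_ancestral <- function(cfg) {
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))
  lapply(stats::setNames(loci, loci), function(l) {
    k <- if (is.null(cfg$alleles_per_locus)) sample(6:12, 1L)
         else cfg$alleles_per_locus[match(l, loci)]
    if (!is.null(cfg$ancestral_freqs)) {
      f <- cfg$ancestral_freqs[[match(l, loci)]]
      if (is.null(names(f))) names(f) <- as.character(seq(6, length.out = length(f)))
      return(f)
    }
    stats::setNames(rdirichlet1(rep(cfg$dirichlet_alpha, k)),
                    as.character(seq(6, length.out = k)))  # STR-like repeat labels
  })
}

#' @noRd
genotypes_from_freqs <- function(pop_freqs, cfg) {
  loci <- names(pop_freqs[[1L]])
  rows <- vector("list", cfg$n_populations)
  for (pi in seq_len(cfg$n_populations)) {
    p <- cfg$population_names[pi]
    n <- cfg$sample_sizes[pi]
    df <- data.frame(individual_id = sprintf("%s_%03d", p, seq_len(n)),
                     population = p, stringsAsFactors = FALSE)
    for (l in loci) {
      f <- pop_freqs[[pi]][[l]]
      calls <- sample(names(f), 2L * n, replace = TRUE, prob = f)
      df[[paste0(l, "_1")]] <- calls[seq_len(n)]
      df[[paste0(l, "_2")]] <- calls[n + seq_len(n)]
    }
    rows[[pi]] <- df
  }
  genotype_table(do.call(rbind, rows))
}

#' Simulate a drifted STR genotype panel
#'
#' See [sim_config()] for the generating model. The exact generating
#' parameters (ancestral and realized population frequencies, source
#' frequencies when admixture is on) are attached as attribute `"truth"` for
#' parameter-recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed (default `cfg$seed`); fixed seed gives a
#'   bit-identical table.
#' @return A [genotype_table()] with attribute `"truth"`.
#' @export
simulate_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    anc <- draw_ancestral(cfg)
    source_freqs <- if (any(cfg$migrant_fraction > 0)) {
      lapply(anc, function(a) {
        stats::setNames(rdirichlet1(a * (1 - cfg$source_f) / cfg$source_f), names(a))
      })
    } else NULL
    pop_freqs <- lapply(seq_len(cfg$n_populations), function(pi) {
      F <- cfg$drift_f[pi]
      m <- cfg$migrant_fraction[pi]
      out <- list()
      for (l in names(anc)) {
        p <- stats::setNames(rdirichlet1(anc[[l]] * (1 - F) / F), names(anc[[l]]))
        if (m > 0) p <- (1 - m) * p + m * source_freqs[[l]]
        out[[l]] <- p
      }
      out
    })
    g <- genotypes_from_freqs(pop_freqs, cfg)
    attr(g, "truth") <- list(cfg = cfg, ancestral = anc,
                             pop_freqs = stats::setNames(pop_freqs, cfg$population_names),
                             source_freqs = source_freqs)
    g
  })
}

#' Simulate an isolation-by-distance structured panel
#'
#' Population frequencies are log-normal perturbations of the ancestral
#' frequencies: `p_i ∝ ancestral * exp(z_i)`, where `z` has an independent
#' component of standard deviation `sigma = sqrt(2 * drift_f)` and a
#' spatially correlated Gaussian field of standard deviation
#' `ibd_slope * sigma` with correlation `exp(-d_ij / d_scale)` (`d_scale` =
#' median pairwise great-circle distance). Pairs far apart share less of the
#' field, so pairwise differentiation increases with distance; `ibd_slope =
#' 0` gives independent drift and no geographic signal.
#'
#' @inheritParams simulate_panel
#' @return A [genotype_table()] with attribute `"truth"` (including the
#'   generating slope).
#' @export
simulate_ibd_panel <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$coordinates)) stop_strpop("simulate_ibd_panel needs cfg$coordinates")
  with_seed(seed, {
    anc <- draw_ancestral(cfg)
    n <- cfg$n_populations
    co <- cfg$coordinates
    d <- outer(seq_len(n), seq_len(n), function(i, j) {
      haversine_distance(co$longitude[i], co$latitude[i],
                         co$longitude[j], co$latitude[j])
    })
    d_scale <- stats::median(d[lower.tri(d)])
    K <- exp(-d / max(d_scale, 1e-9))
    Lk <- chol(K + diag(1e-10, n))
    sigma <- sqrt(2 * mean(cfg$drift_f))
    pop_freqs <- lapply(seq_len(n), function(i) list())
    for (l in names(anc)) {
      a <- anc[[l]]
      k <- length(a)
      z_iid <- matrix(stats::rnorm(n * k, sd = sigma), n, k)
      z_sp <- if (cfg$ibd_slope > 0) {
        crossprod(Lk, matrix(stats::rnorm(n * k), n, k)) * (cfg$ibd_slope * sigma)
      } else matrix(0, n, k)
      z <- z_iid + z_sp
      for (i in seq_len(n)) {
        p <- a * exp(z[i, ])
        pop_freqs[[i]][[l]] <- stats::setNames(p / sum(p), names(a))
      }
    }
    g <- genotypes_from_freqs(pop_freqs, cfg)
    attr(g, "truth") <- list(cfg = cfg, ancestral = anc,
                             pop_freqs = stats::setNames(pop_freqs, cfg$population_names),
                             ibd_slope = cfg$ibd_slope, d_scale = d_scale)
    g
  })
}
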