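#' Run the end-to-end STR population-structure pipeline
#'
#' Orchestrates: input loading (genotypes, or a frequencies-only table, or a
#' precomputed genetic-distance matrix) -> per-locus/per-population
#' diversity and forensic statistics -> pairwise D_A matrix -> NJ tree with
#' locus-bootstrap supports -> covariance PCA -> R-matrix regression ->
#' geographic/linguistic distances and Mantel tests. Stages whose inputs are
#' unavailable are skipped with a logged reason; every seed and replicate
#' count is recorded in a JSON run manifest, and re-running with the same
#' config reproduces all stochastic outputs bit-exactly.
#'
#' @param config A named list, or a path to a YAML/JSON config file, with
#'   fields: `genotypes` (path), `frequencies` (path), `da_matrix` (path or
#'   `"fixture"`), `meta` (path or `"fixture"`), `out_dir` (required),
#'   `bootstrap_reps` (default 1000), `n_permutations` (default 9999),
#'   `seed` (default 1), `weights` (`"by_n"`/`"equal"`), `hwe_reps`
#'   (default 10000), `pca_components` (default 3), `stages` (character
#'   vector subset of `c("stats","tree","pca","rmatrix","mantel")`).
#' @return The run manifest (a list), invisibly; artifacts are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop_strpop("config$out_dir is required")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    bootstrap_reps = config$bootstrap_reps %||% 1000L,
    n_permutations = config$n_permutations %||% 9999L,
    hwe_reps = config$hwe_reps %||% 10000L,
    pca_components = config$pca_components %||% 3L,
    weights = config$weights %||% "by_n",
    seed = config$seed %||% 1L,
    stages = config$stages %||% c("stats", "tree", "pca", "rmatrix", "mantel")
  )
  manifest <- list(package = "strpop",
                   version = as.character(utils::packageVersion("strpop")),
                   config = config, settings = cfg, stages = list(),
                   outputs = character(0))
  note <- function(stage, status, reason = NULL) {
    manifest$stages[[stage]] <<- list(status = status, reason = reason)
    message("[", stage, "] ", status, if (!is.null(reason)) paste0(": ", reason))
  }
  emit <- function(name, writer) {
    path <- file.path(out, name)
    writer(path)
    manifest$outputs <<- c(manifest$outputs, name)
    path
  }

  genotypes <- NULL
  panel <- NULL
  if (!is.null(config$genotypes)) {
    genotypes <- read_genotypes(config$genotypes)
    panel <- suppressMessages(allele_frequencies(genotypes))
  } else if (!is.null(config$frequencies)) {
    panel <- read_freq_table(config$frequencies)
  }
  meta <- if (identical(config$meta, "fixture")) nwc_population_meta()
          else if (!is.null(config$meta)) utils::read.csv(config$meta, stringsAsFactors = FALSE)
  da <- NULL
  if (!is.null(panel)) {
    da <- pairwise_da(panel)
  } else if (identical(config$da_matrix, "fixture")) {
    da <- nwc_da_matrix()
  } else if (!is.null(config$da_matrix)) {
    da <- read_dist_matrix(config$da_matrix)
  }
  if (is.null(panel) && is.null(da)) {
    stop_strpop("config must provide genotypes, frequencies, or a da_matrix")
  }
  if (!is.null(da)) emit("da_matrix.csv", function(p) write_dist_matrix(da, p))

  # stats ---------------------------------------------------------------
  if ("stats" %in% cfg$stages && !is.null(panel)) {
    src <- if (!is.null(genotypes)) genotypes else panel
    ls <- locus_stats(src, hwe = !is.null(genotypes),
                      hwe_reps = cfg$hwe_reps, seed = cfg$seed)
    emit("locus_stats.csv", function(p) utils::write.csv(ls, p, row.names = FALSE))
    emit("population_stats.csv",
         function(p) utils::write.csv(combine_panel(ls), p, row.names = FALSE))
    note("stats", "ok")
  } else if ("stats" %in% cfg$stages) {
    note("stats", "skipped", "no genotype or frequency input")
  }

  # tree ----------------------------------------------------------------
  if ("tree" %in% cfg$stages && !is.null(da)) {
    tree <- if (!is.null(panel) && length(panel$loci) >= 2L) {
      bootstrap_tree(panel, reps = cfg$bootstrap_reps, seed = cfg$seed)
    } else nj_tree(da)
    suppressWarnings(emit("tree.nwk", function(p) write_newick(tree, p)))
    note("tree", "ok",
         if (is.null(panel)) "no frequency data: tree without bootstrap supports")
  } else if ("tree" %in% cfg$stages) {
    note("tree", "skipped", "no distance matrix")
  }

  # pca -----------------------------------------------------------------
  if ("pca" %in% cfg$stages && !is.null(panel)) {
    pca <- covariance_pca(panel, n_components = min(cfg$pca_components,
                                                    length(panel$populations) - 1L))
    if (!pca$degenerate) {
      sc <- data.frame(population = rownames(pca$scores), pca$scores,
                       stringsAsFactors = FALSE)
      emit("pca_scores.csv", function(p) utils::write.csv(sc, p, row.names = FALSE))
      emit("pca_variance.csv", function(p) utils::write.csv(
        data.frame(component = seq_along(pca$variance_ratio),
                   variance_ratio = pca$variance_ratio), p, row.names = FALSE))
      note("pca", "ok")
    } else note("pca", "degenerate", "zero total variance")
  } else if ("pca" %in% cfg$stages) {
    note("pca", "skipped", "no frequency data")
  }

  # rmatrix -------------------------------------------------------------
  if ("rmatrix" %in% cfg$stages && !is.null(panel)) {
    rr <- rmatrix_regression(r_matrix(panel, weights = cfg$weights))
    emit("rmatrix_regression.csv",
         function(p) utils::write.csv(rr$table, p, row.names = FALSE))
    note("rmatrix", "ok")
  } else if ("rmatrix" %in% cfg$stages) {
    note("rmatrix", "skipped", "no frequency data")
  }

  # mantel --------------------------------------------------------------
  if ("mantel" %in% cfg$stages && !is.null(da) && !is.null(meta)) {
    meta_o <- meta[match(rownames(da), meta$name), , drop = FALSE]
    if (any(is.na(meta_o$name))) {
      note("mantel", "skipped", "metadata does not cover all populations in the distance matrix")
    } else {
      geo <- geographic_distances(meta_o)
      lan <- linguistic_distances(meta_o)
      emit("linguistic_coding.csv",
           function(p) utils::write.csv(attr(lan, "coding"), p, row.names = FALSE))
      res <- list(
        "Dgen and Dgeo" = mantel_test(da, geo, cfg$n_permutations, seed = cfg$seed),
        "Dgen and Dlan" = mantel_test(da, lan, cfg$n_permutations, seed = cfg$seed),
        "Dgen and Dgeo, Dlan constant" =
          partial_mantel_test(da, geo, lan, cfg$n_permutations, seed = cfg$seed,
                              controlled = "Dlan"),
        "Dgen and Dlan, Dgeo constant" =
          partial_mantel_test(da, lan, geo, cfg$n_permutations, seed = cfg$seed,
                              controlled = "Dgeo")
      )
      tab <- report_table4(res)
      emit("mantel.csv", function(p) utils::write.csv(tab, p, row.names = FALSE))
      note("mantel", "ok")
    }
  } else if ("mantel" %in% cfg$stages) {
    note("mantel", "skipped", "needs a distance matrix and population metadata")
  }

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}

#' Summarize Mantel results as a four-row comparison table
#'
#' @param results Named list of [mantel_test()] / [partial_mantel_test()]
#'   results; names become the `matrices_compared` labels.
#' @return data.frame with columns `matrices_compared`,
#'   `correlation_coefficient`, `p_value`, `variance_explained` (r^2; `NA`
#'   for partial rows, matching the usual presentation).
#' @export
report_table4 <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L, !is.null(names(results)))
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    stopifnot(inherits(x, "mantel_result"))
    data.frame(matrices_compared = nm,
               correlation_coefficient = x$r,
               p_value = x$p_value,
               variance_explained = if (x$kind == "partial") NA_real_
                                    else x$variance_explained,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
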