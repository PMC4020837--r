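#' Packaged Northwest-China study fixtures
#'
#' The package ships two small plain-text fixtures describing the 13
#' Northwest-China populations of the motivating study: population metadata
#' (chromosome counts, geographic coordinates in decimal degrees, a
#' phylum/family/language classification path, religion) and the published
#' 13 x 13 pairwise Nei's D_A distance matrix. Labels use the canonical
#' spellings (Uyghur, Uzbek, Kirghiz, Kazakh, Salar, Yugur, ...);
#' [canonical_population_names()] maps the variant spellings that also appear
#' in the literature onto these.
#'
#' @return `nwc_population_meta()`: a data.frame with one row per population
#'   and columns `name`, `chromosomes`, `longitude`, `latitude`, `phylum`,
#'   `family`, `language`, `religion`. `nwc_da_matrix()`: a [dist_matrix()].
#' @examples
#' d <- nwc_da_matrix()
#' d["Tu", "Dongxiang"]   # 0.0092, the closest pair
#' @export
nwc_population_meta <- function() {
  path <- system.file("extdata", "nwc_population_meta.csv", package = "strpop",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname nwc_population_meta
#' @export
nwc_da_matrix <- function() {
  path <- system.file("extdata", "nwc_da_distance.csv", package = "strpop",
                      mustWork = TRUE)
  read_dist_matrix(path)
}

#' @rdname nwc_population_meta
#' @param names Character vector of population names, possibly in variant
#'   spellings (`Uygur`, `Uzbik`, `Kirgiz`, `Kazak`, `Sala`, `Yugu`).
#' @return `canonical_population_names()`: `names` with variant spellings
#'   replaced by the canonical ones.
#' @export
canonical_population_names <- function(names) {
  map <- c(Uygur = "Uyghur", Uzbik = "Uzbek", Kirgiz = "Kirghiz",
           Kazak = "Kazakh", Sala = "Salar", Yugu = "Yugur")
  hit <- names %in% names(map)
  names[hit] <- map[names[hit]]
  names
}
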