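#' Great-circle distance
#'
#' Haversine formula on a sphere of radius 6371.0 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @param radius_km Earth radius in km.
#' @return Distance in km.
#' @export
haversine_distance <- function(lon1, lat1, lon2, lat2, radius_km = 6371.0) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix between populations
#'
#' @param meta data.frame with columns `name`, `longitude`, `latitude`
#'   (decimal degrees), as from [nwc_population_meta()].
#' @param radius_km Earth radius in km (default 6371.0).
#' @return A [dist_matrix()] in km.
#' @export
geographic_distances <- function(meta, radius_km = 6371.0) {
  need <- c("name", "longitude", "latitude")
  if (!all(need %in% names(meta))) {
    stop_strpop("meta must have columns: ", paste(need, collapse = ", "))
  }
  if (any(meta$longitude < -180 | meta$longitude > 180) ||
      any(meta$latitude < -90 | meta$latitude > 90)) {
    stop_strpop("coordinates out of range: longitude in [-180, 180], latitude in [-90, 90]")
  }
  n <- nrow(meta)
  d <- matrix(0, n, n, dimnames = list(meta$name, meta$name))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- haversine_distance(
      meta$longitude[i], meta$latitude[i],
      meta$longitude[j], meta$latitude[j], radius_km
    )
  }
  dist_matrix(d)
}

#' Ordinal linguistic distance matrix
#'
#' Pairs of populations are scored on a 0-4 dissimilarity scale from their
#' linguistic classification paths: a difference at the phylum level scores
#' 4; at the branch level 3; at the family level 2; different languages
#' within the same family 1; the same language (or the same population) 0.
#' The path levels used are the intersection of
#' `c("phylum", "branch", "family", "language")` with the columns of `meta`,
#' compared in that order — the packaged metadata carries
#' phylum/family/language, so its default coding never emits 3.
#' Explicit per-pair `overrides` take precedence and are recorded in the
#' result's `"coding"` attribute, the full reviewable pair table.
#'
#' @param meta data.frame with a `name` column and classification-path
#'   columns (see above).
#' @param overrides Optional data.frame with columns `pop1`, `pop2`, `value`
#'   overriding specific pairs (order-insensitive).
#' @return A [dist_matrix()] with values in `{0, 1, 2, 3, 4}` and attribute
#'   `"coding"`: a data.frame of every unordered pair with its value and
#'   source (`"path"` or `"override"`).
#' @export
linguistic_distances <- function(meta, overrides = NULL) {
  if (!"name" %in% names(meta)) stop_strpop("meta must have a 'name' column")
  levels_all <- c(phylum = 4, branch = 3, family = 2, language = 1)
  path_cols <- intersect(names(levels_all), names(meta))
  if (length(path_cols) == 0L) {
    stop_strpop("meta must have classification columns among: ",
                paste(names(levels_all), collapse = ", "))
  }
  ov <- new.env(parent = emptyenv())
  if (!is.null(overrides)) {
    stopifnot(all(c("pop1", "pop2", "value") %in% names(overrides)))
    for (k in seq_len(nrow(overrides))) {
      kk <- paste(sort(c(overrides$pop1[k], overrides$pop2[k])), collapse = "|")
      assign(kk, overrides$value[k], envir = ov)
    }
  }
  n <- nrow(meta)
  d <- matrix(0, n, n, dimnames = list(meta$name, meta$name))
  coding <- list()
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    key <- paste(sort(c(meta$name[i], meta$name[j])), collapse = "|")
    if (exists(key, envir = ov, inherits = FALSE)) {
      val <- get(key, envir = ov)
      src <- "override"
    } else {
      val <- 0
      src <- "path"
      for (cl in path_cols) {
        a <- meta[[cl]][i]; b <- meta[[cl]][j]
        if (is.na(a) || is.na(b) || a == "" || b == "") {
          stop_strpop("malformed classification path for pair ",
                      meta$name[i], " / ", meta$name[j],
                      " (missing '", cl, "'); provide an override")
        }
        if (a != b) { val <- levels_all[[cl]]; break }
      }
    }
    d[i, j] <- d[j, i] <- val
    coding[[length(coding) + 1L]] <- data.frame(
      pop1 = meta$name[i], pop2 = meta$name[j], value = val, source = src,
      stringsAsFactors = FALSE
    )
  }
  out <- dist_matrix(d)
  attr(out, "coding") <- do.call(rbind, coding)
  out
}
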