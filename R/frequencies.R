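#' Allele frequency panels
#'
#' An `freq_panel` is the hub all statistics consume: for every population and
#' locus a named allele-frequency vector (gene-counting estimates) plus the
#' count of non-missing gene copies ("chromosomes"). Frequencies in each cell
#' sum to one; alleles are ordered numerically-then-lexicographically.
#'
#' @param populations Ordered character vector of population names.
#' @param loci Ordered character vector of locus names.
#' @param freq Nested list `freq[[population]][[locus]]` of named numeric
#'   vectors (allele -> frequency). A cell with no data is `NULL`.
#' @param n_copies Integer matrix populations x loci of gene-copy counts
#'   (0 where the cell is absent).
#' @return A validated object of class `freq_panel`.
#' @export
freq_panel <- function(populations, loci, freq, n_copies) {
  stopifnot(is.character(populations), is.character(loci))
  if (anyDuplicated(populations)) stop_strpop("duplicate population names")
  if (anyDuplicated(loci)) stop_strpop("duplicate locus names")
  stopifnot(is.matrix(n_copies),
            nrow(n_copies) == length(populations),
            ncol(n_copies) == length(loci))
  dimnames(n_copies) <- list(populations, loci)
  for (p in populations) for (l in loci) {
    f <- freq[[p]][[l]]
    n <- n_copies[p, l]
    if (is.null(f)) {
      if (n != 0) stop_strpop("cell (", p, ", ", l, "): n_copies > 0 but no frequencies")
      next
    }
    if (n < 1) stop_strpop("cell (", p, ", ", l, "): frequencies present but n_copies = 0")
    if (is.null(names(f)) || any(names(f) == "")) {
      stop_strpop("cell (", p, ", ", l, "): unnamed allele frequencies")
    }
    if (any(f <= 0) || any(f > 1)) {
      stop_strpop("cell (", p, ", ", l, "): frequencies must lie in (0, 1]")
    }
    if (abs(sum(f) - 1) > 1e-9) {
      stop_strpop("cell (", p, ", ", l, "): frequencies sum to ", format(sum(f)),
                  ", not 1")
    }
  }
  structure(list(populations = populations, loci = loci,
                 freq = freq, n_copies = n_copies),
            class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  cat(sprintf("<freq_panel> %d populations x %d loci\n",
              length(x$populations), length(x$loci)))
  invisible(x)
}

#' Estimate allele frequencies by gene counting
#'
#' Per population and locus, the frequency of each allele is its count among
#' non-missing gene copies divided by the number of such copies. Missing
#' genotypes are excluded per cell; a (population, locus) cell with zero
#' non-missing copies is excluded from the panel (with a message), never
#' fabricated.
#'
#' @param g A [genotype_table()].
#' @return A [freq_panel()] with populations in first-encountered order.
#' @examples
#' gt <- genotype_table(data.frame(
#'   individual_id = c("i1", "i2"), population = "P1",
#'   TH01_1 = c("A", "A"), TH01_2 = c("A", "B"), stringsAsFactors = FALSE
#' ))
#' allele_frequencies(gt)$freq$P1$TH01   # A: 0.75, B: 0.25
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  pops <- gt_populations(g)
  loci <- gt_loci(g)
  freq <- stats::setNames(vector("list", length(pops)), pops)
  n_copies <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  for (p in pops) {
    rows <- g$population == p
    cell <- list()
    for (l in loci) {
      a <- c(g[[paste0(l, "_1")]][rows], g[[paste0(l, "_2")]][rows])
      a <- a[!is.na(a)]
      if (length(a) == 0L) {
        message("allele_frequencies: no non-missing copies for (", p, ", ", l,
                "); cell excluded")
        next
      }
      tab <- table(a)
      f <- as.numeric(tab) / length(a)
      names(f) <- names(tab)
      f <- f[order_alleles(names(f))]
      cell[[l]] <- f
      n_copies[p, l] <- length(a)
    }
    freq[[p]] <- cell
  }
  freq_panel(pops, loci, freq, n_copies)
}

# Frequencies of one locus across all populations that carry it, as a
# populations x alleles matrix over the union allele set (absent allele -> 0).
#' @noRd
locus_freq_matrix <- function(panel, locus, populations = panel$populations) {
  cells <- lapply(populations, function(p) panel$freq[[p]][[locus]])
  keep <- !vapply(cells, is.null, logical(1))
  populations <- populations[keep]
  cells <- cells[keep]
  alleles <- sort_alleles(unique(unlist(lapply(cells, names))))
  m <- matrix(0, length(populations), length(alleles),
              dimnames = list(populations, alleles))
  for (i in seq_along(cells)) m[i, names(cells[[i]])] <- cells[[i]]
  m
}

#' Read and write allele-frequency tables
#'
#' Long CSV layout: columns `population`, `locus`, `allele`, `frequency`,
#' `n_copies`. This is the frequencies-only input mode for data published as
#' frequency tables rather than raw genotypes.
#'
#' @param path File path.
#' @return `read_freq_table()` returns a [freq_panel()]; `write_freq_table()`
#'   returns `path` invisibly.
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop_strpop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c(
    population = "character", locus = "character", allele = "character"
  ), stringsAsFactors = FALSE)
  need <- c("population", "locus", "allele", "frequency", "n_copies")
  if (!all(need %in% names(df))) {
    stop_strpop("frequency table must have columns: ", paste(need, collapse = ", "))
  }
  pops <- unique(df$population)
  loci <- unique(df$locus)
  freq <- stats::setNames(vector("list", length(pops)), pops)
  n_copies <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  for (p in pops) {
    cell <- list()
    for (l in loci) {
      sub <- df[df$population == p & df$locus == l, , drop = FALSE]
      if (nrow(sub) == 0L) next
      f <- stats::setNames(sub$frequency, sub$allele)
      f <- f[order_alleles(names(f))]
      cell[[l]] <- f / sum(f)  # renormalize rounded published frequencies
      n_copies[p, l] <- as.integer(sub$n_copies[1L])
    }
    freq[[p]] <- cell
  }
  freq_panel(pops, loci, freq, n_copies)
}

#' @rdname read_freq_table
#' @param panel A `freq_panel`.
#' @export
write_freq_table <- function(panel, path) {
  stopifnot(inherits(panel, "freq_panel"))
  rows <- list()
  for (p in panel$populations) for (l in panel$loci) {
    f <- panel$freq[[p]][[l]]
    if (is.null(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, allele = names(f), frequency = as.numeric(f),
      n_copies = panel$n_copies[p, l], stringsAsFactors = FALSE
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
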