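#' Nei's D_A genetic distance
#'
#' `D_A = 1 - (1/L) * sum_loci sum_alleles sqrt(x_a * y_a)`: one minus the
#' locus-averaged Bhattacharyya affinity of the two allele-frequency
#' distributions. It is symmetric, zero iff the frequency vectors agree at
#' every locus, and 1 when the populations share no allele anywhere; it is
#' not a metric (no triangle inequality), but resolves closely related
#' populations well, which is why it is the distance of choice for
#' within-region STR panels.
#'
#' @param p,q Per-locus allele frequencies: named lists `locus -> named
#'   frequency vector`. Allele sets are unioned per locus (absent allele =
#'   frequency 0).
#' @param loci Loci to average over (default: loci present in both).
#' @return D_A in `[0, 1]`.
#' @export
da_distance <- function(p, q, loci = intersect(names(p), names(q))) {
  if (length(loci) == 0L) stop_strpop("empty locus list")
  if (!all(loci %in% names(p)) || !all(loci %in% names(q))) {
    stop_strpop("both populations must be typed at every locus in 'loci'")
  }
  aff <- vapply(loci, function(l) {
    fp <- p[[l]]; fq <- q[[l]]
    if (is.null(fp) || is.null(fq)) stop_strpop("missing frequencies at locus ", l)
    alleles <- union(names(fp), names(fq))
    xp <- stats::setNames(numeric(length(alleles)), alleles)
    xq <- xp
    xp[names(fp)] <- fp
    xq[names(fq)] <- fq
    sum(sqrt(xp * xq))
  }, numeric(1))
  min(max(1 - mean(aff), 0), 1)
}

#' Pairwise D_A distance matrix
#'
#' @param panel A [freq_panel()]; every population must be typed at every
#'   locus used (loci with full coverage across populations).
#' @return A [dist_matrix()] over the panel's populations.
#' @export
pairwise_da <- function(panel) {
  stopifnot(inherits(panel, "freq_panel"))
  pops <- panel$populations
  if (length(pops) < 2L) stop_strpop("need >= 2 populations")
  covered <- panel$loci[apply(panel$n_copies > 0, 2, all)]
  if (length(covered) == 0L) stop_strpop("no locus typed in all populations")
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- da_distance(panel$freq[[pops[i]]], panel$freq[[pops[j]]],
                                      loci = covered)
  }
  dist_matrix(d)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: repeatedly join the pair (i, j) minimizing
#' `Q(i, j) = (N - 2) d(i, j) - r_i - r_j`, with standard branch-length and
#' distance-update formulas. Ties in Q (within 1e-12) are broken by joining
#' the lexicographically smallest label pair, where a cluster is labeled by
#' its smallest leaf label, so the result is deterministic. Negative branch
#' lengths are retained (see [write_newick()] for export-time clamping).
#'
#' @param d A [dist_matrix()] with `n >= 3` labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- dist_matrix(unclass(d))  # re-validate
  n <- nrow(d)
  if (n < 3L) stop_strpop("neighbor joining needs >= 3 taxa")
  labs <- rownames(d)
  frag <- labs                     # newick fragment per active node
  key <- labs                      # tie-break label = smallest leaf in cluster
  m <- unclass(d)
  while (length(key) > 3L) {
    N <- length(key)
    r <- rowSums(m)
    q <- (N - 2) * m - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      kk <- sort(c(key[ij[1]], key[ij[2]]))
      paste(kk, collapse = "\r")
    })
    pick <- cand[order(pk)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- m[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- m[i, j] - li
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    newkey <- min(key[i], key[j])
    dk <- (m[i, ] + m[j, ] - m[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    m2 <- rbind(cbind(m[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    m <- m2
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  # final three-point resolution
  l1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  l2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  l3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  ape::read.tree(text = nwk)
}

# Canonical bipartition keys of a phylo tree's internal edges. Each split is
# represented by the side not containing `ref` (the alphabetically first
# label), sorted and joined; trivial splits (single leaf / all leaves) are
# dropped.
#' @noRd
tree_splits <- function(tree) {
  labs <- tree$tip.label
  ref <- sort(labs)[1L]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Resamples loci with replacement, recomputes the pairwise D_A matrix and NJ
#' tree for each replicate, and annotates each internal edge of the full-data
#' tree with the percentage of replicates containing the same bipartition
#' (supports are mapped onto the point-estimate tree, not a consensus tree).
#' The resampling unit is the locus, the convention for allele-frequency
#' data.
#'
#' @param panel A [freq_panel()] with >= 3 populations and >= 2 loci.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; a fixed seed gives bit-identical supports.
#' @return The point-estimate `phylo` tree with `node.label` holding support
#'   percentages in `[0, 100]` (`NA` on the root trifurcation).
#' @export
bootstrap_tree <- function(panel, reps = 1000L, seed = NULL) {
  stopifnot(inherits(panel, "freq_panel"))
  if (!is_count(reps, 1L)) stop_strpop("reps must be a positive integer")
  if (length(panel$populations) < 3L) stop_strpop("need >= 3 populations")
  covered <- panel$loci[apply(panel$n_copies > 0, 2, all)]
  if (length(covered) < 2L) stop_strpop("need >= 2 fully typed loci")
  point <- nj_tree(pairwise_da(panel))
  point_splits <- tree_splits(point)
  counts <- stats::setNames(numeric(length(point_splits)), point_splits)
  with_seed(seed, {
    for (b in seq_len(reps)) {
      loci_b <- sample(covered, length(covered), replace = TRUE)
      pops <- panel$populations
      db <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
      for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
        db[i, j] <- db[j, i] <- da_distance(panel$freq[[pops[i]]],
                                            panel$freq[[pops[j]]], loci = loci_b)
      }
      sb <- tree_splits(nj_tree(dist_matrix(db)))
      hit <- point_splits %in% sb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / reps
  # map supports onto internal nodes: node i's split key, or NA for the root
  labs <- point$tip.label
  ref <- sort(labs)[1L]
  parts <- ape::prop.part(point)
  node_label <- rep(NA_character_, point$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    key <- paste(sort(side), collapse = "|")
    node_label[k] <- format(support[[key]])
  }
  point$node.label <- node_label
  attr(point, "bootstrap") <- list(reps = as.integer(reps), seed = seed,
                                   support = support)
  point
}

#' Write a tree as Newick
#'
#' Branch lengths are written in full precision; internal-node support labels
#' (if present) are rounded to integers. Negative branch lengths, a known
#' artifact of neighbor joining, are clamped to zero on export with a
#' warning; the in-memory tree keeps them.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output file path.
#' @param clamp_negative Clamp negative branch lengths to 0 (default TRUE).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, clamp_negative = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (clamp_negative && any(tree$edge.length < 0)) {
    warning("clamping ", sum(tree$edge.length < 0),
            " negative branch length(s) to zero on Newick export")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  if (!is.null(tree$node.label)) {
    num <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(is.na(num), "", as.character(round(num)))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
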