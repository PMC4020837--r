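# Shared fixture builders and independent oracles. Oracles are coded from the
# definitions directly, independently of the package implementation paths.

# Minimal genotype data.frame builder: calls is a list pop -> list of
# "a/b" strings per locus; loci named by the outer structure.
make_gt <- function(calls, loci) {
  rows <- list()
  for (pop in names(calls)) {
    inds <- calls[[pop]]
    for (i in seq_along(inds)) {
      row <- list(individual_id = sprintf("%s_%d", pop, i), population = pop)
      g <- inds[[i]]
      for (k in seq_along(loci)) {
        ab <- strsplit(g[k], "/", fixed = TRUE)[[1]]
        if (identical(g[k], NA_character_) || is.na(g[k])) ab <- c(NA, NA)
        row[[paste0(loci[k], "_1")]] <- ab[1]
        row[[paste0(loci[k], "_2")]] <- ab[2]
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  genotype_table(do.call(rbind, rows))
}

# Random frequency panel built directly (not via the simulator): pops x loci,
# each cell a Dirichlet-ish frequency vector from normalized gamma draws.
random_panel <- function(n_pops = 4, n_loci = 3, k = 4, n_copies = 100,
                         seed = 1) {
  set.seed(seed)
  pops <- sprintf("P%02d", seq_len(n_pops))
  loci <- sprintf("L%02d", seq_len(n_loci))
  freq <- setNames(lapply(pops, function(p) {
    setNames(lapply(loci, function(l) {
      x <- rgamma(k, 1) + 1e-6
      setNames(x / sum(x), as.character(seq_len(k) + 7))
    }), loci)
  }), pops)
  nc <- matrix(as.integer(n_copies), n_pops, n_loci,
               dimnames = list(pops, loci))
  freq_panel(pops, loci, freq, nc)
}

# Independent D_A oracle: plain double loop over loci and union alleles.
oracle_da <- function(p, q, loci) {
  tot <- 0
  for (l in loci) {
    alleles <- union(names(p[[l]]), names(q[[l]]))
    s <- 0
    for (a in alleles) {
      xa <- if (a %in% names(p[[l]])) p[[l]][[a]] else 0
      ya <- if (a %in% names(q[[l]])) q[[l]][[a]] else 0
      s <- s + sqrt(xa * ya)
    }
    tot <- tot + s
  }
  1 - tot / length(loci)
}

# Independent exact HWE oracle for 2 alleles: enumerate all tables with the
# observed allele-count margins via the heterozygote count, weight by the
# Levene probability, sum tables no more probable than the observed one.
oracle_hwe2 <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  cA <- 2 * nAA + nAB
  cB <- 2 * nBB + nAB
  levene <- function(ab) {
    aa <- (cA - ab) / 2
    bb <- (cB - ab) / 2
    if (aa < 0 || bb < 0 || aa != floor(aa)) return(NA_real_)
    exp(lfactorial(n) + lfactorial(cA) + lfactorial(cB) - lfactorial(2 * n) +
          ab * log(2) - lfactorial(aa) - lfactorial(ab) - lfactorial(bb))
  }
  abs <- seq(cA %% 2, min(cA, cB), by = 2)
  probs <- vapply(abs, levene, 1)
  stopifnot(!anyNA(probs), abs(sum(probs) - 1) < 1e-9)
  p_obs <- probs[abs == nAB]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Exhaustive Mantel oracle for small n: exact tail fraction over all n!
# relabelings of b.
oracle_mantel_exhaustive <- function(a, b) {
  n <- nrow(a)
  lt <- lower.tri(a)
  va <- a[lt]
  r_obs <- cor(va, b[lt])
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(x) !anyDuplicated(x)), , drop = FALSE]
  rs <- apply(perms, 1, function(idx) cor(va, b[idx, idx][lt]))
  list(r = r_obs, tail = mean(rs >= r_obs - 1e-12))
}

# Path-length matrix of an ape tree (independent of package code).
tree_dists <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[order(rownames(m)), order(colnames(m))]
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n, seed, labels = sprintf("T%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  dist_matrix(m, labels)
}
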