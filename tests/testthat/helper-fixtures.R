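# Small shared fixtures, all generated in code.

# tiny default-divergence library: 2 families x 2 genera x 2 species x 3
# specimens (24 references + outgroup)
tiny_library <- function(seed = 7) {
  simulate_library(taxonomy_spec(2, 2, 2, 3), divergence_spec(), seed = seed)
}

# two well-separated clades: 2 families x 1 x 1 x 4, identical within,
# p ~ 0.1 between
two_clade_library <- function(seed = 3) {
  simulate_library(taxonomy_spec(2, 1, 1, 4),
                   divergence_spec(0, 0.001, 0.002, 0.1),
                   seed = seed, outgroup = FALSE)
}

# a random unrooted tree with positive branch lengths and its additive
# (cophenetic) distance matrix, labels sorted
random_additive <- function(k) {
  t0 <- ape::rtree(k, rooted = FALSE)
  t0$edge.length <- stats::runif(length(t0$edge.length), 0.05, 0.3)
  D <- stats::cophenetic(t0)
  list(tree = t0, D = D[sort(rownames(D)), sort(rownames(D))])
}

# Exhaustive least-squares topology oracle: enumerate all unrooted
# topologies on the taxa, fit branch lengths by unconstrained least squares
# to the distance matrix, return the minimum-SS topology. Independent of the
# NJ implementation.
ls_best_topology <- function(D) {
  labs <- rownames(D)
  n <- length(labs)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- utils::combn(n, 2)
  d <- D[t(pairs)]
  best <- NULL
  best_ss <- Inf
  for (ti in seq_along(tops)) {
    tp <- tops[[ti]]  # [[ restores compressed multiPhylo tip labels
    ne <- nrow(tp$edge)
    # a tip pair's path crosses an edge iff exactly one of the two tips
    # lies in the subtree below that edge
    below <- phangorn::Descendants(tp, tp$edge[, 2], "tips")
    A <- matrix(0, ncol(pairs), ne)
    for (e in seq_len(ne)) {
      inb <- logical(n)
      inb[below[[e]]] <- TRUE
      A[, e] <- as.numeric(xor(inb[pairs[1, ]], inb[pairs[2, ]]))
    }
    fit <- stats::lm.fit(A, d)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- tp
    }
  }
  best
}
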