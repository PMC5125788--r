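## Neighbour joining (Saitou & Nei) from a p-distance matrix, with
## deterministic tie-breaking and Kuhner-Felsenstein handling of negative
## branch-length estimates (clamped to zero, deficit moved to the sister
## branch so path lengths are preserved). Trees are `ape::phylo` objects;
## Newick I/O, rooting and bipartition counting go through ape.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration. Ties in Q are broken by the
#' lexicographically smallest pair of cluster representative labels, so the
#' same matrix always yields the same tree. The result is unrooted (basal
#' trifurcation).
#'
#' @param D labelled symmetric distance matrix, n >= 3, no `NA` entries.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels) || n < 3) {
    stop("need a labelled distance matrix with at least 3 taxa",
         call. = FALSE)
  }
  if (anyNA(D)) stop("distance matrix contains undefined entries",
                     call. = FALSE)
  if (any(grepl("[();,:\\[\\]]", labels))) {
    stop("labels may not contain Newick metacharacters", call. = FALSE)
  }
  Dm <- D
  reps <- labels          # representative (smallest) tip label per cluster
  nwk <- labels           # Newick substring per cluster
  while (nrow(Dm) > 3) {
    r <- nrow(Dm)
    rs <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(reps[cand[, 1]], reps[cand[, 2]])
    key2 <- pmax(reps[cand[, 1]], reps[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    li <- Dm[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    first <- reps[i] <= reps[j]
    merged <- if (first) {
      sprintf("(%s:%s,%s:%s)", nwk[i], fmt_len(li), nwk[j], fmt_len(lj))
    } else {
      sprintf("(%s:%s,%s:%s)", nwk[j], fmt_len(lj), nwk[i], fmt_len(li))
    }
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    Dm <- Dm2
    reps <- c(reps[keep], min(reps[c(i, j)]))
    nwk <- c(nwk[keep], merged)
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l <- pmax(0, c((d12 + d13 - d23) / 2,
                 (d12 + d23 - d13) / 2,
                 (d13 + d23 - d12) / 2))
  ord <- order(reps)
  txt <- paste0("(", paste(sprintf("%s:%s", nwk[ord], fmt_len(l[ord])),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

# integer-coded alignment from equal-length ungapped records
alignment_codes <- function(records) {
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    stop("records must be equal-length (aligned) for column resampling",
         call. = FALSE)
  }
  seqs <- records$sequence
  names(seqs) <- records$id
  code_alignment(seqs)
}

#' NJ tree with column-resampling bootstrap supports
#'
#' Builds the NJ tree from the full alignment's p-distance matrix, then
#' resamples alignment columns with replacement `n_reps` times, recomputing
#' distances (same pairwise-deletion rule) and the NJ tree per replicate.
#' The support of an internal edge is the percentage of replicates whose
#' tree contains the same bipartition; supports are stored as node labels
#' (`NA` on the basal trifurcation, whose bipartition is trivial).
#'
#' @param records equal-length barcode records (an alignment).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; same seed, same supports.
#' @return an `ape::phylo` tree with `node.label` bootstrap percentages.
#' @export
bootstrap_support <- function(records, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  codes <- alignment_codes(records)
  tree <- nj_tree(pdist_from_codes(codes))
  L <- ncol(codes)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(k) {
      idx <- sample.int(L, L, replace = TRUE)
      nj_tree(pdist_from_codes(codes[, idx, drop = FALSE]))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  supp <- round(100 * counts / n_reps)
  supp[1] <- NA  # basal node: trivial bipartition
  tree$node.label <- ifelse(is.na(supp), "", as.character(supp))
  tree
}

#' Root a tree on its outgroup
#'
#' The root is placed at the midpoint of the outgroup's pendant edge, so the
#' outgroup becomes one child of the root; bootstrap node labels are carried
#' over edge-wise (ape's `edgelabel` convention).
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_tip tip label to root on.
#' @return a rooted `ape::phylo` tree with the same tip set.
#' @export
root_on_outgroup <- function(tree, outgroup_tip) {
  if (!outgroup_tip %in% tree$tip.label) {
    stop("outgroup tip not in tree: ", outgroup_tip, call. = FALSE)
  }
  rt <- ape::root(tree, outgroup = outgroup_tip, resolve.root = TRUE,
                  edgelabel = TRUE)
  root_node <- length(rt$tip.label) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  if (length(kids) == 2L) {
    tot <- sum(rt$edge.length[kids])
    rt$edge.length[kids] <- tot / 2
  }
  rt
}

#' Is a set of tips monophyletic on a tree?
#'
#' Unrooted trees: true iff some edge bipartition separates exactly `tips`
#' from the rest. Rooted trees: true iff some clade equals `tips`.
#' Singletons and the full tip set are trivially monophyletic.
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels (subset of the tree's tips).
#' @return logical flag.
#' @export
is_monophyletic <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip(s): ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  n <- length(tree$tip.label)
  target <- sort(unique(idx))
  if (length(target) %in% c(1L, n)) return(TRUE)
  comp <- setdiff(seq_len(n), target)
  rooted <- ape::is.rooted(tree)
  for (clade in ape::prop.part(tree)) {
    cl <- sort(clade)
    if (identical(cl, target)) return(TRUE)
    if (!rooted && identical(cl, comp)) return(TRUE)
  }
  FALSE
}

#' Bootstrap support of the edge separating a set of tips
#'
#' Looks up the internal edge whose bipartition is exactly `tips` vs the
#' rest and returns its stored support (node label), or `NA` when no such
#' edge exists (the set is not monophyletic) or the edge carries no label.
#'
#' @param tree a tree with `node.label` supports (see
#'   [bootstrap_support()]).
#' @param tips character vector of tip labels.
#' @return numeric support in `[0,100]`, or `NA`.
#' @export
clade_support <- function(tree, tips) {
  idx <- sort(match(tips, tree$tip.label))
  if (anyNA(idx)) stop("unknown tip(s)", call. = FALSE)
  n <- length(tree$tip.label)
  comp <- setdiff(seq_len(n), idx)
  pp <- ape::prop.part(tree)
  rooted <- ape::is.rooted(tree)
  for (k in seq_along(pp)) {
    cl <- sort(pp[[k]])
    if (identical(cl, idx) || (!rooted && identical(cl, comp))) {
      lab <- tree$node.label[k]
      return(if (is.null(lab) || !nzchar(lab)) NA_real_
             else as.numeric(lab))
    }
  }
  NA_real_
}

#' Newick I/O
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; branch lengths
#' and node-label supports round-trip unchanged.
#'
#' @param tree an `ape::phylo` tree.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
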