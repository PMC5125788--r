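## Uncorrected p-distances with pairwise deletion: per sequence pair, only
## columns where both sequences carry an unambiguous base (A/C/G/T) are
## compared; gap and ambiguity columns are dropped for that pair only.
## Similarity value SV = 100 * (1 - p) over the same compared-site support.

seq_of <- function(x) {
  if (is.data.frame(x)) toupper(x$sequence[[1]])
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a one-row record or a single sequence string",
            call. = FALSE)
}

# fixed alignment scoring: match +1, mismatch -1, gap of length L costs
# 5 + 2L (open 5, extend 2)
.ALN_GAP_OPEN <- 5
.ALN_GAP_EXT <- 2

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment via Biostrings with fixed scores
#' (match +1, mismatch -1, gap open 5, gap extend 2) and deterministic
#' traceback, so the same inputs always give the same alignment.
#'
#' @param a,b one-row barcode records or sequence strings (ungapped,
#'   non-empty).
#' @return list of class `aligned_pair`: gapped strings `a`, `b` (equal
#'   length, no gap-gap column) and `score`.
#' @export
align_pair <- function(a, b) {
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  if (grepl("-", sa, fixed = TRUE) || grepl("-", sb, fixed = TRUE)) {
    stop("inputs to align_pair must be ungapped", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    substitutionMatrix = mat, gapOpening = .ALN_GAP_OPEN,
    gapExtension = .ALN_GAP_EXT, type = "global")
  structure(list(a = as.character(Biostrings::alignedPattern(aln)),
                 b = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "aligned_pair")
}

#' Uncorrected p-distance of an aligned pair
#'
#' `p = mismatches / compared sites` under pairwise deletion: a column is
#' compared only if both sequences have an unambiguous base there (gap or
#' IUPAC ambiguity in either sequence drops the column for this pair).
#' Returns `NA` (with a warning) when no sites are comparable — an undefined
#' distance, never 0.
#'
#' @param pair an `aligned_pair`, or a length-2 character vector of equal
#'   gapped sequences.
#' @return p-distance in `[0,1]`, or `NA_real_` if undefined.
#' @export
p_distance <- function(pair) {
  if (inherits(pair, "aligned_pair")) pair <- c(pair$a, pair$b)
  stopifnot(length(pair) == 2L, nchar(pair[1]) == nchar(pair[2]))
  a <- strsplit(toupper(pair[1]), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(pair[2]), "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    warning("no comparable sites; p-distance undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Similarity value (SV) between two barcodes, in percent
#'
#' `SV = 100 * (1 - p)` where `p` is the uncorrected p-distance over the
#' aligned overlap. Under pairwise deletion every gap column — terminal
#' overhang included — is excluded, so a short query scored against a
#' full-length reference is penalized only where the two actually disagree.
#'
#' @param a,b records or sequence strings.
#' @param aligned `"auto"` (treat as aligned when ungapped and equal length),
#'   `TRUE` (positions are homologous as given) or `FALSE` (align first).
#' @return SV in `[0,100]`, `NA` if undefined.
#' @export
similarity_value <- function(a, b, aligned = "auto") {
  sa <- seq_of(a); sb <- seq_of(b)
  as_is <- isTRUE(aligned) ||
    (identical(aligned, "auto") && nchar(sa) == nchar(sb))
  p <- if (as_is) p_distance(c(sa, sb)) else p_distance(align_pair(sa, sb))
  100 * (1 - p)
}

# integer-coded alignment matrix (rows = sequences); non-ACGT -> NA
code_alignment <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  codes <- match(m, c("A", "C", "G", "T"))
  matrix(codes, nrow = nrow(m), dimnames = list(names(seqs), NULL))
}

# all-pairs p-distance on an integer-coded alignment, pairwise deletion,
# via one-hot cross-products (fast enough for hundreds of sequences)
pdist_from_codes <- function(codes) {
  valid <- !is.na(codes)
  V <- matrix(as.numeric(valid), nrow = nrow(codes))
  shared <- tcrossprod(V)
  matches <- matrix(0, nrow(codes), nrow(codes))
  for (b in 1:4) {
    Xb <- matrix(as.numeric(valid & codes == b), nrow = nrow(codes))
    matches <- matches + tcrossprod(Xb)
  }
  p <- (shared - matches) / shared
  p[shared == 0] <- NA_real_
  diag(p) <- 0
  dimnames(p) <- list(rownames(codes), rownames(codes))
  p
}

#' Pairwise p-distance matrix for a set of barcodes
#'
#' Equal-length ungapped sequences (the output of the simulator, or any
#' pre-aligned set) are treated as positionally homologous and compared
#' column-wise; otherwise every pair is globally aligned first with
#' [align_pair()].
#'
#' @param records barcode record data.frame.
#' @param aligned `"auto"`, `TRUE` or `FALSE` as in [similarity_value()].
#' @return labelled symmetric matrix, zero diagonal, entries in `[0,1]`
#'   (`NA` where a pair shares no comparable sites).
#' @export
distance_matrix <- function(records, aligned = "auto") {
  validate_records(records)
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records", call. = FALSE)
  lens <- nchar(records$sequence)
  as_is <- isTRUE(aligned) ||
    (identical(aligned, "auto") && length(unique(lens)) == 1L &&
       !any(grepl("-", records$sequence, fixed = TRUE)))
  if (as_is) {
    seqs <- records$sequence
    names(seqs) <- records$id
    return(pdist_from_codes(code_alignment(seqs)))
  }
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <-
        p_distance(align_pair(records$sequence[i], records$sequence[j]))
    }
  }
  D
}

#' Within- and between-group mean p-distances
#'
#' MEGA-style group means: the within mean averages all unordered in-group
#' pairs (undefined, reported `NA`, for singleton groups — never 0); the
#' between mean averages all cross-group pairs.
#'
#' @param matrix labelled p-distance matrix from [distance_matrix()].
#' @param grouping named character vector (or factor) mapping every matrix
#'   label to a group (any lineage rank or morphotype).
#' @return list with data.frames `within` (`group n mean_within max_within`)
#'   and `between` (`group1 group2 mean_between min_between`).
#' @export
group_distances <- function(matrix, grouping) {
  labs <- rownames(matrix)
  if (!all(labs %in% names(grouping))) {
    stop("grouping must assign every matrix label", call. = FALSE)
  }
  g <- as.character(grouping[labs])
  groups <- sort(unique(g))
  win <- data.frame(group = groups, n = NA_integer_,
                    mean_within = NA_real_, max_within = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(groups)) {
    idx <- which(g == groups[k])
    win$n[k] <- length(idx)
    if (length(idx) >= 2) {
      sub <- matrix[idx, idx, drop = FALSE]
      d <- sub[upper.tri(sub)]
      win$mean_within[k] <- mean(d, na.rm = TRUE)
      win$max_within[k] <- max(d, na.rm = TRUE)
    }
  }
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    btw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      mean_between = NA_real_, min_between = NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_len(ncol(pairs))) {
      d <- matrix[g == pairs[1, k], g == pairs[2, k], drop = FALSE]
      btw$mean_between[k] <- mean(d, na.rm = TRUE)
      btw$min_between[k] <- min(d, na.rm = TRUE)
    }
  } else {
    btw <- data.frame(group1 = character(0), group2 = character(0),
                      mean_between = numeric(0), min_between = numeric(0),
                      stringsAsFactors = FALSE)
  }
  list(within = win, between = btw)
}

#' Kimura 2-parameter distance (comparison only; p-distance is the default)
#'
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4` with `P`, `Q` the transition and
#' transversion proportions over compared sites. Saturated pairs for which a
#' logarithm is undefined return `NA` with a warning.
#'
#' @param pair an `aligned_pair` or length-2 gapped character vector.
#' @return K2P distance (>= the p-distance of the pair), or `NA`.
#' @export
k2p_distance <- function(pair) {
  if (inherits(pair, "aligned_pair")) pair <- c(pair$a, pair$b)
  a <- strsplit(toupper(pair[1]), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(pair[2]), "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) {
    warning("no comparable sites; K2P undefined", call. = FALSE)
    return(NA_real_)
  }
  a <- a[ok]; b <- b[ok]
  purine <- c("A", "G")
  transition <- a != b & ((a %in% purine) == (b %in% purine))
  P <- mean(transition)
  Q <- mean(a != b & !transition)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P undefined: substitution saturation", call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}
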