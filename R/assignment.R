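## Tiered similarity-based identification: a query is granted the rank its
## best similarity value supports — species at SV >= 98, genus at
## 92 <= SV < 98, family at 85 <= SV < 92, otherwise unassigned — with the
## taxon taken from the single best hit, truncated to the granted rank.

#' Rank a query against a reference library by similarity value
#'
#' @param query one-row barcode record.
#' @param library reference barcode records (non-empty).
#' @param k number of hits to return (capped at library size).
#' @param aligned passed to [similarity_value()].
#' @return data.frame `query_id reference_id sv family genus species`, sorted
#'   by descending SV, ties broken by reference id.
#' @export
best_hits <- function(query, library, k = 10, aligned = "auto") {
  if (!nrow(library)) stop("library must be non-empty", call. = FALSE)
  sv <- vapply(seq_len(nrow(library)), function(i) {
    similarity_value(query$sequence[[1]], library$sequence[[i]],
                     aligned = aligned)
  }, numeric(1))
  ord <- order(-sv, library$id)
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(query_id = query$id[[1]],
             reference_id = library$id[top],
             sv = sv[top],
             family = library$family[top],
             genus = library$genus[top],
             species = library$species[top],
             stringsAsFactors = FALSE)
}

#' Default similarity-tier thresholds (percent)
#' @export
default_thresholds <- function() c(species = 98, genus = 92, family = 85)

#' Assign a taxonomic rank from a hit list
#'
#' Applies the tier rule to the best SV: `species` at `SV >= 98`, `genus` at
#' `92 <= SV < 98`, `family` at `85 <= SV < 92`, `unassigned` below 85
#' (half-open intervals, boundaries included in the higher rank). The taxon
#' is the best hit's lineage truncated to the granted rank.
#'
#' @param hits hit list from [best_hits()] (may be empty).
#' @param thresholds named numeric vector `species/genus/family`, strictly
#'   decreasing in `(0, 100]`.
#' @return one-row data.frame
#'   `query_id rank taxon best_sv n_supporting_hits`.
#' @export
assign_rank <- function(hits, thresholds = default_thresholds()) {
  if (any(diff(thresholds) >= 0) || any(thresholds <= 0) ||
      any(thresholds > 100)) {
    stop("thresholds must be strictly decreasing in (0, 100]", call. = FALSE)
  }
  if (!nrow(hits) || all(is.na(hits$sv))) {
    return(data.frame(query_id = if (nrow(hits)) hits$query_id[1]
                                 else NA_character_,
                      rank = "unassigned", taxon = NA_character_,
                      best_sv = NA_real_, n_supporting_hits = 0L,
                      stringsAsFactors = FALSE))
  }
  best <- hits[1, ]
  sv <- best$sv
  rank <- if (sv >= thresholds[["species"]]) "species"
          else if (sv >= thresholds[["genus"]]) "genus"
          else if (sv >= thresholds[["family"]]) "family"
          else "unassigned"
  taxon <- switch(rank,
                  species = best$species,
                  genus = best$genus,
                  family = best$family,
                  NA_character_)
  n_sup <- if (rank == "unassigned") 0L else {
    thr <- thresholds[[rank]]
    agree <- switch(rank, species = hits$species, genus = hits$genus,
                    family = hits$family)
    sum(hits$sv >= thr & !is.na(agree) & agree == taxon)
  }
  data.frame(query_id = best$query_id, rank = rank, taxon = taxon,
             best_sv = sv, n_supporting_hits = n_sup,
             stringsAsFactors = FALSE)
}

#' Learn single-position diagnostic characters per species
#'
#' A column/state pair is diagnostic for a species when every member of the
#' species carries that unambiguous base at that alignment column and no
#' non-member does. This is a pure-diagnostic character classifier in the
#' spirit of character-based barcoding tools, not a re-implementation of any
#' particular one.
#'
#' @param records equal-length (aligned) reference barcode records with
#'   non-`NA` `species`.
#' @return data.frame `species column state` (class `diagnostic_set`), with
#'   the full species list in attribute `"species"` and alignment length in
#'   `"alignment_length"`. Species with no diagnostic column appear in the
#'   attribute but not in the table; they can never be called.
#' @export
learn_diagnostics <- function(records) {
  sp <- records$species
  if (anyNA(sp)) stop("all training records need a species label",
                      call. = FALSE)
  if (length(unique(sp)) < 2) {
    stop("need at least 2 species to learn diagnostics", call. = FALSE)
  }
  M <- do.call(rbind, strsplit(toupper(records$sequence), "", fixed = TRUE))
  if (length(unique(nchar(records$sequence))) != 1L) {
    stop("training records must be aligned to common coordinates",
         call. = FALSE)
  }
  L <- ncol(M)
  out <- list()
  for (s in unique(sp)) {
    idx <- which(sp == s)
    sub <- M[idx, , drop = FALSE]
    first <- sub[1, ]
    allsame <- colSums(sub == matrix(first, nrow(sub), L, byrow = TRUE)) ==
      nrow(sub)
    others <- M[-idx, , drop = FALSE]
    elsewhere <- colSums(others ==
                           matrix(first, nrow(others), L, byrow = TRUE)) > 0
    cols <- which(allsame & first %in% c("A", "C", "G", "T") & !elsewhere)
    if (length(cols)) {
      out[[s]] <- data.frame(species = s, column = cols, state = first[cols],
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), column = integer(0),
               state = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, species = unique(sp), alignment_length = L,
            class = c("diagnostic_set", "data.frame"))
}

#' Classify a query by diagnostic characters
#'
#' The query is called as the unique species whose full diagnostic set it
#' matches; zero or multiple matching species give a no-call (`NA`), as does
#' an ambiguous base at a diagnostic column.
#'
#' @param query one-row barcode record, in the training alignment's
#'   coordinates (same length).
#' @param diagnostics a `diagnostic_set` from [learn_diagnostics()].
#' @return one-row data.frame `query_id call n_matching`.
#' @export
classify_by_characters <- function(query, diagnostics) {
  L <- attr(diagnostics, "alignment_length")
  q <- strsplit(toupper(query$sequence[[1]]), "", fixed = TRUE)[[1]]
  if (length(q) != L) {
    stop("query must be in the training alignment coordinates (length ",
         L, ")", call. = FALSE)
  }
  callable <- unique(diagnostics$species)
  matching <- callable[vapply(callable, function(s) {
    d <- diagnostics[diagnostics$species == s, , drop = FALSE]
    all(q[d$column] == d$state)
  }, logical(1))]
  data.frame(query_id = query$id[[1]],
             call = if (length(matching) == 1L) matching else NA_character_,
             n_matching = length(matching),
             stringsAsFactors = FALSE)
}

#' MOTU verdict from within/between distance summaries
#'
#' Declared, tunable heuristic: `distinct` when the barcode gap is clean
#' (`min_between > max_within`) and the mean between-group distance is at
#' least `ratio` times the mean within-group distance; `merged-signal` when
#' `mean_between < ratio * mean_within`; otherwise `ambiguous`. A group with
#' zero (or undefined, e.g. singleton) within-distance is `distinct` when
#' `mean_between >= zero_within_cut` and `ambiguous` otherwise.
#'
#' @param mean_within,mean_between group mean p-distances (`mean_within` may
#'   be `NA` for singleton groups — treated as the zero-within case and
#'   flagged by the caller).
#' @param max_within,min_between optional distribution extremes; without
#'   them the clean-gap condition cannot be established and `distinct`
#'   requires the zero-within route.
#' @param ratio mean-ratio threshold R (default 5).
#' @param zero_within_cut minimum mean between-distance granting `distinct`
#'   when within-distance is zero (default 0.02).
#' @return one of `"distinct"`, `"merged-signal"`, `"ambiguous"`.
#' @export
motu_verdict <- function(mean_within, mean_between, max_within = NA,
                         min_between = NA, ratio = 5,
                         zero_within_cut = 0.02) {
  if (is.na(mean_between)) return("ambiguous")
  if (is.na(mean_within) || mean_within == 0) {
    return(if (mean_between >= zero_within_cut) "distinct" else "ambiguous")
  }
  if (!is.na(min_between) && !is.na(max_within) &&
      min_between > max_within && mean_between >= ratio * mean_within) {
    return("distinct")
  }
  if (mean_between < ratio * mean_within) return("merged-signal")
  "ambiguous"
}

#' Per-group MOTU congruence report
#'
#' For every group (species, morphotype, ...) in a grouping, summarizes the
#' within-group distance distribution, the distances to the nearest other
#' group, the barcode-gap ratio, the verdict from [motu_verdict()] and —
#' when a tree is supplied — whether the group is monophyletic.
#'
#' @param matrix labelled p-distance matrix.
#' @param grouping named vector mapping matrix labels to groups.
#' @param tree optional `ape::phylo` over the same labels.
#' @param ratio,zero_within_cut passed to [motu_verdict()].
#' @return data.frame, one row per group:
#'   `group n mean_within max_within nearest_group mean_between min_between`
#'   `gap_ratio verdict monophyletic singleton_fallback`.
#' @export
motu_congruence <- function(matrix, grouping, tree = NULL, ratio = 5,
                            zero_within_cut = 0.02) {
  gd <- group_distances(matrix, grouping)
  win <- gd$within
  btw <- gd$between
  out <- win
  out$nearest_group <- NA_character_
  out$mean_between <- NA_real_
  out$min_between <- NA_real_
  for (k in seq_len(nrow(out))) {
    g <- out$group[k]
    rows <- btw[btw$group1 == g | btw$group2 == g, , drop = FALSE]
    if (!nrow(rows)) next
    near <- rows[which.min(rows$mean_between), ]
    out$nearest_group[k] <- ifelse(near$group1 == g, near$group2,
                                   near$group1)
    out$mean_between[k] <- near$mean_between
    out$min_between[k] <- near$min_between
  }
  out$gap_ratio <- ifelse(!is.na(out$max_within) & out$max_within > 0,
                          out$min_between / out$max_within, NA_real_)
  out$verdict <- vapply(seq_len(nrow(out)), function(k) {
    motu_verdict(out$mean_within[k], out$mean_between[k],
                 out$max_within[k], out$min_between[k],
                 ratio = ratio, zero_within_cut = zero_within_cut)
  }, character(1))
  out$monophyletic <- NA
  if (!is.null(tree)) {
    labs <- names(grouping)
    for (k in seq_len(nrow(out))) {
      tips <- intersect(labs[grouping == out$group[k]], tree$tip.label)
      if (length(tips)) {
        out$monophyletic[k] <- is_monophyletic(tree, tips)
      }
    }
  }
  out$singleton_fallback <- out$n < 2
  out
}
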