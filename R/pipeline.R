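## End-to-end identification run: QC -> similarity search -> tiered rank
## assignment -> diagnostic-character classification -> NJ tree with
## bootstrap -> group distances and MOTU congruence -> per-query report and
## per-morphotype summary. Morphotype labels are metadata carried through and
## reconciled with the molecular result; QC failure flags a query but never
## drops it (identification and QC are independent evidence streams).

#' Pipeline run configuration
#'
#' @param thresholds similarity tiers, named `species/genus/family`, strictly
#'   decreasing in `(0, 100]` (defaults 98/92/85).
#' @param bootstrap NJ bootstrap replicates (default 1000).
#' @param motu_ratio mean-ratio R of the MOTU verdict rule (default 5).
#' @param seed integer seed for every stochastic step.
#' @param outgroup optional outgroup record id for rooting; `NULL` uses any
#'   `role == "outgroup"` record present, if one exists.
#' @param k_hits hits retained per query.
#' @param out_dir optional directory; when set, every intermediate artifact
#'   is written there as its stage completes.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(thresholds = default_thresholds(),
                            bootstrap = 1000, motu_ratio = 5, seed = 1,
                            outgroup = NULL, k_hits = 10, out_dir = NULL) {
  if (any(diff(thresholds) >= 0) || any(thresholds <= 0) ||
      any(thresholds > 100)) {
    stop("thresholds must be strictly decreasing in (0, 100]", call. = FALSE)
  }
  structure(list(thresholds = thresholds, bootstrap = bootstrap,
                 motu_ratio = motu_ratio, seed = seed, outgroup = outgroup,
                 k_hits = k_hits, out_dir = out_dir),
            class = "run_config")
}

run_stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log(sprintf("stage %-12s done", name))
  res
}

#' Run the full identification pipeline
#'
#' @param queries barcode records with `role == "query"` (morphotype labels
#'   optional).
#' @param references barcode records with `role` `"reference"` (and
#'   optionally one `"outgroup"`).
#' @param config a [pipeline_config()].
#' @return list with per-stage artifacts: `qc`, `hits`, `assignments`,
#'   `character_calls`, `tree` (bootstrapped, unrooted), `rooted_tree`,
#'   `dist`, `motu`, the per-query `report`, the per-morphotype `summary`,
#'   the `config` and the run `log`.
#' @export
run_pipeline <- function(queries, references, config = pipeline_config()) {
  validate_records(queries); validate_records(references)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(sprintf("run_pipeline: %d queries, %d references, seed %d",
              nrow(queries), nrow(references), config$seed))
  refs <- references[references$role == "reference", , drop = FALSE]
  if (!nrow(refs)) stop("no reference records", call. = FALSE)
  og <- references[references$role == "outgroup", , drop = FALSE]
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, file) {
    if (!is.null(out_dir)) {
      utils::write.table(obj, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  ## similarity search + tier assignment
  search <- run_stage("similarity", log, {
    hits <- list(); assg <- list()
    for (i in seq_len(nrow(queries))) {
      q <- queries[i, , drop = FALSE]
      h <- best_hits(q, refs, k = config$k_hits)
      hits[[i]] <- h
      assg[[i]] <- assign_rank(h, thresholds = config$thresholds)
    }
    list(hits = do.call(rbind, hits), assignments = do.call(rbind, assg))
  })
  emit(search$hits, "hits.tsv")
  emit(search$assignments, "assignments.tsv")

  ## QC against each query's best reference
  qc <- run_stage("qc", log, {
    best_ref_id <- vapply(split(search$hits, search$hits$query_id),
                          function(h) h$reference_id[1], character(1))
    out <- lapply(seq_len(nrow(queries)), function(i) {
      q <- queries[i, , drop = FALSE]
      ref <- refs[refs$id == best_ref_id[[q$id]], , drop = FALSE]
      qc_barcode(q, best_reference = ref)
    })
    do.call(rbind, out)
  })
  emit(qc, "qc.tsv")
  log(sprintf("qc: %d/%d records flagged",
              sum(qc$has_internal_stop | qc$indel_flag), nrow(qc)))

  ## diagnostic characters (training = references with species labels)
  chars <- run_stage("characters", log, {
    train <- refs[!is.na(refs$species), , drop = FALSE]
    L <- unique(nchar(train$sequence))
    diagnostics <- if (length(L) == 1L && length(unique(train$species)) >= 2)
      learn_diagnostics(train) else NULL
    calls <- lapply(seq_len(nrow(queries)), function(i) {
      q <- queries[i, , drop = FALSE]
      if (!is.null(diagnostics) &&
          nchar(q$sequence) == attr(diagnostics, "alignment_length")) {
        classify_by_characters(q, diagnostics)
      } else {
        data.frame(query_id = q$id, call = NA_character_,
                   n_matching = NA_integer_, stringsAsFactors = FALSE)
      }
    })
    list(diagnostics = diagnostics, calls = do.call(rbind, calls))
  })
  emit(chars$calls, "character_calls.tsv")

  ## NJ tree with bootstrap over all equal-length records
  treestage <- run_stage("tree", log, {
    pool <- rbind(refs, og, queries)
    lens <- nchar(pool$sequence)
    modal <- as.integer(names(which.max(table(lens))))
    pool <- pool[lens == modal, , drop = FALSE]
    if (nrow(pool) < 3) {
      log("tree: fewer than 3 alignable records, skipped")
      list(tree = NULL, rooted = NULL, dist = NULL, pool = pool)
    } else {
      tr <- bootstrap_support(pool, n_reps = config$bootstrap,
                              seed = config$seed)
      og_id <- config$outgroup %||%
        (if (nrow(og)) og$id[1] else NULL)
      rooted <- if (!is.null(og_id) && og_id %in% tr$tip.label) {
        root_on_outgroup(tr, og_id)
      } else NULL
      list(tree = tr, rooted = rooted, dist = distance_matrix(pool),
           pool = pool)
    }
  })
  if (!is.null(out_dir) && !is.null(treestage$tree)) {
    write_newick(treestage$tree, file.path(out_dir, "nj_bootstrap.nwk"))
    if (!is.null(treestage$rooted)) {
      write_newick(treestage$rooted, file.path(out_dir, "nj_rooted.nwk"))
    }
    utils::write.table(treestage$dist,
                       file.path(out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  }

  ## group distances + MOTU congruence (references by species, queries by
  ## morphotype)
  motu <- run_stage("motu", log, {
    if (is.null(treestage$dist)) NULL else {
      pool <- treestage$pool
      grp <- ifelse(pool$role == "query",
                    ifelse(is.na(pool$morphotype), "unlabelled",
                           pool$morphotype),
                    ifelse(is.na(pool$species), "unlabelled", pool$species))
      names(grp) <- pool$id
      motu_congruence(treestage$dist, grp, tree = treestage$tree,
                      ratio = config$motu_ratio)
    }
  })
  if (!is.null(motu)) emit(motu, "motu.tsv")

  ## per-query report
  report <- run_stage("report", log, {
    a <- search$assignments
    besth <- do.call(rbind, lapply(split(search$hits, search$hits$query_id),
                                   function(h) h[1, ]))
    i <- match(queries$id, a$query_id)
    j <- match(queries$id, besth$query_id)
    k <- match(queries$id, qc$id)
    m <- match(queries$id, chars$calls$query_id)
    rep <- data.frame(
      query_id = queries$id,
      morphotype = queries$morphotype,
      qc_frame = qc$frame[k],
      qc_stop = qc$has_internal_stop[k],
      qc_indel = qc$indel_flag[k],
      qc_pass = !(qc$has_internal_stop[k] | qc$indel_flag[k]),
      best_hit = besth$reference_id[j],
      best_sv = besth$sv[j],
      rank = a$rank[i],
      taxon = a$taxon[i],
      character_call = chars$calls$call[m],
      stringsAsFactors = FALSE)
    rep$nj_group_monophyletic <- NA
    if (!is.null(motu)) {
      gm <- match(rep$morphotype, motu$group)
      rep$nj_group_monophyletic <- motu$monophyletic[gm]
    }
    rep$congruence <- congruence_flag(rep, refs)
    rep
  })
  emit(report, "report.tsv")

  summary <- summary_table(report)
  emit(summary, "summary.tsv")
  log(sprintf("report: %d queries, %d morphotypes", nrow(report),
              nrow(summary)))
  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(qc = qc, hits = search$hits, assignments = search$assignments,
       character_calls = chars$calls, diagnostics = chars$diagnostics,
       tree = treestage$tree, rooted_tree = treestage$rooted,
       dist = treestage$dist, motu = motu, report = report,
       summary = summary, config = config, log = log_lines)
}

# morphotype-vs-molecule congruence at the granted rank; mismatch only when
# both labels exist and disagree at that rank
congruence_flag <- function(report, refs) {
  vapply(seq_len(nrow(report)), function(i) {
    morpho <- report$morphotype[i]
    rank <- report$rank[i]
    taxon <- report$taxon[i]
    if (is.na(morpho) || is.na(taxon) || rank == "unassigned") {
      return("indeterminate")
    }
    hit <- refs[!is.na(refs$species) & refs$species == morpho, , drop = FALSE]
    if (!nrow(hit)) return("indeterminate")  # morphotype unknown to library
    morpho_at_rank <- switch(rank, species = hit$species[1],
                             genus = hit$genus[1], family = hit$family[1])
    if (is.na(morpho_at_rank)) return("indeterminate")
    if (morpho_at_rank == taxon) "match" else "mismatch"
  }, character(1))
}

#' Per-morphotype summary of an identification report
#'
#' One row per morphotype: specimen count, modal molecular taxon and rank,
#' SV range (min/median/max), modal character-classifier call (`NA` when the
#' classifier never called the group), NJ monophyly of the group, and the
#' congruence of morphology and molecules.
#'
#' @param report the per-query report from [run_pipeline()].
#' @return data.frame, one row per distinct morphotype.
#' @export
summary_table <- function(report) {
  morpho <- ifelse(is.na(report$morphotype), "unlabelled", report$morphotype)
  out <- lapply(sort(unique(morpho)), function(mt) {
    r <- report[morpho == mt, , drop = FALSE]
    modal <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      tt <- sort(table(x), decreasing = TRUE)
      names(tt)[1]
    }
    data.frame(morphotype = mt, n = nrow(r),
               taxon = modal(r$taxon), rank = modal(r$rank),
               sv_min = min(r$best_sv, na.rm = TRUE),
               sv_median = stats::median(r$best_sv, na.rm = TRUE),
               sv_max = max(r$best_sv, na.rm = TRUE),
               character_call = modal(r$character_call),
               nj_monophyletic = r$nj_group_monophyletic[1],
               congruence = modal(r$congruence),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the pipeline from files
#'
#' @param query_fasta,library_fasta FASTA paths.
#' @param meta_tsv metadata TSV
#'   (`id family genus species morphotype life_stage role`) covering both
#'   files.
#' @param config a [pipeline_config()].
#' @return as [run_pipeline()].
#' @export
run_pipeline_files <- function(query_fasta, library_fasta, meta_tsv,
                               config = pipeline_config()) {
  queries <- suppressWarnings(read_metadata(read_fasta(query_fasta),
                                            meta_tsv))
  queries$role[is.na(queries$role)] <- "query"
  lib <- suppressWarnings(read_metadata(read_fasta(library_fasta), meta_tsv))
  run_pipeline(queries[queries$role == "query", , drop = FALSE],
               lib[lib$role != "query", , drop = FALSE], config)
}
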