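q_from <- function(seq) barcode_records("q", seq, role = "query")

hitlist <- function(sv, species = "Gen01_sp1", genus = "Gen01",
                    family = "Fam1") {
  data.frame(query_id = rep("q", length(sv)),
             reference_id = sprintf("r%d", seq_along(sv)),
             sv = sv, family = rep(family, length(sv)),
             genus = rep(genus, length(sv)),
             species = rep(species, length(sv)),
             stringsAsFactors = FALSE)
}

test_that("the tier rule maps SV bands to ranks with exact boundaries", {
  cases <- list(
    # the family- and genus-level outcomes seen with Chlopsis (85.9) and
    # Facciolella (93), and a >=99 species-level match
    list(85.9, "family"), list(93, "genus"), list(99, "species"),
    list(100, "species"), list(98.0, "species"), list(97.999, "genus"),
    list(92.0, "genus"), list(91.999, "family"), list(85.0, "family"),
    list(84.999, "unassigned"))
  for (cs in cases) {
    expect_identical(assign_rank(hitlist(cs[[1]]))$rank, cs[[2]])
  }
  # taxon is truncated to the granted rank
  expect_identical(assign_rank(hitlist(99))$taxon, "Gen01_sp1")
  expect_identical(assign_rank(hitlist(93))$taxon, "Gen01")
  expect_identical(assign_rank(hitlist(85.9))$taxon, "Fam1")
  expect_true(is.na(assign_rank(hitlist(80))$taxon))
  # empty hit list -> unassigned
  out <- assign_rank(hitlist(numeric(0)))
  expect_identical(out$rank, "unassigned")
  expect_identical(out$n_supporting_hits, 0L)
  expect_error(assign_rank(hitlist(99), thresholds = c(species = 90,
                                                       genus = 92,
                                                       family = 85)),
               "strictly decreasing")
})

test_that("every SV in [0,100] maps to exactly one rank", {
  svs <- seq(0, 100, by = 0.5)
  ranks <- vapply(svs, function(s) assign_rank(hitlist(s))$rank,
                  character(1))
  expect_true(all(ranks %in% c("species", "genus", "family", "unassigned")))
  expect_identical(ranks, vapply(svs, function(s)
    assign_rank(hitlist(s))$rank, character(1)))  # deterministic
  # band edges
  expect_identical(unique(ranks[svs >= 98]), "species")
  expect_identical(unique(ranks[svs >= 92 & svs < 98]), "genus")
  expect_identical(unique(ranks[svs >= 85 & svs < 92]), "family")
  expect_identical(unique(ranks[svs < 85]), "unassigned")
})

test_that("best hits are ranked by SV with deterministic ties", {
  lib <- tiny_library()
  refs <- lib$records[lib$records$role == "reference", ]
  q <- refs[5, , drop = FALSE]
  q$id <- "query1"; q$role <- "query"
  h <- best_hits(q, refs, k = 3)
  expect_identical(h$reference_id[1], refs$id[5])
  expect_equal(h$sv[1], 100)
  expect_true(all(diff(h$sv) <= 0))
  # k larger than the library returns the full ranking
  h2 <- best_hits(q, refs, k = 1000)
  expect_identical(nrow(h2), nrow(refs))
  # exact ties break by reference id
  twins <- barcode_records(c("b_ref", "a_ref"), rep(refs$sequence[1], 2),
                           family = "F", genus = "G",
                           species = c("G_s1", "G_s2"))
  ht <- best_hits(q_from(refs$sequence[1]), twins, k = 2)
  expect_identical(ht$reference_id, c("a_ref", "b_ref"))
})

test_that("conspecific queries hit a conspecific reference first", {
  lib <- simulate_library()
  qs <- simulate_queries(lib$records, n_conspecific = 20,
                         n_novel_species = 0, n_novel_genus = 0, seed = 13)
  refs <- lib$records[lib$records$role == "reference", ]
  top_ok <- vapply(seq_len(nrow(qs$records)), function(i) {
    h <- best_hits(qs$records[i, , drop = FALSE], refs, k = 1)
    h$species[1] == qs$truth$species[i]
  }, logical(1))
  expect_gte(mean(top_ok), 0.95)
})

test_that("diagnostic characters are pure and drive classification", {
  # two species differing at exactly one fixed column
  s1 <- strrep("ATGGCC", 20)
  s2 <- paste0(substr(s1, 1, 29), "T", substr(s1, 31, 120))
  recs <- barcode_records(paste0("r", 1:4), c(s1, s1, s2, s2),
                          family = "F", genus = "G",
                          species = rep(c("G_s1", "G_s2"), each = 2))
  d <- learn_diagnostics(recs)
  expect_identical(sort(unique(d$species)), c("G_s1", "G_s2"))
  expect_identical(d$column, c(30L, 30L))
  expect_identical(d$state[d$species == "G_s1"], "C")
  expect_identical(d$state[d$species == "G_s2"], "T")
  # purity invariant holds by re-verification against the training matrix
  for (k in seq_len(nrow(d))) {
    members <- recs$species == d$species[k]
    col_states <- substr(recs$sequence, d$column[k], d$column[k])
    expect_true(all(col_states[members] == d$state[k]))
    expect_false(any(col_states[!members] == d$state[k]))
  }
  # conspecific query -> correct call
  expect_identical(classify_by_characters(q_from(s1), d)$call, "G_s1")
  expect_identical(classify_by_characters(q_from(s2), d)$call, "G_s2")
  # an N at the diagnostic column -> no-call
  sN <- paste0(substr(s1, 1, 29), "N", substr(s1, 31, 120))
  out <- classify_by_characters(q_from(sN), d)
  expect_true(is.na(out$call))
  expect_identical(out$n_matching, 0L)
  expect_error(learn_diagnostics(recs[1:2, ]), "at least 2 species")
})

test_that("character classification recovers simulated conspecifics", {
  lib <- simulate_library()
  refs <- lib$records[lib$records$role == "reference", ]
  d <- learn_diagnostics(refs)
  qs <- simulate_queries(lib$records, n_conspecific = 30,
                         n_novel_species = 0, n_novel_genus = 0, seed = 21)
  calls <- vapply(seq_len(nrow(qs$records)), function(i) {
    out <- classify_by_characters(qs$records[i, , drop = FALSE], d)
    identical(out$call, qs$truth$species[i])
  }, logical(1))
  expect_gte(mean(calls), 0.9)
})

test_that("the MOTU verdict rule reproduces both qualitative outcomes", {
  # congeneric split at the same magnitude as within-species variation
  # (between 0.009 vs within 0.004)
  expect_identical(motu_verdict(0.004, 0.009), "merged-signal")
  # zero within-species distance, between >= 0.059: well-defined MOTU
  expect_identical(motu_verdict(0.000, 0.059), "distinct")
  expect_identical(motu_verdict(0.000, 0.070), "distinct")
  # equal means fall on the merged side of the mean-ratio rule
  expect_identical(motu_verdict(0.01, 0.01), "merged-signal")
  # zero within but negligible between: ambiguous
  expect_identical(motu_verdict(0, 0.001), "ambiguous")
  # clean gap and large ratio: distinct
  expect_identical(motu_verdict(0.004, 0.08, max_within = 0.006,
                                min_between = 0.06), "distinct")
  # large mean ratio but no extreme information: cannot call distinct
  expect_identical(motu_verdict(0.004, 0.08), "ambiguous")
  expect_identical(motu_verdict(NA, 0.05), "distinct")  # singleton fallback
  expect_identical(motu_verdict(0.01, NA), "ambiguous")
})

test_that("motu_congruence summarizes groups against matrix and tree", {
  lib <- two_clade_library()
  refs <- lib$records
  D <- distance_matrix(refs)
  tr <- nj_tree(D)
  grp <- stats::setNames(refs$species, refs$id)
  rep <- motu_congruence(D, grp, tree = tr)
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$verdict == "distinct"))  # within 0, between ~0.1
  expect_true(all(rep$monophyletic))
  expect_false(any(rep$singleton_fallback))
  # singleton group flagged, within undefined
  grp2 <- grp
  grp2[1] <- "solo"
  rep2 <- motu_congruence(D, grp2, tree = tr)
  solo <- rep2[rep2$group == "solo", ]
  expect_true(is.na(solo$mean_within))
  expect_true(solo$singleton_fallback)
})
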