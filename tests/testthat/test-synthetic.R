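test_that("same specs and seed give byte-identical libraries", {
  a <- simulate_library(taxonomy_spec(2, 2, 2, 2), divergence_spec(),
                        seed = 11)
  b <- simulate_library(taxonomy_spec(2, 2, 2, 2), divergence_spec(),
                        seed = 11)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$records, f1); write_fasta(b$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c <- simulate_library(taxonomy_spec(2, 2, 2, 2), divergence_spec(),
                        seed = 12)
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("zero within-species divergence gives identical conspecifics", {
  lib <- simulate_library(taxonomy_spec(2, 1, 2, 4),
                          divergence_spec(0, 0.05, 0.10, 0.15),
                          seed = 5, outgroup = FALSE)
  refs <- lib$records
  for (sp in unique(refs$species)) {
    seqs <- refs$sequence[refs$species == sp]
    expect_length(unique(seqs), 1L)
  }
  D <- distance_matrix(refs)
  gd <- group_distances(D, stats::setNames(refs$species, refs$id))
  expect_true(all(gd$within$mean_within == 0))
})

test_that("realized divergence tiers hit their targets within 30%", {
  targets <- c(0.005, 0.05, 0.10, 0.15)
  lib <- simulate_library(taxonomy_spec(5, 2, 3, 4),
                          divergence_spec(targets[1], targets[2],
                                          targets[3], targets[4],
                                          seq_length = 657),
                          seed = 42, outgroup = FALSE)
  refs <- lib$records
  D <- distance_matrix(refs)
  sp <- refs$species[match(rownames(D), refs$id)]
  gen <- refs$genus[match(rownames(D), refs$id)]
  fam <- refs$family[match(rownames(D), refs$id)]
  ut <- upper.tri(D)
  tier <- matrix("between_family", nrow(D), ncol(D))
  tier[outer(fam, fam, "==")] <- "within_family"
  tier[outer(gen, gen, "==")] <- "within_genus"
  tier[outer(sp, sp, "==")] <- "within_species"
  means <- tapply(D[ut], tier[ut], mean)
  realized <- means[c("within_species", "within_genus", "within_family",
                      "between_family")]
  expect_true(all(abs(realized - targets) / targets <= 0.30))
  # tier ordering holds
  expect_true(all(diff(realized) > 0))
})

test_that("simulated coding sequences are stop-free in frame 0", {
  lib <- tiny_library()
  for (s in lib$records$sequence) {
    n_cod <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    expect_false(any(cods %in% c("TAA", "TAG", "AGA", "AGG")))
  }
})

test_that("impossible divergence orderings are rejected", {
  expect_error(divergence_spec(0.05, 0.05, 0.10, 0.15), "within-genus")
  expect_error(divergence_spec(0.01, 0.2, 0.1, 0.3), "within-genus")
  expect_error(divergence_spec(0.01, 0.05, 0.1, 0.8), "within-genus")
  expect_error(divergence_spec(seq_length = 656), "multiple of 3")
  expect_error(taxonomy_spec(n_families = 0), "counts")
})

test_that("query truth tables record the expected assignable rank", {
  lib <- tiny_library()
  qs <- simulate_queries(lib$records, n_conspecific = 2,
                         n_novel_species = 2, n_novel_genus = 2, seed = 9)
  expect_identical(qs$truth$expected_rank,
                   rep(c("species", "genus", "family"), each = 2))
  # novel-genus queries carry a family but no genus/species
  ng <- qs$truth[qs$truth$expected_rank == "family", ]
  expect_true(all(!is.na(ng$family)))
  expect_true(all(is.na(ng$genus)))
  # conspecific query at zero divergence is identical to its source
  lib0 <- simulate_library(taxonomy_spec(1, 1, 2, 2),
                           divergence_spec(0, 0.05, 0.10, 0.15),
                           seed = 2, outgroup = FALSE)
  q0 <- simulate_queries(lib0$records, 1, 0, 0, seed = 3)
  src <- unique(lib0$records$sequence[lib0$records$species ==
                                        q0$truth$source])
  expect_identical(q0$records$sequence, src)
  expect_identical(q0$truth$expected_rank, "species")
})

test_that("query simulation rejects requests the library cannot support", {
  lib <- tiny_library()
  bare <- lib$records
  bare$species <- NA_character_
  bare$genus <- NA_character_
  bare$family <- NA_character_
  expect_error(simulate_queries(bare, 1, 0, 0, seed = 1,
                                divergence = divergence_spec()),
               "exceeds available taxa")
  expect_error(simulate_queries(lib$records[0, ], 1, 0, 0, seed = 1,
                                divergence = divergence_spec()),
               "no reference records")
})

test_that("artifact injection is deterministic and by construction", {
  lib <- tiny_library()
  refs <- lib$records
  # identity at zero rates
  none <- inject_artifacts(refs, 0, 0, seed = 1)
  expect_identical(none$records$sequence, refs$sequence)
  expect_false(any(none$truth$has_indel | none$truth$has_stop))
  # stop_rate 1: every record acquires an internal frame-0 stop
  allstop <- inject_artifacts(refs, 0, 1, seed = 1)
  expect_true(all(allstop$truth$has_stop))
  for (s in allstop$records$sequence) {
    n_cod <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    expect_true(any(cods[2:(n_cod - 1)] %in% c("TAA", "TAG", "AGA", "AGG")))
  }
  # same seed corrupts the same subset
  a <- inject_artifacts(refs, 0.5, 0.2, seed = 8)
  b <- inject_artifacts(refs, 0.5, 0.2, seed = 8)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_identical(a$truth, b$truth)
  # indels change length by a non-multiple of 3
  changed <- a$truth$has_indel
  dlen <- abs(nchar(a$records$sequence) - nchar(refs$sequence))
  expect_true(all(dlen[changed] == 1))
  expect_true(all(dlen[!changed] == 0))
  expect_error(inject_artifacts(refs, -0.1, 0, seed = 1), "rates")
})
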