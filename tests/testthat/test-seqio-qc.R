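test_that("FASTA write/read round-trips a simulated library exactly", {
  lib <- tiny_library()
  f <- tempfile(fileext = ".fasta")
  write_fasta(lib$records, f)
  back <- read_fasta(f)
  expect_identical(back$id, lib$records$id)
  expect_identical(back$sequence, lib$records$sequence)
  # 70-column wrap
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 70))
})

test_that("malformed FASTA and metadata are rejected with the offender named", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACGT", ">dup", "ACGA"), f)
  expect_error(read_fasta(f), "dup")
  writeLines(c(">ok", "ACGT", ">bad", "ACXT"), f)
  expect_error(read_fasta(f), "bad")
  # metadata with species but no genus violates the lineage nesting
  lib <- simulate_library(taxonomy_spec(1, 1, 1, 2), divergence_spec(),
                          seed = 1, outgroup = FALSE)
  fa <- tempfile(); md <- tempfile()
  write_fasta(lib$records, fa)
  bad <- lib$records
  bad$genus <- NA_character_
  write_metadata(bad, md)
  expect_error(read_metadata(read_fasta(fa), md), "lineage invariant")
})

test_that("metadata joins by id and reports unmatched rows", {
  lib <- tiny_library()
  fa <- tempfile(); md <- tempfile()
  write_fasta(lib$records, fa)
  extra <- rbind(lib$records,
                 within(lib$records[1, ], {
                   id <- "ghost"; sequence <- "ACGT"
                 }))
  write_metadata(extra, md)
  expect_warning(out <- read_metadata(read_fasta(fa), md), "ghost")
  expect_identical(attr(out, "unmatched"), "ghost")
  expect_identical(out$species, lib$records$species)
  expect_identical(out$role, lib$records$role)
})

test_that("reading frame is the argmin of internal stop counts", {
  lib <- simulate_library(taxonomy_spec(1, 1, 1, 1), divergence_spec(),
                          seed = 4, outgroup = FALSE)
  clean <- lib$records$sequence[1]
  fr <- detect_reading_frame(clean)
  expect_identical(fr$frame, 0L)
  expect_identical(fr$stops_per_frame[["0"]], 0L)
  # shifting by one base moves the clean frame to 1
  shifted <- paste0("G", clean)
  expect_identical(detect_reading_frame(shifted)$frame, 1L)
  # independent brute-force count agrees in every frame
  brute <- function(s, f) {
    stops <- c("TAA", "TAG", "AGA", "AGG")
    cods <- character(0)
    i <- f + 1
    while (i + 2 <= nchar(s)) {
      cods <- c(cods, substr(s, i, i + 2))
      i <- i + 3
    }
    if ((nchar(s) - f) %% 3 == 0 && length(cods)) {
      cods <- cods[-length(cods)]
    }
    sum(cods %in% stops)
  }
  for (f in 0:2) {
    expect_identical(detect_reading_frame(shifted)$stops_per_frame[[
      as.character(f)]], brute(shifted, f))
  }
  expect_error(detect_reading_frame("AC-GT"), "ungapped")
  expect_error(detect_reading_frame("ACGTACGT"), "too short")
})

test_that("a sequence with tied stop counts in all frames is undetermined", {
  # ATGGCC repeats are stop-free in every frame; plant one TAA per frame
  base <- strrep("ATGGCC", 20)
  plant <- function(s, at) {
    paste0(substr(s, 1, at - 1), "TAA", substr(s, at + 3, nchar(s)))
  }
  s3 <- plant(plant(plant(base, 13), 32), 63)
  fr <- detect_reading_frame(s3)
  expect_identical(unname(fr$stops_per_frame), c(1L, 1L, 1L))
  expect_identical(fr$frame, "undetermined")
  # an extra stop in frames 1 and 2 breaks the tie: frame 0 is the argmin
  s4 <- plant(plant(s3, 92), 117)
  fr4 <- detect_reading_frame(s4)
  expect_identical(fr4$frame, 0L)
  expect_true(fr4$stops_per_frame[["0"]] <= min(fr4$stops_per_frame[-1]))
})

test_that("QC flags injected stops and indels and passes clean records", {
  lib <- simulate_library(taxonomy_spec(2, 2, 2, 3), divergence_spec(),
                          seed = 7, outgroup = FALSE)
  corr <- inject_artifacts(lib$records, indel_rate = 0.3, stop_rate = 0.3,
                           seed = 42)
  qc <- qc_barcodes(corr$records, references = lib$records)
  truth <- corr$truth
  expect_identical(qc$id, truth$id)
  # sensitivity 100%
  expect_true(all(qc$has_internal_stop[truth$has_stop]))
  expect_true(all(qc$indel_flag[truth$has_indel]))
  # no false positives on clean records
  clean <- !truth$has_stop & !truth$has_indel
  expect_true(any(clean))
  expect_false(any(qc$has_internal_stop[clean] | qc$indel_flag[clean]))
  expect_true(all(qc$indel_basis == "alignment"))
})

test_that("QC reports frame, length and ambiguity without a reference", {
  rec <- barcode_records("amb", paste0(strrep("ATGGCC", 20), "NNN"))
  out <- qc_barcode(rec, modal_mod3 = 0L)
  expect_identical(out$frame, "0")
  expect_false(out$has_internal_stop)
  expect_false(out$indel_flag)
  expect_identical(out$indel_basis, "length_mod3")
  expect_identical(out$length, 123L)
  expect_equal(out$ambiguous_fraction, 3 / 123)
  # length fallback flags a record off the modal length class
  rec2 <- barcode_records("short", strrep("ATGGCC", 20))
  out2 <- qc_barcode(rec2, modal_mod3 = 1L)
  expect_true(out2$indel_flag)
})
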