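## Functional-barcode QC: a clean COI fragment translates without internal
## stop codons under the vertebrate mitochondrial code (table 2; stops TAA,
## TAG, AGA, AGG) and aligns to a reference without internal gaps. Stop or
## indel signals suggest a pseudogene/NUMT or a sequencing artifact.

# Internal codons of `seq` in frame f (0/1/2): complete codons excluding the
# terminal one (partial or not). Ambiguity codes never count as stops.
count_internal_stops <- function(seq, frame) {
  L <- nchar(seq)
  starts <- seq.int(frame + 1L, L - 2L, by = 3L)
  if (length(starts) <= 1L) return(0L)
  if ((L - frame) %% 3L == 0L) {
    starts <- starts[-length(starts)]  # terminal codon never counted
  }  # else the terminal codon is partial and already excluded
  sum(substring(seq, starts, starts + 2L) %in% .MITO_STOPS)
}

#' Detect the reading frame of a COI fragment
#'
#' Returns the frame (0, 1 or 2) minimizing the number of internal stop
#' codons under the vertebrate mitochondrial genetic code, together with the
#' per-frame stop counts. When all three frames tie with more than zero
#' stops the frame is `"undetermined"`; a tie between two frames at the
#' minimum resolves to the lower frame index.
#'
#' @param sequence an ungapped IUPAC nucleotide string of length >= 60.
#' @return list with `frame` (integer 0/1/2 or the string `"undetermined"`)
#'   and `stops_per_frame` (integer vector, names `"0" "1" "2"`).
#' @export
detect_reading_frame <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE)) {
    stop("sequence must be ungapped", call. = FALSE)
  }
  if (nchar(sequence) < 60) {
    stop("sequence too short for frame detection (< 60 bases)",
         call. = FALSE)
  }
  stops <- vapply(0:2, count_internal_stops, integer(1), seq = sequence)
  names(stops) <- as.character(0:2)
  frame <- if (all(stops == stops[1]) && stops[1] > 0L) "undetermined"
           else unname(which.min(stops)) - 1L
  list(frame = frame, stops_per_frame = stops)
}

#' QC report for one barcode
#'
#' Frame and internal-stop status come from [detect_reading_frame()]. When
#' `best_reference` is supplied the record is first projected into the
#' reference's coordinates (insertions dropped, deleted sites masked as `N`),
#' so stop screening happens in the homologous reading frame even when the
#' record carries a frameshifting indel; the reported frame is then the
#' frame of the reference coordinate system. The indel flag is set when the
#' global alignment against `best_reference` contains an internal gap;
#' without a reference it falls back to comparing `length mod 3` against the
#' modal length class of the dataset (`modal_mod3`), and the report records
#' which criterion was used.
#'
#' @param record one-row barcode record data.frame (or list with `id`,
#'   `sequence`).
#' @param best_reference optional one-row record to align against.
#' @param modal_mod3 optional integer in 0:2, the modal `length %% 3` of the
#'   dataset; used only when `best_reference` is missing.
#' @return one-row data.frame:
#'   `id frame has_internal_stop indel_flag indel_basis length`
#'   `ambiguous_fraction`.
#' @export
qc_barcode <- function(record, best_reference = NULL, modal_mod3 = NULL) {
  seq <- toupper(record$sequence[[1]])
  if (!is.null(best_reference)) {
    aln <- align_pair(record, best_reference)
    gaps <- internal_gap_columns(aln)
    indel <- gaps > 0L
    basis <- "alignment"
    fr <- detect_reading_frame(project_to_reference(aln))
  } else {
    fr <- detect_reading_frame(seq)
    if (!is.null(modal_mod3)) {
      indel <- (nchar(seq) %% 3L) != modal_mod3
      basis <- "length_mod3"
    } else {
      indel <- NA
      basis <- "none"
    }
  }
  has_stop <- if (identical(fr$frame, "undetermined")) TRUE
              else fr$stops_per_frame[[as.character(fr$frame)]] > 0L
  n <- nchar(seq)
  amb <- 1 - sum(strsplit(seq, "", fixed = TRUE)[[1]] %in%
                   c("A", "C", "G", "T")) / n
  data.frame(id = record$id[[1]],
             frame = as.character(fr$frame),
             has_internal_stop = has_stop,
             indel_flag = indel,
             indel_basis = basis,
             length = n,
             ambiguous_fraction = amb,
             stringsAsFactors = FALSE)
}

# record sequence in reference coordinates: drop columns where the
# reference is gapped (insertions), mask record gaps (deletions) as N
project_to_reference <- function(aln) {
  a <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  keep <- b != "-"
  out <- a[keep]
  out[out == "-"] <- "N"
  paste(out, collapse = "")
}

# number of gap characters in non-terminal alignment columns
internal_gap_columns <- function(aln) {
  a <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  gap <- a == "-" | b == "-"
  core <- seq_along(gap)
  nong <- which(!gap)
  if (!length(nong)) return(0L)
  core <- core >= min(nong) & core <= max(nong)
  sum(gap & core)
}

#' QC a whole dataset of barcodes
#'
#' Runs [qc_barcode()] on every record. When `references` is supplied, each
#' record is screened against its nearest reference (best SV hit); otherwise
#' the modal length class of `records` drives the indel fallback.
#'
#' @param records barcode record data.frame.
#' @param references optional reference record data.frame for
#'   alignment-based indel screening.
#' @return QC report data.frame, one row per record.
#' @export
qc_barcodes <- function(records, references = NULL) {
  validate_records(records)
  modal <- as.integer(names(which.max(table(nchar(records$sequence) %% 3L))))
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    ref <- NULL
    if (!is.null(references)) {
      hits <- best_hits(rec, references, k = 1L)
      ref <- references[references$id == hits$reference_id[1], , drop = FALSE]
    }
    out[[i]] <- qc_barcode(rec, best_reference = ref, modal_mod3 = modal)
  }
  do.call(rbind, out)
}
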