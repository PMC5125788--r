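#' Read a FASTA file into barcode records
#'
#' Sequences only; lineage/morphotype/role come from [read_metadata()].
#' Rejects duplicate ids, empty sequences and non-IUPAC symbols, naming the
#' offending record.
#'
#' @param path FASTA file.
#' @return barcode record data.frame (lineage fields `NA`, role
#'   `"reference"`).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))  # id = first whitespace-separated token
  barcode_records(id = ids, sequence = as.character(x))
}

#' Write barcode records to FASTA (70-column wrap)
#'
#' @param records barcode record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a metadata TSV and join it onto sequence records
#'
#' The TSV must have the header
#' `id family genus species morphotype life_stage role`. The join is by `id`;
#' metadata rows without a matching sequence are reported via a warning and
#' attached as attribute `"unmatched"`.
#'
#' @param records barcode record data.frame (typically from [read_fasta()]).
#' @param path metadata TSV.
#' @return records with metadata columns filled in.
#' @export
read_metadata <- function(records, path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character")
  need <- c("id", "family", "genus", "species", "morphotype", "life_stage",
            "role")
  if (!identical(names(md), need)) {
    stop("metadata header must be exactly: ", paste(need, collapse = " "),
         call. = FALSE)
  }
  if (anyDuplicated(md$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "),
         call. = FALSE)
  }
  i <- match(records$id, md$id)
  hit <- !is.na(i)
  for (col in setdiff(need, "id")) {
    records[[col]][hit] <- md[[col]][i[hit]]
  }
  records$role[is.na(records$role)] <- "reference"
  validate_records(records)
  unmatched <- setdiff(md$id, records$id)
  if (length(unmatched)) {
    warning("metadata rows with no matching sequence: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  attr(records, "unmatched") <- unmatched
  records
}

#' Write the metadata table for a set of records
#' @param records barcode record data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  cols <- c("id", "family", "genus", "species", "morphotype", "life_stage",
            "role")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
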