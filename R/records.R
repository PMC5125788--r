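## Barcode records are plain data.frames with one row per sequence and the
## columns below; `barcode_records()` is the validating constructor used by
## the simulator and the FASTA/metadata readers.

.RECORD_COLS <- c("id", "sequence", "family", "genus", "species",
                  "morphotype", "life_stage", "role")

.IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

.LIFE_STAGES <- c("larva", "metamorphosing", "juvenile", "adult")

#' Construct a validated set of barcode records
#'
#' A barcode record ties one nucleotide sequence to its identifier, lineage
#' (family/genus/species, each optional but nested: species implies genus
#' implies family), an optional morphotype label and life stage, and its role
#' in an analysis (`query`, `reference` or `outgroup`).
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of IUPAC nucleotide sequences (gap `-`
#'   allowed).
#' @param family,genus,species optional lineage fields (`NA` where unknown).
#' @param morphotype optional morphotype label.
#' @param life_stage optional; one of `"larva"`, `"metamorphosing"`,
#'   `"juvenile"`, `"adult"`.
#' @param role one of `"query"`, `"reference"`, `"outgroup"` per record.
#' @return a `data.frame` with one row per record.
#' @export
barcode_records <- function(id, sequence,
                            family = NA_character_, genus = NA_character_,
                            species = NA_character_,
                            morphotype = NA_character_,
                            life_stage = NA_character_,
                            role = "reference") {
  df <- data.frame(id = as.character(id),
                   sequence = toupper(as.character(sequence)),
                   family = as.character(family),
                   genus = as.character(genus),
                   species = as.character(species),
                   morphotype = as.character(morphotype),
                   life_stage = as.character(life_stage),
                   role = as.character(role),
                   stringsAsFactors = FALSE)
  validate_records(df)
  df
}

#' @keywords internal
validate_records <- function(df) {
  stopifnot(is.data.frame(df), all(.RECORD_COLS %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("duplicate record id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  empty <- !nzchar(df$sequence) | is.na(df$sequence)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(df$id[empty], collapse = ", "), call. = FALSE)
  }
  chars <- unique(unlist(strsplit(df$sequence, "", fixed = TRUE)))
  bad <- setdiff(chars, .IUPAC_CHARS)
  if (length(bad)) {
    offender <- df$id[vapply(strsplit(df$sequence, "", fixed = TRUE),
                             function(s) any(s %in% bad), logical(1))][1]
    stop("non-IUPAC symbol(s) ", paste(bad, collapse = ""),
         " in record ", offender, call. = FALSE)
  }
  check_lineage(df)
  badrole <- !df$role %in% c("query", "reference", "outgroup")
  if (any(badrole)) {
    stop("invalid role for record(s): ",
         paste(df$id[badrole], collapse = ", "), call. = FALSE)
  }
  ok_stage <- is.na(df$life_stage) | df$life_stage %in% .LIFE_STAGES
  if (!all(ok_stage)) {
    stop("invalid life_stage for record(s): ",
         paste(df$id[!ok_stage], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# species set => genus set => family set
check_lineage <- function(df) {
  has <- function(x) !is.na(x) & nzchar(x)
  bad <- (has(df$species) & !has(df$genus)) | (has(df$genus) & !has(df$family))
  if (any(bad)) {
    stop("lineage invariant violated (species implies genus implies family) ",
         "for record(s): ", paste(df$id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

## Vertebrate mitochondrial genetic code (NCBI translation table 2):
## stop codons TAA, TAG, AGA, AGG; TGA codes for tryptophan.
.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")
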