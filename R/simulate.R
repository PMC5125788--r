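## Synthetic COI reference libraries with a hierarchical divergence structure
## (specimens within species within genera within families), calibrated so the
## realized p-distance tiers straddle the 98/92/85% similarity thresholds.
## Divergence is realized on a star topology per tier: every taxon at a tier
## descends independently from its tier ancestor, which gives direct control
## of the tier means. Substitutions are Jukes-Cantor-like (per-site, equal
## rates to the 3 alternative bases); codons that would create an in-frame
## stop under the vertebrate mitochondrial code are reverted.

#' Taxonomy specification for the synthetic library
#'
#' @param n_families,genera_per_family,species_per_genus,specimens_per_species
#'   counts, all >= 1.
#' @param name_prefixes named character vector with elements `family`, `genus`,
#'   `species` used to build taxon names.
#' @return a list of class `taxonomy_spec`.
#' @export
taxonomy_spec <- function(n_families = 5, genera_per_family = 2,
                          species_per_genus = 3, specimens_per_species = 4,
                          name_prefixes = c(family = "Fam", genus = "Gen",
                                            species = "sp")) {
  counts <- c(n_families, genera_per_family, species_per_genus,
              specimens_per_species)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all taxonomy counts must be integers >= 1", call. = FALSE)
  }
  structure(list(n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 specimens_per_species = specimens_per_species,
                 name_prefixes = name_prefixes),
            class = "taxonomy_spec")
}

#' Divergence specification for the synthetic library
#'
#' Expected mean pairwise p-distances per tier. The tiers must be strictly
#' increasing and below 0.75 (the Jukes-Cantor saturation ceiling). Defaults
#' place conspecific pairs well above the species similarity threshold
#' (SV ~ 99.5), congeneric pairs in the genus band (SV ~ 95) and confamilial
#' pairs in the family band (SV ~ 90).
#'
#' @param d_within_species,d_within_genus,d_within_family,d_between_family
#'   target mean pairwise p-distances (fractions).
#' @param seq_length fragment length in bases; must be a multiple of 3.
#' @param seed integer seed used when none is passed to the generator.
#' @return a list of class `divergence_spec`.
#' @export
divergence_spec <- function(d_within_species = 0.005, d_within_genus = 0.05,
                            d_within_family = 0.10, d_between_family = 0.15,
                            seq_length = 657, seed = 42) {
  d <- c(d_within_species, d_within_genus, d_within_family, d_between_family)
  if (d[1] < 0 || any(diff(d) <= 0) || d[4] >= 0.75) {
    stop("divergence tiers must satisfy 0 <= within-species < within-genus ",
         "< within-family < between-family < 0.75", call. = FALSE)
  }
  if (seq_length %% 3 != 0 || seq_length < 60) {
    stop("seq_length must be a multiple of 3 and >= 60", call. = FALSE)
  }
  structure(list(d_within_species = d_within_species,
                 d_within_genus = d_within_genus,
                 d_within_family = d_within_family,
                 d_between_family = d_between_family,
                 seq_length = seq_length, seed = seed),
            class = "divergence_spec")
}

# Per-branch substitution proportion m such that two lineages independently
# mutated at m from a common ancestor sit at expected p-distance d:
# E[p] = 2m(1-m) + (2/3)m^2  =>  (4/3)m^2 - 2m + d = 0.
branch_m <- function(d) {
  if (d <= 0) return(0)
  (2 - sqrt(4 - 16 * d / 3)) * 3 / 8
}

# Random coding sequence: uniform draw over the 60 non-stop codons of the
# vertebrate mitochondrial code.
random_coding_seq <- function(seq_length) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, .MITO_STOPS)
  paste(sample(codons, seq_length / 3, replace = TRUE), collapse = "")
}

# Mutate a clean coding sequence at per-site proportion m (each hit site moves
# to one of the 3 alternative bases); codons that become in-frame stops are
# reverted to the parental codon, so output stays stop-free if input was.
mutate_coding <- function(seq, m) {
  if (m <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(s)
  hit <- which(stats::runif(L) < m)
  if (!length(hit)) return(seq)
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  for (i in hit) {
    j <- sample.int(3, 1)
    s[i] <- substr(alt[[s[i]]], j, j)
  }
  # revert any codon that became a stop
  n_cod <- L %/% 3
  cod <- substring(paste(s, collapse = ""),
                   3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  bad <- which(cod %in% .MITO_STOPS)
  if (length(bad)) {
    old <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (b in bad) {
      idx <- (3 * b - 2):(3 * b)
      s[idx] <- old[idx]
    }
  }
  paste(s, collapse = "")
}

#' Simulate a hierarchical COI reference library
#'
#' Generates one clean coding fragment per specimen, with divergence tiers
#' realized on nested star topologies, plus a truth table. With the same
#' specs and seed the output is byte-identical across runs.
#'
#' @param taxonomy a [taxonomy_spec()].
#' @param divergence a [divergence_spec()].
#' @param seed integer; defaults to the seed stored in `divergence`.
#' @param outgroup logical; also emit one distant `role = "outgroup"` record.
#' @return a list with elements `records` (barcode record data.frame, with the
#'   divergence spec attached as attribute `"divergence"`) and `truth`
#'   (per-record truth table).
#' @export
simulate_library <- function(taxonomy = taxonomy_spec(),
                             divergence = divergence_spec(),
                             seed = divergence$seed, outgroup = TRUE) {
  stopifnot(inherits(taxonomy, "taxonomy_spec"),
            inherits(divergence, "divergence_spec"))
  tiers <- c(divergence$d_within_species, divergence$d_within_genus,
             divergence$d_within_family, divergence$d_between_family)
  # per-tier branch proportions; upper tiers are incremental over lower ones
  m_spec <- branch_m(tiers[1])
  m_sp_anc <- branch_m(tiers[2] - tiers[1])
  m_gen_anc <- branch_m(tiers[3] - tiers[2])
  m_fam_anc <- branch_m(tiers[4] - tiers[3])
  px <- taxonomy$name_prefixes

  with_seed(seed, {
    root <- random_coding_seq(divergence$seq_length)
    ids <- character(0); seqs <- character(0)
    fams <- character(0); gens <- character(0); sps <- character(0)
    anc <- list(root = root, family = character(0), genus = character(0),
                species = character(0))
    g_counter <- 0L
    for (f in seq_len(taxonomy$n_families)) {
      fam_name <- paste0(px[["family"]], f)
      fam_anc <- mutate_coding(root, m_fam_anc)
      anc$family[fam_name] <- fam_anc
      for (g in seq_len(taxonomy$genera_per_family)) {
        g_counter <- g_counter + 1L
        gen_name <- sprintf("%s%02d", px[["genus"]], g_counter)
        gen_anc <- mutate_coding(fam_anc, m_gen_anc)
        anc$genus[gen_name] <- gen_anc
        for (s in seq_len(taxonomy$species_per_genus)) {
          sp_name <- sprintf("%s_%s%d", gen_name, px[["species"]], s)
          sp_anc <- mutate_coding(gen_anc, m_sp_anc)
          anc$species[sp_name] <- sp_anc
          for (i in seq_len(taxonomy$specimens_per_species)) {
            ids <- c(ids, sprintf("%s_i%02d", sp_name, i))
            seqs <- c(seqs, mutate_coding(sp_anc, m_spec))
            fams <- c(fams, fam_name); gens <- c(gens, gen_name)
            sps <- c(sps, sp_name)
          }
        }
      }
    }
    role <- rep("reference", length(ids))
    if (outgroup) {
      ids <- c(ids, "Outgroup1")
      seqs <- c(seqs, mutate_coding(root, min(0.74, 2 * tiers[4])))
      fams <- c(fams, "OutFam"); gens <- c(gens, "OutGen")
      sps <- c(sps, "OutGen_sp1")
      role <- c(role, "outgroup")
    }
    records <- barcode_records(id = ids, sequence = seqs, family = fams,
                               genus = gens, species = sps, role = role)
    attr(records, "divergence") <- divergence
    attr(records, "ancestors") <- anc
    attr(records, "branch_m") <- c(specimen = m_spec, species = m_sp_anc,
                                   genus = m_gen_anc, family = m_fam_anc)
    truth <- data.frame(id = ids, family = fams, genus = gens, species = sps,
                        expected_rank = "species",
                        has_indel = FALSE, has_stop = FALSE,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Simulate query barcodes against a reference library
#'
#' Produces the three identification situations a barcoding survey meets:
#' conspecific queries (a new specimen of a library species, at the
#' within-species divergence from its conspecifics; expected rank
#' `species`), novel-species queries (a new lineage branching from a sampled
#' genus at the within-genus divergence; expected rank `genus`) and
#' novel-genus queries (a new lineage branching from a sampled family at the
#' within-family divergence; expected rank `family`). With a library from
#' [simulate_library()], novel lineages branch from the stored tier
#' ancestors, so they sit beside — never inside — existing species clusters;
#' for an external library they branch from a sampled specimen instead.
#'
#' @param library the `records` data.frame from [simulate_library()] (its
#'   `"divergence"` attribute supplies the tier targets), or any barcode
#'   record data.frame plus an explicit `divergence`.
#' @param n_conspecific,n_novel_species,n_novel_genus query counts.
#' @param seed integer seed.
#' @param divergence optional [divergence_spec()] override.
#' @return list with `records` (queries, role `"query"`, morphotype set to
#'   the true/nearest species name) and `truth` (truth table with
#'   `expected_rank` and the `source` taxon or specimen each query
#'   descends from).
#' @export
simulate_queries <- function(library, n_conspecific = 30,
                             n_novel_species = 15, n_novel_genus = 15,
                             seed = 1, divergence = NULL) {
  divergence <- divergence %||% attr(library, "divergence")
  if (is.null(divergence)) {
    stop("no divergence spec: pass `divergence` or a simulated library",
         call. = FALSE)
  }
  refs <- library[library$role == "reference", , drop = FALSE]
  if (!nrow(refs)) stop("library has no reference records", call. = FALSE)
  need_rank <- c(species = n_conspecific, genus = n_novel_species,
                 family = n_novel_genus)
  have <- c(species = sum(!is.na(refs$species)),
            genus = sum(!is.na(refs$genus)),
            family = sum(!is.na(refs$family)))
  if (any(need_rank > 0 & have == 0)) {
    stop("request exceeds available taxa: library lacks records with ",
         paste(names(which(need_rank > 0 & have == 0)), collapse = "/"),
         " labels", call. = FALSE)
  }
  anc <- attr(library, "ancestors")
  bm <- attr(library, "branch_m")
  tiers <- c(divergence$d_within_species, divergence$d_within_genus,
             divergence$d_within_family)

  with_seed(seed, {
    draw <- function(n, rank, novel_tag) {
      if (n < 1) return(NULL)
      rows <- refs[sample.int(nrow(refs), n, replace = TRUE), , drop = FALSE]
      if (!is.null(anc)) {
        # branch a fresh lineage off the stored tier ancestor. Conspecific
        # queries are ordinary extra specimens; novel lineages target the
        # midpoint of the two flanking tiers (so a novel species sits
        # between the within-species and within-family divergences of its
        # genus, a novel genus between within- and between-family). The
        # branch proportion `a` inverts the two-lineage expectation
        # p = a + b - (4/3)ab, with b the substitution depth of the
        # existing specimens below the shared ancestor.
        start <- switch(rank,
                        species = anc$species[rows$species],
                        genus = anc$genus[rows$genus],
                        family = anc$family[rows$family])
        solve_a <- function(t, b) max(0, (t - b) / (1 - 4 * b / 3))
        m <- switch(rank,
                    species = bm[["specimen"]],
                    genus = solve_a((tiers[1] + tiers[3]) / 2,
                                    1 - (1 - bm[["species"]]) *
                                      (1 - bm[["specimen"]])),
                    family = solve_a((tiers[3] +
                                        divergence$d_between_family) / 2,
                                     1 - (1 - bm[["genus"]]) *
                                       (1 - bm[["species"]]) *
                                       (1 - bm[["specimen"]])))
        src <- switch(rank, species = rows$species, genus = rows$genus,
                      family = rows$family)
      } else {
        start <- rows$sequence
        m <- switch(rank, species = tiers[1], genus = tiers[2],
                    family = tiers[3])
        src <- rows$id
      }
      qs <- vapply(start, mutate_coding, character(1), m = m,
                   USE.NAMES = FALSE)
      sp <- rows$species
      if (!is.null(novel_tag)) {
        sp <- sprintf("%s_%s%d",
                      if (novel_tag == "novelsp") rows$genus else rows$family,
                      novel_tag, seq_len(n))
      }
      data.frame(source = src, sequence = qs, family = rows$family,
                 genus = if (rank == "family") NA_character_ else rows$genus,
                 species = if (rank == "species") rows$species
                           else NA_character_,
                 morphotype = sp, expected_rank = rank,
                 stringsAsFactors = FALSE)
    }
    qdf <- rbind(
      draw(n_conspecific, "species", NULL),
      draw(n_novel_species, "genus", "novelsp"),
      draw(n_novel_genus, "family", "novelgen"))
    if (is.null(qdf)) stop("no queries requested", call. = FALSE)
    qdf$id <- sprintf("Q%03d", seq_len(nrow(qdf)))
    records <- barcode_records(id = qdf$id, sequence = qdf$sequence,
                               family = qdf$family, genus = qdf$genus,
                               species = qdf$species,
                               morphotype = qdf$morphotype, role = "query")
    attr(records, "divergence") <- divergence
    truth <- data.frame(id = qdf$id, family = qdf$family, genus = qdf$genus,
                        species = qdf$species,
                        morphotype = qdf$morphotype, source = qdf$source,
                        expected_rank = qdf$expected_rank,
                        has_indel = FALSE, has_stop = FALSE,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Inject QC artifacts (indels, in-frame stop codons) into barcode records
#'
#' Each record independently acquires, with probability `indel_rate`, a single
#' 1-base internal insertion or deletion (never a multiple of 3) and, with
#' probability `stop_rate`, one substitution converting an internal codon into
#' a vertebrate-mitochondrial stop. Used to exercise the QC stage against a
#' known truth table.
#'
#' @param records barcode record data.frame of clean coding sequences.
#' @param indel_rate,stop_rate per-record corruption probabilities in `[0,1]`.
#' @param seed integer seed.
#' @return list with `records` (corrupted) and `truth` (`id`, `has_indel`,
#'   `has_stop`).
#' @export
inject_artifacts <- function(records, indel_rate = 0, stop_rate = 0,
                             seed = 1) {
  if (indel_rate < 0 || indel_rate > 1 || stop_rate < 0 || stop_rate > 1) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  out <- records
  n <- nrow(records)
  with_seed(seed, {
    do_stop <- stats::runif(n) < stop_rate
    do_indel <- stats::runif(n) < indel_rate
    for (i in seq_len(n)) {
      s <- out$sequence[i]
      stop_bases <- integer(0)
      if (do_stop[i]) {
        st <- add_internal_stop(s)
        s <- st$seq
        stop_bases <- st$bases
      }
      if (do_indel[i]) {
        L <- nchar(s)
        # a deletion inside the planted stop codon would erase it, leaving
        # the truth flag undetectable; keep the two artifacts disjoint
        pos <- sample(setdiff(4:(L - 3), stop_bases), 1)
        if (stats::runif(1) < 0.5) {
          s <- paste0(substr(s, 1, pos - 1), substr(s, pos + 1, L))  # deletion
        } else {
          s <- paste0(substr(s, 1, pos), sample(c("A", "C", "G", "T"), 1),
                      substr(s, pos + 1, L))                        # insertion
        }
      }
      out$sequence[i] <- s
    }
    truth <- data.frame(id = records$id, has_indel = do_indel,
                        has_stop = do_stop, stringsAsFactors = FALSE)
    list(records = out, truth = truth)
  })
}

# One substitution turning an internal (non-terminal) frame-0 codon into a
# stop codon; falls back to overwriting a codon wholesale if no codon is a
# single substitution away from a stop. Returns the mutated sequence and the
# base positions of the affected codon.
add_internal_stop <- function(seq) {
  n_cod <- nchar(seq) %/% 3
  internal <- 2:(n_cod - 1)
  cods <- substring(seq, 3 * internal - 2, 3 * internal)
  cand <- list()
  for (k in seq_along(cods)) {
    for (st in .MITO_STOPS) {
      diffpos <- which(strsplit(cods[k], "")[[1]] != strsplit(st, "")[[1]])
      if (length(diffpos) == 1L) {
        cand[[length(cand) + 1L]] <- c(internal[k], match(st, .MITO_STOPS),
                                       diffpos)
      }
    }
  }
  if (length(cand)) {
    pick <- cand[[sample.int(length(cand), 1)]]
    cod_i <- pick[1]; st <- .MITO_STOPS[pick[2]]
    idx <- 3 * cod_i - 3 + pick[3]
    out <- paste0(substr(seq, 1, idx - 1), substr(st, pick[3], pick[3]),
                  substr(seq, idx + 1, nchar(seq)))
  } else {
    cod_i <- sample(internal, 1)
    out <- paste0(substr(seq, 1, 3 * cod_i - 3), sample(.MITO_STOPS, 1),
                  substr(seq, 3 * cod_i + 1, nchar(seq)))
  }
  list(seq = out, bases = (3 * cod_i - 2):(3 * cod_i))
}
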