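#' Read protein records from a UniProt-style FASTA file
#'
#' Parses FASTA with UniProt headers of the form
#' `>sp|ACCESSION|NAME Description OS=Organism OX=... GN=Gene ...` into a
#' record tibble. The database tag (`sp` = Swiss-Prot, `tr` = TrEMBL) sets
#' the `reviewed` flag. FASTA headers carry no taxonomic lineage, so the
#' `lineage` list-column is empty for every record; use
#' [read_uniprot_tab()] (or supply lineage yourself) when group filtering
#' by lineage is required.
#'
#' @param path Path to a FASTA file.
#' @return A record tibble with columns `accession` (character),
#'   `reviewed` (logical), `gene_names` (list of character vectors),
#'   `organism` (character), `lineage` (list of character vectors),
#'   `description` (character), `sequence` (character, uppercase).
#' @export
read_uniprot_fasta <- function(path) {
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    return(empty_records())
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    return(empty_records())
  }
  headers <- names(seqs)
  parsed <- purrr::map(headers, parse_uniprot_header)
  records <- dplyr::bind_rows(parsed)
  records$sequence <- unname(toupper(as.character(seqs)))
  validate_records(records)
}

parse_uniprot_header <- function(header) {
  m <- stringr::str_match(header, "^(sp|tr)\\|([^|]+)\\|(\\S+)\\s*(.*)$")
  if (is.na(m[1, 1])) {
    # Plain header: treat the first token as the accession, unreviewed.
    acc <- stringr::str_split_1(header, "\\s+")[1]
    if (!nzchar(acc)) abort(paste0("Malformed FASTA header: '", header, "'"))
    rest <- stringr::str_trim(stringr::str_remove(header, stringr::fixed(acc)))
    reviewed <- FALSE
    entry_name <- acc
  } else {
    reviewed <- m[1, 2] == "sp"
    acc <- m[1, 3]
    entry_name <- m[1, 4]
    rest <- m[1, 5]
  }
  os <- stringr::str_match(rest, "OS=(.*?)(?:\\s+[A-Z]{2}=|$)")[, 2]
  gn <- stringr::str_match(rest, "GN=(\\S+)")[, 2]
  desc <- stringr::str_trim(stringr::str_match(rest, "^(.*?)(?:\\s+OS=.*)?$")[, 2])
  tibble(
    accession = acc,
    entry_name = entry_name,
    reviewed = reviewed,
    gene_names = list(if (is.na(gn)) character() else gn),
    organism = ifelse(is.na(os), NA_character_, os),
    lineage = list(character()),
    description = ifelse(is.na(desc), "", desc)
  )
}

#' Read protein records from a UniProt tab-separated export
#'
#' Expects named columns `accession`, `reviewed`, `gene_names`, `organism`,
#' `lineage`, `protein_name` and `sequence`. `reviewed` may be logical or
#' the UniProt strings `"reviewed"`/`"unreviewed"`; `gene_names` is split
#' on whitespace and semicolons; `lineage` is split on commas with order
#' preserved (most-general taxon first, as UniProt exports it).
#'
#' @param path Path to a TSV file.
#' @return A record tibble (see [read_uniprot_fasta()] for columns).
#' @export
read_uniprot_tab <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("accession", "reviewed", "gene_names", "organism", "lineage",
              "protein_name", "sequence")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Tabular export is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  records <- tibble(
    accession = tab$accession,
    entry_name = tab$accession,
    reviewed = tolower(tab$reviewed) %in% c("true", "reviewed", "yes", "1"),
    gene_names = stringr::str_split(dplyr::coalesce(tab$gene_names, ""), "[;\\s]+") |>
      purrr::map(~ .x[nzchar(.x)]),
    organism = tab$organism,
    lineage = stringr::str_split(dplyr::coalesce(tab$lineage, ""), ",\\s*") |>
      purrr::map(~ .x[nzchar(.x)]),
    description = dplyr::coalesce(tab$protein_name, ""),
    sequence = toupper(tab$sequence)
  )
  validate_records(records)
}

empty_records <- function() {
  tibble(
    accession = character(), entry_name = character(), reviewed = logical(),
    gene_names = list(), organism = character(), lineage = list(),
    description = character(), sequence = character()
  )
}

validate_records <- function(records) {
  if (nrow(records) == 0) return(records)
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate accession(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(records$accession) | !nzchar(records$accession))) {
    abort("Every record needs a non-empty accession.")
  }
  if (any(!nzchar(records$sequence))) {
    bad <- records$accession[!nzchar(records$sequence)]
    abort(paste0("Empty sequence for: ", paste(bad, collapse = ", ")))
  }
  bad_chars <- stringr::str_remove_all(records$sequence,
                                       paste0("[", paste(AA_EXTENDED, collapse = ""), "]"))
  if (any(nzchar(bad_chars))) {
    bad <- records$accession[nzchar(bad_chars)]
    abort(paste0("Sequence contains non-amino-acid symbols for: ",
                 paste(bad, collapse = ", ")))
  }
  records
}

#' Define a homologous-group selection rule
#'
#' A rule selects records whose taxonomic lineage contains one required
#' taxon, whose gene names (any synonym) intersect an accepted set
#' (case-sensitive exact match; skipped when the set is empty), and whose
#' description contains none of the exclusion words (case-insensitive
#' substring).
#'
#' @param name Group identifier.
#' @param lineage_taxon Required taxon name, e.g. `"Eutheria"`.
#' @param gene_names Accepted gene names, e.g. `c("PRM1", "Prm1")`; empty
#'   means any gene name.
#' @param description_excludes Words whose presence in the description
#'   excludes a record, e.g. `"like"`.
#' @param dedupe_per_organism Whether [dedupe_per_organism()] applies to
#'   this group (one entry per organism, reviewed preferred).
#' @return A `group_rule` object.
#' @export
group_rule <- function(name, lineage_taxon, gene_names = character(),
                       description_excludes = character(),
                       dedupe_per_organism = TRUE) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(lineage_taxon), length(lineage_taxon) == 1)
  structure(
    list(name = name, lineage_taxon = lineage_taxon,
         gene_names = gene_names,
         description_excludes = description_excludes,
         dedupe_per_organism = isTRUE(dedupe_per_organism)),
    class = "group_rule"
  )
}

#' @export
print.group_rule <- function(x, ...) {
  cat("<group_rule>", x$name, "\n")
  cat("  lineage contains:", x$lineage_taxon, "\n")
  if (length(x$gene_names) > 0)
    cat("  gene name in: {", paste(x$gene_names, collapse = ", "), "}\n")
  if (length(x$description_excludes) > 0)
    cat("  description excludes:", paste(x$description_excludes, collapse = ", "), "\n")
  cat("  one entry per organism:", x$dedupe_per_organism, "\n")
  invisible(x)
}

#' The four protamine group rules
#'
#' The standard homologous protamine groups: eutherian P1 (lineage contains
#' Eutheria, gene PRM1/Prm1), eutherian P2 (Eutheria, PRM2/Prm2),
#' metatherian P1 (Metatheria, PRM1/Prm1) and fish protamines
#' (Actinopterygii, any gene name, description must not contain "like" —
#' dropping protamine-like proteins). Fish groups may keep several genes
#' per species, so per-organism deduplication is off for that rule.
#'
#' @return A named list of [group_rule()] objects.
#' @export
protamine_rules <- function() {
  list(
    eutherian_p1 = group_rule("eutherian_p1", "Eutheria", c("PRM1", "Prm1")),
    eutherian_p2 = group_rule("eutherian_p2", "Eutheria", c("PRM2", "Prm2")),
    metatherian_p1 = group_rule("metatherian_p1", "Metatheria", c("PRM1", "Prm1")),
    fish = group_rule("fish", "Actinopterygii", character(),
                      description_excludes = "like",
                      dedupe_per_organism = FALSE)
  )
}

rule_predicate <- function(records, rule) {
  in_lineage <- purrr::map_lgl(records$lineage, ~ rule$lineage_taxon %in% .x)
  gene_ok <- if (length(rule$gene_names) == 0) {
    rep(TRUE, nrow(records))
  } else {
    purrr::map_lgl(records$gene_names, ~ length(intersect(.x, rule$gene_names)) > 0)
  }
  desc_ok <- if (length(rule$description_excludes) == 0) {
    rep(TRUE, nrow(records))
  } else {
    !purrr::reduce(
      purrr::map(rule$description_excludes,
                 ~ stringr::str_detect(tolower(records$description),
                                       stringr::fixed(tolower(.x)))),
      `|`
    )
  }
  in_lineage & gene_ok & desc_ok
}

#' Select the members of a homologous group
#'
#' Applies a [group_rule()] to a record tibble, keeping input order. The
#' result carries a `provenance` attribute with the rule and the record
#' counts before and after filtering. Filtering is idempotent and an empty
#' result is valid.
#'
#' @param records A record tibble (see [read_uniprot_fasta()]).
#' @param rule A [group_rule()].
#' @return The filtered record tibble with attributes `group_name` and
#'   `provenance`.
#' @export
filter_group <- function(records, rule) {
  stopifnot(inherits(rule, "group_rule"))
  keep <- rule_predicate(records, rule)
  out <- records[keep, , drop = FALSE]
  attr(out, "group_name") <- rule$name
  attr(out, "rule") <- rule
  attr(out, "provenance") <- add_provenance(
    attr(records, "provenance"),
    step = paste0("filter_group:", rule$name),
    n_in = nrow(records), n_out = nrow(out)
  )
  out
}

add_provenance <- function(prov, step, n_in, n_out, note = NA_character_) {
  new <- tibble(step = step, n_in = n_in, n_out = n_out, note = note)
  if (is.null(prov)) new else dplyr::bind_rows(prov, new)
}

#' Keep one entry per organism, preferring reviewed entries
#'
#' Within each organism, a reviewed (Swiss-Prot) entry wins over unreviewed
#' (TrEMBL) ones; among equally reviewed candidates, the lexicographically
#' smallest accession is kept, which makes the result independent of the
#' input row order. Retained entries keep their original relative order.
#'
#' @param group A record tibble, typically from [filter_group()].
#' @return The deduplicated record tibble with updated provenance.
#' @export
dedupe_per_organism <- function(group) {
  if (nrow(group) == 0) return(group)
  winners <- group |>
    dplyr::mutate(.orig = dplyr::row_number()) |>
    dplyr::group_by(.data$organism) |>
    dplyr::arrange(dplyr::desc(.data$reviewed), .data$accession, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.orig) |>
    dplyr::select(-".orig")
  out <- winners
  for (a in c("group_name", "rule")) attr(out, a) <- attr(group, a)
  attr(out, "provenance") <- add_provenance(
    attr(group, "provenance"), "dedupe_per_organism",
    n_in = nrow(group), n_out = nrow(out)
  )
  out
}

#' Remove named members from a group
#'
#' Drops entries whose organism or accession matches the exclusion list —
#' used, for example, to remove aberrant P2 sequences that would distort an
#' alignment, or known pseudogenes. An exclusion that matches nothing
#' raises a warning, not an error.
#'
#' @param group A record tibble.
#' @param exclusions Character vector of organisms and/or accessions.
#' @param reason Free-text reason recorded in provenance.
#' @return The reduced record tibble with updated provenance.
#' @export
remove_members <- function(group, exclusions, reason = "manual exclusion") {
  if (length(exclusions) == 0) return(group)
  hit <- group$organism %in% exclusions | group$accession %in% exclusions
  unmatched <- setdiff(exclusions, c(group$organism, group$accession))
  if (length(unmatched) > 0) {
    warn(paste0("Exclusion(s) matched no member: ",
                paste(unmatched, collapse = ", ")))
  }
  out <- group[!hit, , drop = FALSE]
  for (a in c("group_name", "rule")) attr(out, a) <- attr(group, a)
  attr(out, "provenance") <- add_provenance(
    attr(group, "provenance"), "remove_members",
    n_in = nrow(group), n_out = nrow(out),
    note = paste0(reason, " (removed ", sum(hit), ")")
  )
  out
}

#' Write a group of sequences to FASTA
#'
#' @param records A record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(setNames(records$sequence, records$accession))
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}
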