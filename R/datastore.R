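#' Build the cross-linked protein/peptide/epitope datastore
#'
#' Runs every workflow on every protein, deduplicates peptides by sequence,
#' annotates each peptide with its average, monoisotopic and
#' singly-protonated monoisotopic masses and its unrecognized-residue count
#' (#UA), maps the epitopes onto both proteins and peptides, and assembles
#' the six cross-keyed tables: `proteins`, `peptides`, `epitopes`,
#' `digestion_events`, `protein_epitope_matches`, `peptide_epitope_matches`.
#'
#' Rebuilds are deterministic: identical inputs give byte-identical tables
#' (ids are content hashes; metadata records input checksums and the active
#' rule-set identity, but no wall-clock timestamp).
#'
#' @param proteins Protein data.frame (`accession`, `sequence`, optional
#'   annotation columns `protein_type`, `organism`, `genotype`, `genome`,
#'   `chromosome`, `allele`, `gene_ids`).
#' @param epitopes Optional epitope data.frame (see [read_epitope_table()]).
#' @param workflows Workflows to run; default the 15-workflow panel.
#' @param rules An [enzyme_rules()] table.
#' @param masses A [mass_table()].
#' @return A `peptide_datastore` object (list of data.frames + `metadata`).
#' @examples
#' p <- data.frame(accession = "P1", sequence = "PQPQPFPKPQPQLPYPQ")
#' ds <- build_datastore(p, workflows = list("TR"))
#' ds$peptides$sequence
#' @export
build_datastore <- function(proteins, epitopes = NULL,
                            workflows = default_workflows(),
                            rules = enzyme_rules(), masses = mass_table()) {
  proteins <- as_protein_table(proteins)
  if (is.null(epitopes)) {
    epitopes <- empty_epitope_table()
  } else {
    epitopes <- validate_epitopes(epitopes)
  }
  workflows <- lapply(workflows, function(w)
    if (is.character(w)) parse_workflow(w) else w)

  events <- digest_all(proteins, workflows, rules)

  seqs <- sort(unique(events$peptide_sequence))
  peptides <- data.frame(
    peptide_id = if (length(seqs)) peptide_id_for(seqs) else character(0),
    sequence = seqs, length = nchar(seqs), stringsAsFactors = FALSE)
  if (anyDuplicated(peptides$peptide_id)) {
    # hash collision: disambiguate deterministically in sequence sort order
    dup <- duplicated(peptides$peptide_id)
    peptides$peptide_id[dup] <- paste0(peptides$peptide_id[dup], "-",
                                       cumsum(dup)[dup] + 1L)
  }
  if (nrow(peptides) > 0) {
    peptides$average_mass <- average_mass(peptides$sequence, masses)
    peptides$monoisotopic_mass <- monoisotopic_mass(peptides$sequence, masses)
    peptides$protonated_monoisotopic_mass <-
      protonated_mass(peptides$sequence, masses)
    peptides$unrecognized_count <- count_unrecognized(peptides$sequence)
  } else {
    peptides$average_mass <- numeric(0)
    peptides$monoisotopic_mass <- numeric(0)
    peptides$protonated_monoisotopic_mass <- numeric(0)
    peptides$unrecognized_count <- integer(0)
  }

  ds <- structure(list(
    proteins = proteins,
    peptides = peptides,
    epitopes = epitopes,
    digestion_events = events,
    protein_epitope_matches = match_epitopes_to_proteins(epitopes, proteins),
    peptide_epitope_matches = match_epitopes_to_peptides(epitopes, peptides),
    metadata = list(
      rule_set = attr(rules, "rule_set") %||% "custom",
      mass_set = attr(masses, "mass_set") %||% "custom",
      workflows = vapply(workflows, format, character(1)),
      input_checksum = fnv1a32(paste(
        paste(proteins$accession, proteins$sequence, collapse = ";"),
        paste(epitopes$epitope_id, epitopes$sequence, collapse = ";"),
        sep = "#"))
    )), class = "peptide_datastore")
  validate_datastore(ds)
  ds
}

# Referential integrity: every foreign id resolves.
validate_datastore <- function(ds) {
  stopifnot(all(ds$digestion_events$protein_accession %in% ds$proteins$accession))
  stopifnot(all(ds$protein_epitope_matches$target_id %in% ds$proteins$accession))
  stopifnot(all(ds$peptide_epitope_matches$target_id %in% ds$peptides$peptide_id))
  stopifnot(all(ds$protein_epitope_matches$epitope_id %in% ds$epitopes$epitope_id))
  stopifnot(!anyDuplicated(ds$peptides$sequence))
  stopifnot(!anyDuplicated(ds$digestion_events$event_id))
  invisible(ds)
}

#' @export
print.peptide_datastore <- function(x, ...) {
  cat("<peptide datastore>\n")
  cat(sprintf("  proteins: %d   peptides: %d   epitopes: %d\n",
              nrow(x$proteins), nrow(x$peptides), nrow(x$epitopes)))
  cat(sprintf("  digestion events: %d   (workflows: %d, rule set: %s)\n",
              nrow(x$digestion_events), length(x$metadata$workflows),
              x$metadata$rule_set))
  cat(sprintf("  epitope matches: %d on proteins, %d on peptides\n",
              nrow(x$protein_epitope_matches), nrow(x$peptide_epitope_matches)))
  invisible(x)
}

#' Chained column filtering
#'
#' Applies an ordered list of conjunctive column filters (the step-by-step
#' narrowing used interactively: organism, then disease, then cell type, then
#' protein type ...).  Each filter is `list(column =, value =, exact =)`;
#' the default is case-insensitive substring matching, `exact = TRUE` is
#' exact equality.  The row count after each step is recorded in
#' `attr(, "step_counts")`, mirroring the running entry count of a query UI.
#'
#' @param table A data.frame (any datastore table, possibly pre-joined).
#' @param filters List of filters as above.
#' @return The filtered data.frame, with `step_counts` attribute.
#' @examples
#' df <- data.frame(organism = c("Triticum urartu", "Hordeum vulgare"),
#'                  protein_type = c("alpha gliadin", "B-hordein"))
#' attr(filter_chain(df, list(list(column = "organism", value = "triticum"))),
#'      "step_counts")
#' @export
filter_chain <- function(table, filters = list()) {
  counts <- integer(0)
  for (f in filters) {
    col <- f$column
    if (is.null(col) || !col %in% names(table)) {
      stop("unknown filter column: ", col %||% "<missing>", call. = FALSE)
    }
    values <- as.character(table[[col]])
    keep <- if (isTRUE(f$exact)) {
      values == as.character(f$value)
    } else {
      grepl(tolower(as.character(f$value)), tolower(values), fixed = TRUE)
    }
    table <- table[keep, , drop = FALSE]
    counts <- c(counts, stats::setNames(nrow(table), col))
  }
  attr(table, "step_counts") <- counts
  table
}

#' Search peptides by singly-protonated monoisotopic mass
#'
#' Default mode `"display"` reproduces typing a value into the [M+H]+ search
#' box: both the stored mass and the query are rounded to 4 decimals and
#' compared exactly.  `"absolute"` keeps peptides within `tolerance` Da,
#' `"ppm"` within `tolerance` parts per million.  Peptides with undefined
#' masses (#UA > 0 or other unmassed letters) never match.
#'
#' @param ds A `peptide_datastore`.
#' @param query_mass Query mass in Da.
#' @param mode `"display"`, `"absolute"` or `"ppm"`.
#' @param tolerance Tolerance for the non-display modes (Da or ppm).
#' @return Subset of `ds$peptides`.
#' @export
mass_search <- function(ds, query_mass,
                        mode = c("display", "absolute", "ppm"),
                        tolerance = 0) {
  mode <- match.arg(mode)
  if (tolerance < 0) stop("negative tolerance", call. = FALSE)
  mz <- ds$peptides$protonated_monoisotopic_mass
  keep <- switch(mode,
    display = !is.na(mz) & display_mass(mz) == display_mass(query_mass),
    absolute = !is.na(mz) & abs(mz - query_mass) <= tolerance,
    ppm = !is.na(mz) & abs(mz - query_mass) <= query_mass * tolerance / 1e6)
  ds$peptides[keep, , drop = FALSE]
}

#' Peptide specificity summary
#'
#' For one peptide sequence, one row per workflow that yields it as a final
#' digestion product: the number of distinct source proteins, the maximum
#' copy number within a single protein (distinct start positions), and the
#' numbers of distinct species, protein types and genotypes carrying it --
#' the counts that tell how specific a detected mass/peptide is for a
#' species or protein type.
#'
#' @param ds A `peptide_datastore`.
#' @param peptide_sequence Peptide sequence present in the datastore.
#' @return data.frame with columns `peptide_sequence`, `workflow_id`,
#'   `n_proteins`, `n_peptides_in_protein`, `n_species`, `n_types`,
#'   `n_genotypes`.
#' @export
peptide_specificity_summary <- function(ds, peptide_sequence) {
  peptide_sequence <- normalize_sequence(peptide_sequence)
  if (!peptide_sequence %in% ds$peptides$sequence) {
    stop("unknown peptide: ", peptide_sequence, call. = FALSE)
  }
  ev <- ds$digestion_events
  ev <- ev[ev$peptide_sequence == peptide_sequence, , drop = FALSE]
  out <- list()
  for (wf in sort(unique(ev$workflow_id))) {
    final_level <- length(parse_workflow(wf)$steps) - 1L
    sub <- ev[ev$workflow_id == wf & ev$level == final_level, , drop = FALSE]
    occ <- unique(sub[, c("protein_accession", "start")])
    if (nrow(occ) == 0) next  # intermediate only: cut further in step 2
    prot <- ds$proteins[ds$proteins$accession %in% occ$protein_accession, ,
                        drop = FALSE]
    nz <- function(x) length(unique(x[nzchar(x)]))
    out[[length(out) + 1]] <- data.frame(
      peptide_sequence = peptide_sequence, workflow_id = wf,
      n_proteins = length(unique(occ$protein_accession)),
      n_peptides_in_protein = max(table(occ$protein_accession)),
      n_species = nz(prot$organism), n_types = nz(prot$protein_type),
      n_genotypes = nz(prot$genotype), stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(peptide_sequence = character(0),
                      workflow_id = character(0), n_proteins = integer(0),
                      n_peptides_in_protein = integer(0),
                      n_species = integer(0), n_types = integer(0),
                      n_genotypes = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# digestion events joined with their protein annotations (query-time join).
events_with_proteins <- function(ds) {
  idx <- match(ds$digestion_events$protein_accession, ds$proteins$accession)
  cbind(ds$digestion_events,
        ds$proteins[idx, setdiff(PROTEIN_COLUMNS, c("accession", "sequence")),
                    drop = FALSE],
        row.names = NULL)
}

#' Grouped peptide count matrix
#'
#' Cross-tabulates digestion events (default) or unique peptide sequences
#' (`unique_peptides = TRUE`) by two grouping columns -- typically protein
#' type by workflow -- with row/column/grand-total margins.  `filters`
#' restricts scope via [filter_chain()] first; cells absent from the scope
#' are zero, and matrix dimensions are taken from the full datastore so an
#' empty scope yields an all-zero matrix.
#'
#' @param ds A `peptide_datastore`.
#' @param rows,cols Grouping column names (event or protein-annotation
#'   columns, e.g. `"protein_type"`, `"workflow_id"`, `"organism"`).
#' @param filters Optional filter list as in [filter_chain()].
#' @param unique_peptides Count distinct peptide sequences per cell instead
#'   of digestion events.
#' @return Integer matrix with `Sum` margins ([stats::addmargins()]).
#' @export
peptide_count_matrix <- function(ds, rows = "protein_type",
                                 cols = "workflow_id", filters = NULL,
                                 unique_peptides = FALSE) {
  base <- events_with_proteins(ds)
  for (col in c(rows, cols)) {
    if (!col %in% names(base)) stop("unknown grouping column: ", col,
                                    call. = FALSE)
  }
  row_levels <- sort(unique(as.character(base[[rows]])))
  col_levels <- sort(unique(as.character(base[[cols]])))
  scoped <- if (length(filters)) filter_chain(base, filters) else base
  if (unique_peptides) {
    scoped <- scoped[!duplicated(scoped[, c(rows, cols, "peptide_sequence")]), ,
                     drop = FALSE]
  }
  tab <- table(factor(scoped[[rows]], levels = row_levels),
               factor(scoped[[cols]], levels = col_levels))
  names(dimnames(tab)) <- c(rows, cols)
  out <- stats::addmargins(tab)
  storage.mode(out) <- "integer"
  out
}

#' Normalized epitope density per group
#'
#' For each group (by default protein type crossed with genome), the number
#' of epitope match rows passing the filter divided by the number of
#' distinct proteins in the group with at least one passing match.  This
#' normalization removes the bias from unequal numbers of deposited
#' sequences per protein type; groups with no matching protein are absent
#' from the result (not 0/0).  Without expression levels it is a prevalence
#' measure, not an allergenicity score.
#'
#' @param ds A `peptide_datastore`.
#' @param group_by Protein-annotation columns defining the groups.
#' @param cell_type Optional exact filter on epitope cell type
#'   (`"T cell"`/`"B cell"`).
#' @param disease Optional case-insensitive substring filter on disease.
#' @param core_only Keep only core epitopes.
#' @param distinct_epitopes Count distinct epitopes instead of match rows.
#' @return data.frame: group columns, `n_matches`, `n_proteins`, `density`.
#' @export
epitope_density <- function(ds, group_by = c("protein_type", "genome"),
                            cell_type = NULL, disease = NULL,
                            core_only = FALSE, distinct_epitopes = FALSE) {
  m <- ds$protein_epitope_matches
  if (nrow(m) == 0) {
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(group_by))), group_by)
    out$n_matches <- integer(0); out$n_proteins <- integer(0)
    out$density <- numeric(0)
    return(out)
  }
  ei <- match(m$epitope_id, ds$epitopes$epitope_id)
  pi <- match(m$target_id, ds$proteins$accession)
  keep <- rep(TRUE, nrow(m))
  if (!is.null(cell_type)) keep <- keep & ds$epitopes$cell_type[ei] == cell_type
  if (!is.null(disease)) {
    keep <- keep & grepl(tolower(disease), tolower(ds$epitopes$disease[ei]),
                         fixed = TRUE)
  }
  if (core_only) keep <- keep & ds$epitopes$is_core[ei]
  m <- m[keep, , drop = FALSE]; pi <- pi[keep]
  if (nrow(m) == 0) {
    return(epitope_density(structure(list(
      protein_epitope_matches = empty_match_table(), epitopes = ds$epitopes,
      proteins = ds$proteins), class = "peptide_datastore"),
      group_by = group_by))
  }
  for (col in group_by) {
    if (!col %in% names(ds$proteins)) stop("unknown grouping column: ", col,
                                           call. = FALSE)
  }
  key <- do.call(paste, c(lapply(group_by, function(col)
    ds$proteins[[col]][pi]), sep = "\r"))
  split_idx <- split(seq_len(nrow(m)), key)
  rows <- lapply(names(split_idx), function(k) {
    idx <- split_idx[[k]]
    vals <- strsplit(k, "\r", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad back
    vals <- c(vals, rep("", length(group_by) - length(vals)))
    grp <- stats::setNames(as.list(vals), group_by)
    n_matches <- if (distinct_epitopes) {
      length(unique(m$epitope_id[idx]))
    } else {
      length(idx)
    }
    n_prot <- length(unique(m$target_id[idx]))
    data.frame(grp, n_matches = n_matches, n_proteins = n_prot,
               density = n_matches / n_prot, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[do.call(order, out[group_by]), , drop = FALSE]
}

#' Export a table as CSV
#'
#' RFC-4180-style CSV: header row, UTF-8, all character fields quoted,
#' stable column order, missing numbers written empty.  Round-trips through
#' [read_csv_table()].
#'
#' @param table A data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-import a CSV written by [export_csv()]
#'
#' @param path CSV file path.
#' @return data.frame (character columns stay character, empty numeric
#'   fields become `NA`).
#' @export
read_csv_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

DATASTORE_TABLES <- c("proteins", "peptides", "epitopes", "digestion_events",
                      "protein_epitope_matches", "peptide_epitope_matches")

#' Serialize a datastore to a directory of CSVs
#'
#' Writes the six tables plus a `metadata.dcf` provenance block (rule set,
#' mass set, workflow panel, input checksum).  Deterministic: rebuilding
#' from identical inputs and re-exporting gives byte-identical files.
#'
#' @param ds A `peptide_datastore`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_datastore <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in DATASTORE_TABLES) {
    export_csv(ds[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  meta <- ds$metadata
  meta$workflows <- paste(meta$workflows, collapse = ",")
  write.dcf(as.data.frame(meta, stringsAsFactors = FALSE),
            file.path(dir, "metadata.dcf"))
  invisible(dir)
}

#' Load a datastore serialized by [export_datastore()]
#'
#' @param dir Directory written by [export_datastore()].
#' @return A `peptide_datastore`.
#' @export
read_datastore <- function(dir) {
  ds <- lapply(stats::setNames(DATASTORE_TABLES, DATASTORE_TABLES),
               function(tb) {
    df <- read_csv_table(file.path(dir, paste0(tb, ".csv")))
    # all-empty character columns read back as logical NA; restore ""
    for (col in names(df)) {
      if (is.logical(df[[col]]) && all(is.na(df[[col]])) && col != "is_core") {
        df[[col]] <- rep("", nrow(df))
      }
    }
    df
  })
  meta <- as.list(read.dcf(file.path(dir, "metadata.dcf"))[1, ])
  meta$workflows <- strsplit(meta$workflows, ",", fixed = TRUE)[[1]]
  ds$metadata <- meta
  structure(ds, class = "peptide_datastore")
}
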