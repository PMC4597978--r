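EPITOPE_COLUMNS <- c("epitope_id", "name", "sequence", "cell_type", "is_core",
                     "disease", "antibody", "mhc_serotype", "host")

empty_epitope_table <- function() {
  df <- data.frame(epitope_id = character(0), name = character(0),
                   sequence = character(0), cell_type = character(0),
                   is_core = logical(0), disease = character(0),
                   antibody = character(0), mhc_serotype = character(0),
                   host = character(0), stringsAsFactors = FALSE)
  df
}

#' Validate an epitope table
#'
#' Enforces the epitope-record invariants: `epitope_id` unique and
#' non-empty, sequences non-empty over the standard residue letters,
#' `cell_type` one of `"T cell"`/`"B cell"`, and the core flag allowed only
#' on nine-residue T-cell (celiac-register) epitopes.  Missing optional
#' columns (`name`, `disease`, `antibody`, `mhc_serotype`, `host`) are
#' filled with empty strings; `is_core` defaults to `FALSE`.
#'
#' @param epitopes data.frame with at least `epitope_id`, `sequence`,
#'   `cell_type`.
#' @return The normalized epitope data.frame (stable column order).
#' @export
validate_epitopes <- function(epitopes) {
  required <- c("epitope_id", "sequence", "cell_type")
  missing <- setdiff(required, names(epitopes))
  if (length(missing) > 0) {
    stop("epitope table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  epitopes$epitope_id <- as.character(epitopes$epitope_id)
  if (any(!nzchar(epitopes$epitope_id)) || anyDuplicated(epitopes$epitope_id)) {
    stop("epitope_id must be unique and non-empty", call. = FALSE)
  }
  epitopes$sequence <- normalize_sequence(epitopes$sequence)
  if (any(!nzchar(epitopes$sequence))) stop("empty epitope sequence",
                                            call. = FALSE)
  bad <- !grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"),
                epitopes$sequence)
  if (any(bad)) {
    stop("epitope sequence with non-standard residue letters: ",
         paste(epitopes$epitope_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(epitopes$cell_type %in% c("T cell", "B cell"))) {
    stop("cell_type must be 'T cell' or 'B cell'", call. = FALSE)
  }
  if (!"is_core" %in% names(epitopes)) epitopes$is_core <- FALSE
  if (is.character(epitopes$is_core)) {
    epitopes$is_core <- toupper(trimws(epitopes$is_core)) %in%
      c("TRUE", "T", "1", "YES")
  }
  offending <- epitopes$is_core &
    !(epitopes$cell_type == "T cell" & nchar(epitopes$sequence) == 9)
  if (any(offending)) {
    stop("core flag is only valid for nine-residue T-cell epitopes: ",
         paste(epitopes$epitope_id[offending], collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(EPITOPE_COLUMNS, names(epitopes))) epitopes[[col]] <- ""
  epitopes[, EPITOPE_COLUMNS, drop = FALSE]
}

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of the header;
#' annotation columns are left empty for a later join with
#' [read_annotation_table()].  Duplicate accessions are an error.
#'
#' @param path FASTA file of amino-acid sequences (may contain `X`).
#' @return Protein data.frame in the standard schema.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA: ", path, call. = FALSE)
  accession <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (any(is.na(accession)) || any(!nzchar(accession))) {
    stop("malformed FASTA header", call. = FALSE)
  }
  as_protein_table(data.frame(accession = accession,
                              sequence = as.character(set),
                              stringsAsFactors = FALSE))
}

#' Read a protein annotation table
#'
#' Delimited text (comma or tab, sniffed from the header) keyed by
#' `accession`, carrying any of `protein_type`, `organism`, `genotype`,
#' `genome`, `chromosome`, `allele`, `gene_ids`.  Empty cells are kept as
#' empty strings.
#'
#' @param path Annotation file path.
#' @return data.frame keyed by accession.
#' @export
read_annotation_table <- function(path) {
  df <- read_delim_auto(path, colClasses = "character")
  if (!"accession" %in% names(df)) {
    stop("annotation table lacks 'accession' column", call. = FALSE)
  }
  keep <- intersect(c("accession",
                      setdiff(PROTEIN_COLUMNS, c("sequence", "length"))),
                    names(df))
  df <- df[, keep, drop = FALSE]
  if (anyDuplicated(df$accession)) {
    stop("duplicate accession in annotation table", call. = FALSE)
  }
  df
}

#' Join annotations onto a protein table
#'
#' Left join by accession; annotation rows whose accession is absent from
#' the protein table produce a warning (curation tables often lag the
#' sequence set) but are not fatal.
#'
#' @param proteins Protein data.frame ([read_fasta()] output).
#' @param annotations [read_annotation_table()] output.
#' @return Annotated protein data.frame.
#' @export
annotate_proteins <- function(proteins, annotations) {
  proteins <- as_protein_table(proteins)
  unknown <- setdiff(annotations$accession, proteins$accession)
  if (length(unknown) > 0) {
    warning("annotation rows with no matching protein: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(proteins$accession, annotations$accession)
  for (col in setdiff(names(annotations), "accession")) {
    vals <- annotations[[col]][idx]
    vals[is.na(vals)] <- ""
    has <- nzchar(vals)
    proteins[[col]][has] <- vals[has]
  }
  proteins
}

#' Read an epitope table
#'
#' Delimited text (comma or tab) with columns `epitope_id`, `sequence`,
#' `cell_type` and optionally `name`, `is_core`, `disease`, `antibody`,
#' `mhc_serotype`, `host`; validated with [validate_epitopes()].
#'
#' @param path Epitope file path.
#' @return Normalized epitope data.frame.
#' @export
read_epitope_table <- function(path) {
  validate_epitopes(read_delim_auto(path, colClasses = "character"))
}

#' Write protein sequences as FASTA
#'
#' @param proteins Protein data.frame.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  lines <- unlist(lapply(seq_len(nrow(proteins)), function(i) {
    seq <- proteins$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    c(paste0(">", proteins$accession[i]),
      substring(seq, starts, pmin(starts + width - 1, nchar(seq))))
  }))
  writeLines(lines, path)
  invisible(path)
}
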