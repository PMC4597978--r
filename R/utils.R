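# Internal helpers: sequence validation, deterministic content hashes, CSV sniffing.

`%||%` <- function(a, b) if (is.null(a)) b else a

# 20 standard residues; ambiguity letters are carried through sequences but
# never cleaved at, never blocking, never massed (X alone counts toward #UA).
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("B", "Z", "U", "O", "X")

normalize_sequence <- function(x) toupper(trimws(as.character(x)))

assert_residues <- function(x, what = "sequence") {
  chars <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(AA_STANDARD, AA_AMBIGUOUS))
  if (length(bad) > 0) {
    stop(sprintf("invalid residue letter(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# FNV-1a 32-bit over UTF-8 bytes, in double arithmetic (no 32-bit overflow:
# the multiply is split into 16-bit limbs so intermediates stay < 2^53).
fnv1a32 <- function(x) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(enc2utf8(s))
    h <- 2166136261
    for (b in bytes) {
      h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
      lo <- h %% 65536
      hi <- h %/% 65536
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, character(1), USE.NAMES = FALSE)
}

peptide_id_for <- function(sequence) {
  sprintf("PEP-%s-%d", fnv1a32(sequence), nchar(sequence))
}

event_id_for <- function(accession, workflow_id, level, start,
                         sequence, parent_sequence) {
  key <- paste(accession, workflow_id, level, start, sequence,
               parent_sequence, sep = "|")
  sprintf("EVT-%s", fnv1a32(key))
}

# Delimiter sniffing for curation tables that may come from spreadsheets:
# tab wins if present in the header line, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_auto <- function(path, colClasses = NA) {
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = colClasses, comment.char = "",
                          na.strings = character(0), fill = TRUE)
  attr(df, "sep") <- sep
  df
}

# Standard protein table schema shared across the package.
PROTEIN_COLUMNS <- c("accession", "sequence", "length", "protein_type",
                     "organism", "genotype", "genome", "chromosome",
                     "allele", "gene_ids")

as_protein_table <- function(df) {
  if (!all(c("accession", "sequence") %in% names(df))) {
    stop("protein table needs 'accession' and 'sequence' columns", call. = FALSE)
  }
  df$accession <- as.character(df$accession)
  df$sequence <- normalize_sequence(df$sequence)
  assert_residues(df$sequence, "protein sequence")
  if (anyDuplicated(df$accession)) {
    stop("duplicate protein accession(s): ",
         paste(unique(df$accession[duplicated(df$accession)]), collapse = ", "),
         call. = FALSE)
  }
  df$length <- nchar(df$sequence)
  for (col in setdiff(PROTEIN_COLUMNS, names(df))) df[[col]] <- ""
  df[, PROTEIN_COLUMNS, drop = FALSE]
}

empty_match_table <- function() {
  data.frame(epitope_id = character(0), target_kind = character(0),
             target_id = character(0), position = integer(0),
             stringsAsFactors = FALSE)
}
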