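#' Exact-substring positions of an epitope in a target sequence
#'
#' 100\%-identity matching: every 1-based start position at which the epitope
#' equals the target substring, overlapping occurrences included (frequent in
#' repetitive prolamin domains), in ascending order.  `X` in the target never
#' matches any epitope letter (literal comparison).
#'
#' @param epitope_sequence,target_sequence Single amino-acid strings.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' find_exact_matches("QQQ", "QQQQQ")  # 1 2 3
#' @export
find_exact_matches <- function(epitope_sequence, target_sequence) {
  ep <- normalize_sequence(epitope_sequence)
  tg <- normalize_sequence(target_sequence)
  if (nchar(ep) < 1 || nchar(tg) < 1) {
    stop("epitope and target sequences must be non-empty", call. = FALSE)
  }
  k <- nchar(ep)
  n <- nchar(tg) - k + 1L
  if (n < 1) return(integer(0))
  starts <- seq_len(n)
  starts[substring(tg, starts, starts + k - 1L) == ep]
}

# Collapse identical assay reports for matching: one representative per
# (sequence, cell_type, disease), the lexicographically first epitope_id.
# Assay provenance stays in the epitope table itself.
dedupe_epitopes <- function(epitopes) {
  if (nrow(epitopes) == 0) return(epitopes)
  key <- paste(normalize_sequence(epitopes$sequence),
               epitopes$cell_type %||% "", epitopes$disease %||% "", sep = "\r")
  ord <- order(key, epitopes$epitope_id)
  ep <- epitopes[ord, , drop = FALSE]
  ep[!duplicated(paste(normalize_sequence(ep$sequence),
                       ep$cell_type %||% "", ep$disease %||% "", sep = "\r")), ,
     drop = FALSE]
}

match_epitopes_to_targets <- function(epitopes, targets, id_col, target_kind) {
  if (nrow(epitopes) == 0 || nrow(targets) == 0) return(empty_match_table())
  ep <- dedupe_epitopes(epitopes)
  rows <- list()
  for (i in seq_len(nrow(ep))) {
    epseq <- normalize_sequence(ep$sequence[i])
    for (j in seq_len(nrow(targets))) {
      pos <- find_exact_matches(epseq, targets$sequence[j])
      if (length(pos) > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          epitope_id = ep$epitope_id[i], target_kind = target_kind,
          target_id = targets[[id_col]][j], position = as.integer(pos),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_match_table())
  out <- do.call(rbind, rows)
  out[order(out$epitope_id, out$target_id, out$position), , drop = FALSE]
}

#' Map epitopes onto full-length proteins
#'
#' One match row per (epitope, protein, start position); annotation columns
#' are joined from the protein and epitope tables at query time rather than
#' duplicated here.  Epitopes with identical (sequence, cell type, disease)
#' are collapsed to one representative record for matching.
#'
#' @param epitopes Epitope data.frame (`epitope_id`, `sequence`, plus
#'   optional `cell_type`, `disease`, ... columns).
#' @param proteins Protein data.frame (`accession`, `sequence`).
#' @return Match data.frame: `epitope_id`, `target_kind`, `target_id`,
#'   `position`.
#' @export
match_epitopes_to_proteins <- function(epitopes, proteins) {
  match_epitopes_to_targets(epitopes, proteins, "accession", "protein")
}

#' Map epitopes onto digestion peptides
#'
#' A peptide-level match exists iff the epitope survives digestion intact
#' inside a single peptide; positions are relative to the peptide.  Epitopes
#' split across a cut site therefore retain their protein-level match but
#' have no peptide-level match.
#'
#' @param epitopes Epitope data.frame.
#' @param peptides Peptide data.frame (`peptide_id`, `sequence`).
#' @return Match data.frame as in [match_epitopes_to_proteins()].
#' @export
match_epitopes_to_peptides <- function(epitopes, peptides) {
  match_epitopes_to_targets(epitopes, peptides, "peptide_id", "peptide")
}
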