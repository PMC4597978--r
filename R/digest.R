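#' Simultaneous multi-enzyme digestion of one sequence
#'
#' Fragments are the maximal substrings between the union of all enzymes'
#' cut sites; they tile the input exactly (their concatenation reproduces
#' the sequence) and are returned in order of their 1-based start position.
#'
#' @param sequence A single amino-acid string.
#' @param enzymes Character vector of enzyme codes applied together.
#' @param rules An [enzyme_rules()] table.
#' @return data.frame with columns `sequence`, `start`.
#' @examples
#' digest_simultaneous("AAKAARAA", c("LysC", "TR"))
#' @export
digest_simultaneous <- function(sequence, enzymes, rules = enzyme_rules()) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  if (length(enzymes) == 0) stop("empty enzyme set", call. = FALSE)
  sites <- cut_sites_union(sequence, enzymes, rules)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, nchar(sequence))
  data.frame(sequence = substring(sequence, starts, ends),
             start = starts, stringsAsFactors = FALSE)
}

new_event_table <- function(n = 0) {
  data.frame(event_id = character(n), protein_accession = character(n),
             workflow_id = character(n), step_enzymes = character(n),
             peptide_sequence = character(n), start = integer(n),
             level = integer(n), parent_enzymes = character(n),
             parent_peptide_sequence = character(n), stringsAsFactors = FALSE)
}

#' Run one digestion workflow on one protein
#'
#' Step-1 fragments are emitted as level-0 digestion events (direct products
#' of the protein; parent fields empty).  For two-step workflows each level-0
#' fragment is then digested with the step-2 enzyme set and every resulting
#' fragment -- including fragments the second step leaves uncut -- is emitted
#' as a level-1 event carrying the step-1 fragment as its parent.  `start`
#' is always the absolute 1-based position in the protein, so every event can
#' be checked against the protein sequence.
#'
#' @param protein A one-row protein data.frame (or list) with at least
#'   `accession` and `sequence`.
#' @param workflow A `digestion_workflow` or notation string.
#' @param rules An [enzyme_rules()] table.
#' @return Event data.frame (one row per digestion event).
#' @examples
#' p <- data.frame(accession = "P1", sequence = "AAFKAA")
#' run_workflow(p, "TR-CTR")[, c("level", "start", "peptide_sequence")]
#' @export
run_workflow <- function(protein, workflow, rules = enzyme_rules()) {
  if (is.character(workflow)) workflow <- parse_workflow(workflow)
  stopifnot(inherits(workflow, "digestion_workflow"))
  accession <- as.character(protein$accession %||% protein[["accession"]])
  sequence <- normalize_sequence(protein$sequence)
  if (length(sequence) != 1 || nchar(sequence) < 1) {
    stop("empty protein sequence", call. = FALSE)
  }
  wf_id <- workflow$workflow_id
  step1 <- workflow$steps[[1]]
  step1_str <- paste(step1, collapse = "+")

  frag1 <- digest_simultaneous(sequence, step1, rules)
  level0 <- data.frame(
    event_id = event_id_for(accession, wf_id, 0L, frag1$start,
                            frag1$sequence, ""),
    protein_accession = accession, workflow_id = wf_id,
    step_enzymes = step1_str, peptide_sequence = frag1$sequence,
    start = frag1$start, level = 0L, parent_enzymes = "",
    parent_peptide_sequence = "", stringsAsFactors = FALSE)

  if (length(workflow$steps) == 1) return(level0)

  step2 <- workflow$steps[[2]]
  step2_str <- paste(step2, collapse = "+")
  level1 <- lapply(seq_len(nrow(frag1)), function(i) {
    sub <- digest_simultaneous(frag1$sequence[i], step2, rules)
    abs_start <- frag1$start[i] + sub$start - 1L
    data.frame(
      event_id = event_id_for(accession, wf_id, 1L, abs_start,
                              sub$sequence, frag1$sequence[i]),
      protein_accession = accession, workflow_id = wf_id,
      step_enzymes = step2_str, peptide_sequence = sub$sequence,
      start = abs_start, level = 1L, parent_enzymes = step1_str,
      parent_peptide_sequence = frag1$sequence[i], stringsAsFactors = FALSE)
  })
  rbind(level0, do.call(rbind, level1))
}

#' Digest every protein with every workflow
#'
#' Concatenation of [run_workflow()] over the protein-by-workflow cross
#' product, deduplicated by event identity (protein accession, workflow,
#' level, start, peptide sequence, parent peptide sequence).
#'
#' @param proteins Protein data.frame (`accession`, `sequence`, optional
#'   annotation columns).
#' @param workflows List of workflows (objects or notation strings);
#'   default: the 15-workflow panel of [default_workflows()].
#' @param rules An [enzyme_rules()] table.
#' @return Event data.frame.
#' @export
digest_all <- function(proteins, workflows = default_workflows(),
                       rules = enzyme_rules()) {
  if (is.character(workflows)) workflows <- as.list(workflows)
  workflows <- lapply(workflows, function(w)
    if (is.character(w)) parse_workflow(w) else w)
  if (nrow(proteins) == 0 || length(workflows) == 0) return(new_event_table())
  chunks <- vector("list", nrow(proteins) * length(workflows))
  k <- 0
  for (i in seq_len(nrow(proteins))) {
    for (w in workflows) {
      k <- k + 1
      chunks[[k]] <- run_workflow(proteins[i, , drop = FALSE], w, rules)
    }
  }
  events <- do.call(rbind, chunks)
  events[!duplicated(events$event_id), , drop = FALSE]
}
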