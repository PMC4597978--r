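WORKFLOW_ENZYME_CODES <- c("TR", "CTR", "PEP", "TLN", "LysC", "PROK")

# The default panel of 15 digestion workflows ("+" = same step, "-" = step
# boundary) spanning single-enzyme, simultaneous and two-step sequential runs.
DEFAULT_WORKFLOW_IDS <- c(
  "CTR", "CTR-PEP", "CTR-TR", "LysC", "LysC+TR", "LysC+TR+CTR",
  "PEP", "PEP-CTR", "PEP-CTR+TR", "PEP-TR", "PROK", "TLN",
  "TR", "TR-CTR", "TR-PEP"
)

#' Parse a digestion-workflow notation string
#'
#' Workflow notation joins enzyme codes with `+` when they act together in
#' the same step (union of cut sites) and with `-` between the at most two
#' consecutive steps of a sequential digestion.  `"PEP-CTR+TR"` is pepsin
#' first, then chymotrypsin and trypsin together on every pepsin fragment.
#' `"LysC+TR+CTR"` is a single simultaneous three-enzyme step.
#'
#' @param notation Workflow string, e.g. `"TR"`, `"LysC+TR"`, `"TR-CTR"`.
#' @return A `digestion_workflow` object: `workflow_id` plus an ordered
#'   `steps` list of enzyme-code vectors.
#' @examples
#' parse_workflow("PEP-CTR+TR")$steps
#' @export
parse_workflow <- function(notation) {
  if (length(notation) != 1 || is.na(notation) || !nzchar(notation)) {
    stop("'notation' must be a single non-empty string", call. = FALSE)
  }
  step_strings <- strsplit(notation, "-", fixed = TRUE)[[1]]
  if (length(step_strings) > 2) {
    stop("at most two '-'-separated digestion steps are supported: ",
         notation, call. = FALSE)
  }
  if (any(!nzchar(step_strings))) {
    stop("malformed workflow notation: ", notation, call. = FALSE)
  }
  steps <- lapply(step_strings, function(s) {
    codes <- strsplit(s, "+", fixed = TRUE)[[1]]
    unknown <- setdiff(codes, WORKFLOW_ENZYME_CODES)
    if (length(unknown) > 0) {
      stop("unknown enzyme code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(codes)) {
      stop("duplicate enzyme code within a step: ", s, call. = FALSE)
    }
    codes
  })
  structure(list(workflow_id = notation, steps = steps),
            class = "digestion_workflow")
}

#' Format a digestion workflow back to its notation
#'
#' Round-trips with [parse_workflow()]: `format(parse_workflow(w)) == w`.
#'
#' @param x A `digestion_workflow`.
#' @param ... Ignored.
#' @export
format.digestion_workflow <- function(x, ...) {
  paste(vapply(x$steps, paste, character(1), collapse = "+"), collapse = "-")
}

#' @export
print.digestion_workflow <- function(x, ...) {
  cat("<digestion workflow> ", format(x), "  (",
      length(x$steps), " step", if (length(x$steps) > 1) "s", ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.digestion_workflow <- function(x, ...) format(x)

#' The default panel of 15 digestion workflows
#'
#' Single-step digestions with each of the six proteases, the simultaneous
#' combinations `LysC+TR` and `LysC+TR+CTR`, and the two-step sequential
#' workflows `CTR-PEP`, `CTR-TR`, `PEP-CTR`, `PEP-CTR+TR`, `PEP-TR`,
#' `TR-CTR` and `TR-PEP`.
#'
#' @return List of `digestion_workflow` objects.
#' @examples
#' vapply(default_workflows(), format, character(1))
#' @export
default_workflows <- function() {
  lapply(DEFAULT_WORKFLOW_IDS, parse_workflow)
}
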