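#' Load an enzyme cleavage rule table
#'
#' Cleavage specificity is data, not code: each enzyme is one row of a
#' delimited table giving the residue side the specificity letter sits on
#' (`C` = cut after a target residue, `N` = cut before one), the set of target
#' residues, and zero or more blocking contexts over the positions P2, P1,
#' P1', P2' around the candidate bond (Schechter--Berger nomenclature;
#' P1/P1' are the residues immediately N-/C-terminal of the bond).
#'
#' The shipped baseline table covers the six proteases used throughout:
#' trypsin (`TR`, after K/R unless before P), low-specificity chymotrypsin
#' (`CTR`, after F/L/M/W/Y unless before P), pepsin at pH 1.3 (`PEP`, after
#' F/L unless before P), thermolysin (`TLN`, before A/F/I/L/M/V unless after
#' P), LysC (after K, no exception) and proteinase K (`PROK`, after
#' A/E/F/I/L/T/V/W/Y, no exception).  Higher-fidelity rule matrices fit the
#' same schema and can be supplied via `path`; the active rule-set name is
#' recorded in datastore metadata.
#'
#' Blocking-context grammar: contexts are separated by `;`, terms within a
#' context by `&`, each term `POS=LETTERS` (e.g. `P1'=P`).  A bond is blocked
#' when every term of at least one context holds.  Ambiguity letters
#' (X, B, Z, U, O) are never cleavage targets and never satisfy a blocking
#' context, so bonds flanking them stay intact unless another residue
#' triggers cleavage.
#'
#' @param path Path to a rule table (TSV/CSV with columns `enzyme_code`,
#'   `enzyme_name`, `side`, `targets`, `blocked_when`).  Default: the
#'   baseline table shipped with the package.
#' @return A data.frame of class `enzyme_rule_set` with one row per enzyme
#'   and the rule-set name in `attr(, "rule_set")`.
#' @examples
#' rules <- enzyme_rules()
#' rules$enzyme_code
#' @export
enzyme_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cleavage_rules_baseline.tsv",
                        package = "prolampep", mustWork = TRUE)
  }
  df <- read_delim_auto(path, colClasses = "character")
  required <- c("enzyme_code", "side", "targets")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("rule table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"blocked_when" %in% names(df)) df$blocked_when <- ""
  df$blocked_when[is.na(df$blocked_when)] <- ""
  if (!"enzyme_name" %in% names(df)) df$enzyme_name <- df$enzyme_code
  if (!all(df$side %in% c("C", "N"))) {
    stop("rule table 'side' must be 'C' or 'N'", call. = FALSE)
  }
  if (any(!nzchar(df$targets))) stop("empty target set in rule table", call. = FALSE)
  if (anyDuplicated(df$enzyme_code)) {
    stop("duplicate enzyme_code in rule table", call. = FALSE)
  }
  attr(df, "rule_set") <- sub("\\.[^.]*$", "", basename(path))
  class(df) <- c("enzyme_rule_set", class(df))
  df
}

# "P1'=P;P2=K&P1=R" -> list(list(`P1'` = "P"), list(P2 = "K", P1 = "R"))
parse_block_contexts <- function(expr) {
  if (is.na(expr) || !nzchar(expr)) return(list())
  lapply(strsplit(expr, ";", fixed = TRUE)[[1]], function(ctx) {
    terms <- strsplit(ctx, "&", fixed = TRUE)[[1]]
    parsed <- lapply(terms, function(term) {
      kv <- strsplit(term, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2 || !kv[1] %in% c("P2", "P1", "P1'", "P2'")) {
        stop("malformed blocking context term: ", term, call. = FALSE)
      }
      strsplit(kv[2], "")[[1]]
    })
    names(parsed) <- vapply(terms, function(term)
      strsplit(term, "=", fixed = TRUE)[[1]][1], character(1))
    parsed
  })
}

# Position of each context symbol relative to bond i (between residues i, i+1).
.CTX_OFFSET <- c("P2" = -1L, "P1" = 0L, "P1'" = 1L, "P2'" = 2L)

bond_blocked <- function(i, chars, contexts) {
  L <- length(chars)
  for (ctx in contexts) {
    hit <- TRUE
    for (posname in names(ctx)) {
      j <- i + .CTX_OFFSET[[posname]]
      if (j < 1 || j > L) { hit <- FALSE; break }
      res <- chars[j]
      # ambiguity letters never satisfy a blocking context
      if (res %in% AA_AMBIGUOUS || !(res %in% ctx[[posname]])) {
        hit <- FALSE; break
      }
    }
    if (hit) return(TRUE)
  }
  FALSE
}

#' Predict the cut sites of one enzyme on a sequence
#'
#' A cut site is the index `i` of the peptide bond between residues `i` and
#' `i + 1` (1-based, so sites lie strictly between 1 and the sequence
#' length).  A bond is a site iff the enzyme's target/side predicate holds
#' and no blocking context of the rule matches.
#'
#' @param sequence A single amino-acid string.
#' @param enzyme An enzyme code present in `rules` (e.g. `"TR"`).
#' @param rules An [enzyme_rules()] table.
#' @return Sorted integer vector of bond indices.
#' @examples
#' find_cut_sites("AAKAAA", "TR")    # 3
#' find_cut_sites("AAKPAA", "TR")    # blocked by proline
#' find_cut_sites("AAKPAA", "LysC")  # 3: LysC has no proline exception
#' @export
find_cut_sites <- function(sequence, enzyme, rules = enzyme_rules()) {
  sequence <- normalize_sequence(sequence)
  if (length(sequence) != 1 || nchar(sequence) < 1) {
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  }
  row <- which(rules$enzyme_code == enzyme)
  if (length(row) != 1) stop("unknown enzyme code: ", enzyme, call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2) return(integer(0))
  targets <- setdiff(strsplit(rules$targets[row], "")[[1]], AA_AMBIGUOUS)
  cand <- if (rules$side[row] == "C") {
    which(chars[-L] %in% targets)
  } else {
    which(chars[-1] %in% targets)
  }
  if (length(cand) == 0) return(integer(0))
  contexts <- parse_block_contexts(rules$blocked_when[row])
  if (length(contexts) > 0) {
    cand <- cand[!vapply(cand, bond_blocked, logical(1),
                         chars = chars, contexts = contexts)]
  }
  sort(as.integer(cand))
}

# Union of cut sites over a set of enzyme codes.
cut_sites_union <- function(sequence, enzymes, rules) {
  sort(unique(unlist(lapply(enzymes, function(e)
    find_cut_sites(sequence, e, rules)))))
}
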