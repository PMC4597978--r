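#' Load a residue mass table
#'
#' The default table ships the IUPAC monoisotopic and average residue masses
#' of the 20 standard amino acids; peptide masses are residue sums plus one
#' water.  The selenocysteine/pyrrolysine letters U and O (and the B/Z
#' ambiguity codes) carry no mass by default, so any peptide containing
#' them -- or X -- has undefined masses rather than a silently wrong value.
#'
#' @param path Optional path to an alternative table (delimited text with
#'   columns `residue`, `monoisotopic`, `average`).
#' @param water_monoisotopic,water_average,proton Mass constants in Da.
#' @return data.frame of class `mass_table` with the constants as attributes.
#' @examples
#' mt <- mass_table()
#' attr(mt, "proton")
#' @export
mass_table <- function(path = NULL, water_monoisotopic = 18.010565,
                       water_average = 18.01528, proton = 1.007276) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_masses.tsv",
                        package = "prolampep", mustWork = TRUE)
  }
  df <- read_delim_auto(path)
  needed <- c("residue", "monoisotopic", "average")
  if (!all(needed %in% names(df))) {
    stop("mass table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df$residue <- as.character(df$residue)
  df$monoisotopic <- as.numeric(df$monoisotopic)
  df$average <- as.numeric(df$average)
  missing <- setdiff(AA_STANDARD, df$residue)
  if (length(missing) > 0) {
    stop("mass table lacks standard residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$monoisotopic <= 0) || any(df$average <= 0) ||
      water_monoisotopic <= 0 || water_average <= 0 || proton <= 0) {
    stop("mass constants must be positive", call. = FALSE)
  }
  attr(df, "water_monoisotopic") <- water_monoisotopic
  attr(df, "water_average") <- water_average
  attr(df, "proton") <- proton
  attr(df, "mass_set") <- sub("\\.[^.]*$", "", basename(path))
  class(df) <- c("mass_table", class(df))
  df
}

residue_sum <- function(sequences, lookup) {
  vapply(strsplit(sequences, ""), function(chars) {
    m <- lookup[chars]
    if (anyNA(m)) NA_real_ else sum(m)
  }, numeric(1))
}

check_mass_input <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  if (length(sequence) == 0 || any(is.na(sequence)) || any(!nzchar(sequence))) {
    stop("empty sequence", call. = FALSE)
  }
  sequence
}

#' Count unrecognized residues (#UA)
#'
#' The number of literal `X` characters in the sequence.  Other ambiguity
#' letters (B, Z, U, O) also void the mass columns but are not counted here.
#'
#' @param sequence Character vector of sequences.
#' @return Integer vector.
#' @examples
#' count_unrecognized(c("PQXQF", "PQQQF", "XX"))
#' @export
count_unrecognized <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  nchar(sequence) - nchar(gsub("X", "", sequence, fixed = TRUE))
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water.  `NA` when the
#' sequence contains any residue absent from the table (X, B, Z and by
#' default U, O).
#'
#' @param sequence Character vector of peptide sequences.
#' @param table A [mass_table()].
#' @return Numeric vector in Da (`NA` where undefined).
#' @examples
#' monoisotopic_mass("G")   # 75.0320
#' @export
monoisotopic_mass <- function(sequence, table = mass_table()) {
  sequence <- check_mass_input(sequence)
  lookup <- stats::setNames(table$monoisotopic, table$residue)
  residue_sum(sequence, lookup) + attr(table, "water_monoisotopic")
}

#' Singly-protonated monoisotopic peptide mass [M+H]+
#'
#' [monoisotopic_mass()] plus one proton: the singly-charged monoisotopic
#' mass a mass spectrometrist searches for.  Values are stored unrounded;
#' display and mass-search use 4-decimal rounding (see [mass_search()]).
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector in Da (`NA` where undefined).
#' @examples
#' round(protonated_mass("FQQPQPQQ"), 4)  # 1000.4847
#' @export
protonated_mass <- function(sequence, table = mass_table()) {
  monoisotopic_mass(sequence, table) + attr(table, "proton")
}

#' Average peptide mass [M]
#'
#' @inheritParams monoisotopic_mass
#' @return Numeric vector in Da (`NA` where undefined).
#' @export
average_mass <- function(sequence, table = mass_table()) {
  sequence <- check_mass_input(sequence)
  lookup <- stats::setNames(table$average, table$residue)
  residue_sum(sequence, lookup) + attr(table, "water_average")
}

# 4-decimal display rounding used by the peptide list view and mass search.
display_mass <- function(x) round(x, 4)
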