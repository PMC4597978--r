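# Brute-force oracles, independent of the rule-table engine: every bond is
# tested with literal if-rules, fragments are recovered by scanning bonds one
# at a time.  Also small fixture builders shared across test files.

RULES <- enzyme_rules()
MASSES <- mass_table()

# literal per-bond rules for the six baseline enzymes
oracle_bond_cut <- function(chars, i, code) {
  a <- chars[i]
  b <- chars[i + 1]
  switch(code,
    TR = (a %in% c("K", "R")) && b != "P",
    CTR = (a %in% c("F", "L", "M", "W", "Y")) && b != "P",
    PEP = (a %in% c("F", "L")) && b != "P",
    TLN = (b %in% c("A", "F", "I", "L", "M", "V")) && a != "P",
    LysC = a == "K",
    PROK = a %in% c("A", "E", "F", "I", "L", "T", "V", "W", "Y"),
    stop("oracle: unknown code ", code))
}

oracle_sites <- function(sequence, codes) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < 2) return(integer(0))
  which(vapply(seq_len(length(chars) - 1), function(i)
    any(vapply(codes, function(code) oracle_bond_cut(chars, i, code),
               logical(1))), logical(1)))
}

oracle_fragments <- function(sequence, codes) {
  sites <- oracle_sites(sequence, codes)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, nchar(sequence))
  data.frame(sequence = substring(sequence, starts, ends), start = starts,
             stringsAsFactors = FALSE)
}

# two-step oracle: re-digest every step-1 fragment, absolute coordinates
oracle_two_step <- function(sequence, codes1, codes2) {
  f1 <- oracle_fragments(sequence, codes1)
  do.call(rbind, lapply(seq_len(nrow(f1)), function(i) {
    f2 <- oracle_fragments(f1$sequence[i], codes2)
    f2$start <- f1$start[i] + f2$start - 1L
    f2
  }))
}

random_sequences <- function(n, lengths, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(lengths, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

all_sequences <- function(len, alphabet) {
  if (len == 1) return(alphabet)
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  do.call(paste0, grid)
}

# tiling check: fragments sorted by start reproduce the sequence exactly
expect_tiles <- function(frag, sequence) {
  frag <- frag[order(frag$start), , drop = FALSE]
  expect_equal(frag$start,
               c(1L, utils::head(cumsum(nchar(frag$sequence)), -1) + 1L))
  expect_identical(paste(frag$sequence, collapse = ""), sequence)
}

toy_proteins <- function() {
  data.frame(
    accession = c("TOY1", "TOY2", "TOY3"),
    sequence = c("GGFQQPQPQQAGGKPQPQLPYPQK",
                 "GGTPQQPQQQFGGFQQPQPQQAGG",
                 "QQPFPQQPFPQQPFPKR"),
    protein_type = c("alpha gliadin", "gamma gliadin", "omega gliadin"),
    organism = c("Triticum aestivum", "Triticum aestivum", "Hordeum vulgare"),
    genotype = c("Chinese Spring", "Butte 86", "landrace-1"),
    genome = c("A", "D", "H"),
    stringsAsFactors = FALSE)
}

toy_epitopes <- function() {
  validate_epitopes(data.frame(
    epitope_id = c("E1", "E2", "E3"),
    sequence = c("PQPQLPYPQ", "QQPFP", "FQQPQPQQ"),
    cell_type = c("T cell", "B cell", "B cell"),
    is_core = c(TRUE, FALSE, FALSE),
    disease = c("celiac disease", "celiac disease", "wheat allergy"),
    stringsAsFactors = FALSE))
}
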