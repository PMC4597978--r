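# Seeded synthetic-fixture generator: prolamin-like proteins (repetitive
# P/Q-rich domains between unique cysteine-bearing termini), annotations,
# a toy epitope panel, and a ground-truth manifest built with independent
# naive scanners so every other module can be oracle-tested offline.

#' Default fixture protein types
#'
#' Prolamin-like families with their repeat motifs.  Real prolamins are
#' built from short repeated units (hence the epitope-rich, protease-poor
#' sequences); the generator concatenates mutated copies of these units.
#'
#' @return data.frame with `protein_type`, `motif`.
#' @export
default_protein_types <- function() {
  data.frame(
    protein_type = c("alpha gliadin", "gamma gliadin", "omega gliadin",
                     "HMW glutenin x-type"),
    motif = c("PQPQPFP", "PQQPFPQQ", "QQPQQPFPQQ", "PGQGQQGYYPTSPQQ"),
    stringsAsFactors = FALSE)
}

#' Default fixture epitope panel
#'
#' Six toy linear epitopes: two nine-residue celiac T-cell core registers,
#' a celiac B-cell pentamer, a WDEIA-style omega-gliadin B-cell heptamer,
#' and two deliberately cleavable epitopes bridging a K or R residue so that
#' trypsin destroys them (protein-level match retained, peptide-level match
#' lost).
#'
#' @return Epitope data.frame in the standard schema.
#' @export
default_epitope_panel <- function() {
  validate_epitopes(data.frame(
    epitope_id = sprintf("EPI%03d", 1:6),
    name = c("alpha-core-1", "alpha-core-2", "gliadin-B-pentamer",
             "omega-allergy-heptamer", "lysine-bridged", "arginine-bridged"),
    sequence = c("PFPQPQLPY", "PQPQLPYPQ", "QQPFP",
                 "QQIPQQQ", "PQQKFPQQ", "QPQRQPQY"),
    cell_type = c("T cell", "T cell", "B cell", "B cell", "B cell", "T cell"),
    is_core = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    disease = c("celiac disease", "celiac disease", "celiac disease",
                "wheat allergy WDEIA", "wheat allergy", "celiac disease"),
    antibody = c("", "", "IgA", "IgE", "IgG", ""),
    mhc_serotype = c("DQ2.5", "DQ2.5", "", "", "", "DQ8"),
    host = rep("Homo sapiens", 6), stringsAsFactors = FALSE))
}

#' Specification of a synthetic fixture set
#'
#' Defaults describe a small but structurally faithful prolamin world:
#' 12 proteins over 4 prolamin families and 5 Triticeae species, repeat
#' regions of 4--8 mutated motif copies flanked by unique termini carrying
#' 2--6 cysteines, a 2\% point-substitution rate within repeats (substitution
#' only, so planted coordinates stay exact), and each panel epitope planted
#' twice.  Same seed, same bytes.
#'
#' @param seed Integer RNG seed (Mersenne-Twister; recorded in the manifest).
#' @param n_proteins Number of proteins.
#' @param n_repeats Range (min, max) of motif copies per protein.
#' @param flank_length Range of unique terminal-domain lengths.
#' @param n_cysteines Range of cysteines placed in the flanks.
#' @param mutation_rate Per-residue substitution probability within repeats.
#' @param plants_per_epitope Planted occurrences per panel epitope.
#' @param epitopes Epitope panel ([default_epitope_panel()]).
#' @param types Protein-type/motif table ([default_protein_types()]).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 12L, n_repeats = c(4L, 8L),
                         flank_length = c(8L, 14L), n_cysteines = c(2L, 6L),
                         mutation_rate = 0.02, plants_per_epitope = 2L,
                         epitopes = default_epitope_panel(),
                         types = default_protein_types()) {
  stopifnot(n_proteins >= 1, length(n_repeats) == 2, n_repeats[1] >= 1,
            mutation_rate >= 0, mutation_rate < 1, plants_per_epitope >= 0)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_repeats = as.integer(n_repeats),
                 flank_length = as.integer(flank_length),
                 n_cysteines = as.integer(n_cysteines),
                 mutation_rate = mutation_rate,
                 plants_per_epitope = as.integer(plants_per_epitope),
                 epitopes = validate_epitopes(epitopes), types = types),
            class = "fixture_spec")
}

# --- independent naive oracles (deliberately dumb character loops, kept
# --- separate from the rule-table engine and the vectorized matcher) -------

naive_find_all <- function(pattern, subject) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  out <- integer(0)
  if (length(pc) > length(sc)) return(out)
  for (i in seq_len(length(sc) - length(pc) + 1)) {
    ok <- TRUE
    for (j in seq_along(pc)) {
      if (sc[i + j - 1] != pc[j]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# Literal transcription of the six baseline rules, bond by bond.
naive_cut_sites <- function(sequence, code) {
  sc <- strsplit(sequence, "")[[1]]
  L <- length(sc)
  out <- integer(0)
  if (L < 2) return(out)
  for (i in seq_len(L - 1)) {
    a <- sc[i]      # P1
    b <- sc[i + 1]  # P1'
    cut <- switch(code,
      TR = (a == "K" || a == "R") && b != "P",
      CTR = a %in% c("F", "L", "M", "W", "Y") && b != "P",
      PEP = (a == "F" || a == "L") && b != "P",
      TLN = b %in% c("A", "F", "I", "L", "M", "V") && a != "P",
      LysC = a == "K",
      PROK = a %in% c("A", "E", "F", "I", "L", "T", "V", "W", "Y"),
      stop("unknown enzyme code: ", code))
    if (cut) out <- c(out, i)
  }
  out
}

# Does trypsin cut strictly inside this epitope?  Internal bonds depend only
# on the epitope's own residues, so resistance is a property of the sequence.
tr_resistant_epitope <- function(sequence) {
  sc <- strsplit(sequence, "")[[1]]
  k <- length(sc)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    if ((sc[i] == "K" || sc[i] == "R") && sc[i + 1] != "P") return(FALSE)
  }
  TRUE
}

.FIXTURE_SPECIES <- data.frame(
  organism = c("Triticum aestivum", "Triticum urartu", "Aegilops tauschii",
               "Aegilops speltoides", "Hordeum vulgare"),
  genome = c("D", "A", "D", "S", "H"),
  stringsAsFactors = FALSE)

.FIXTURE_GENOTYPES <- c("Chinese Spring", "Butte 86", "Cheyenne", "landrace-1")

#' Generate a seeded synthetic fixture set
#'
#' Builds prolamin-like proteins (mutated repeat units between unique
#' flanks), plants the panel epitopes at recorded positions, and emits a
#' ground-truth manifest produced by independent naive scanners: every
#' epitope occurrence in every protein (planted or motif-emergent, flagged),
#' each epitope's trypsin-resistance (no internal K/R|notP bond), and every
#' single-enzyme cut site of every protein.  The manifest is what oracle
#' tests compare the digestion engine and epitope mapper against.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `proteins.fasta`,
#'   `annotations.csv`, `epitopes.csv`, `manifest.csv`, `cut_sites.csv` and
#'   `fixture_metadata.dcf`.
#' @return List with `proteins`, `epitopes`, `manifest`, `cut_sites`,
#'   `spec` (and `files` when `dir` is given).
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7, n_proteins = 4))
#' head(fx$manifest)
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  types <- spec$types
  flank_pool <- c("G", "S", "T", "V", "E", "Q", "P", "K", "R", "N", "H", "D")
  sub_pool <- c("P", "Q", "L", "F", "S", "Y")

  make_flank <- function(len, n_cys) {
    chars <- sample(flank_pool, len, replace = TRUE)
    if (n_cys > 0) chars[sample(len, min(n_cys, len))] <- "C"
    paste(chars, collapse = "")
  }

  proteins <- do.call(rbind, lapply(seq_len(spec$n_proteins), function(i) {
    ty <- types[((i - 1) %% nrow(types)) + 1, ]
    sp <- .FIXTURE_SPECIES[sample(nrow(.FIXTURE_SPECIES), 1), ]
    n_rep <- sample(spec$n_repeats[1]:spec$n_repeats[2], 1)
    unit <- strsplit(ty$motif, "")[[1]]
    repeats <- vapply(seq_len(n_rep), function(r) {
      chars <- unit
      hit <- stats::runif(length(chars)) < spec$mutation_rate
      if (any(hit)) chars[hit] <- sample(sub_pool, sum(hit), replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
    n_cys <- sample(spec$n_cysteines[1]:spec$n_cysteines[2], 1)
    flankN <- make_flank(sample(spec$flank_length[1]:spec$flank_length[2], 1),
                         ceiling(n_cys / 2))
    flankC <- make_flank(sample(spec$flank_length[1]:spec$flank_length[2], 1),
                         floor(n_cys / 2))
    data.frame(accession = sprintf("FIX%04d", i),
               sequence = paste0(flankN, paste(repeats, collapse = ""), flankC),
               protein_type = ty$protein_type, organism = sp$organism,
               genotype = sample(.FIXTURE_GENOTYPES, 1), genome = sp$genome,
               chromosome = paste0(sample(1:7, 1), sp$genome),
               allele = "", gene_ids = "", stringsAsFactors = FALSE)
  }))

  # plant epitopes at non-overlapping recorded positions
  epitopes <- spec$epitopes
  planted <- list()
  occupied <- lapply(seq_len(nrow(proteins)), function(i) integer(0))
  if (spec$plants_per_epitope > 0 && nrow(epitopes) > 0) {
    for (e in seq_len(nrow(epitopes))) {
      epseq <- epitopes$sequence[e]
      k <- nchar(epseq)
      for (p in seq_len(spec$plants_per_epitope)) {
        for (attempt in 1:50) {
          pr <- sample(nrow(proteins), 1)
          L <- nchar(proteins$sequence[pr])
          if (L < k) next
          pos <- sample(L - k + 1, 1)
          span <- pos:(pos + k - 1)
          if (any(span %in% occupied[[pr]])) next
          substr(proteins$sequence[pr], pos, pos + k - 1) <- epseq
          occupied[[pr]] <- c(occupied[[pr]], span)
          planted[[length(planted) + 1]] <- data.frame(
            epitope_id = epitopes$epitope_id[e],
            accession = proteins$accession[pr], position = pos,
            stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(epitope_id = character(0), accession = character(0),
               position = integer(0), stringsAsFactors = FALSE)

  # ground truth by naive scan: every occurrence, planted or emergent
  manifest <- do.call(rbind, c(list(
    data.frame(epitope_id = character(0), accession = character(0),
               position = integer(0), sequence = character(0),
               planted = logical(0), tr_resistant = logical(0),
               stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(epitopes)), function(e) {
      do.call(rbind, lapply(seq_len(nrow(proteins)), function(pr) {
        pos <- naive_find_all(epitopes$sequence[e], proteins$sequence[pr])
        if (length(pos) == 0) return(NULL)
        data.frame(epitope_id = epitopes$epitope_id[e],
                   accession = proteins$accession[pr], position = pos,
                   sequence = epitopes$sequence[e],
                   planted = paste(epitopes$epitope_id[e],
                                   proteins$accession[pr], pos) %in%
                     paste(planted$epitope_id, planted$accession,
                           planted$position),
                   tr_resistant = tr_resistant_epitope(epitopes$sequence[e]),
                   stringsAsFactors = FALSE)
      }))
    })))
  manifest <- manifest[order(manifest$epitope_id, manifest$accession,
                             manifest$position), , drop = FALSE]
  rownames(manifest) <- NULL

  cut_sites <- do.call(rbind, c(list(
    data.frame(accession = character(0), enzyme_code = character(0),
               site = integer(0), stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(proteins)), function(pr) {
      do.call(rbind, lapply(WORKFLOW_ENZYME_CODES, function(code) {
        s <- naive_cut_sites(proteins$sequence[pr], code)
        if (length(s) == 0) return(NULL)
        data.frame(accession = proteins$accession[pr], enzyme_code = code,
                   site = s, stringsAsFactors = FALSE)
      }))
    })))
  rownames(cut_sites) <- NULL

  proteins <- as_protein_table(proteins)
  out <- list(proteins = proteins, epitopes = epitopes, manifest = manifest,
              cut_sites = cut_sites, spec = spec)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(fasta = file.path(dir, "proteins.fasta"),
               annotations = file.path(dir, "annotations.csv"),
               epitopes = file.path(dir, "epitopes.csv"),
               manifest = file.path(dir, "manifest.csv"),
               cut_sites = file.path(dir, "cut_sites.csv"),
               metadata = file.path(dir, "fixture_metadata.dcf"))
    write_fasta(proteins, files[["fasta"]])
    export_csv(proteins[, setdiff(PROTEIN_COLUMNS, c("sequence", "length"))],
               files[["annotations"]])
    export_csv(epitopes, files[["epitopes"]])
    export_csv(manifest, files[["manifest"]])
    export_csv(cut_sites, files[["cut_sites"]])
    write.dcf(data.frame(seed = spec$seed, rng = "Mersenne-Twister",
                         n_proteins = spec$n_proteins,
                         generator = "prolampep::generate_fixture"),
              files[["metadata"]])
    out$files <- files
  }
  out
}
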