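test_that("single-enzyme cut-site prediction follows the baseline rules", {
  expect_identical(find_cut_sites("AAKAAA", "TR", RULES), 3L)
  expect_identical(find_cut_sites("AAKPAA", "TR", RULES), integer(0))
  expect_identical(find_cut_sites("AAKPAA", "LysC", RULES), 3L)
  expect_identical(find_cut_sites("AAFAAA", "CTR", RULES), 3L)
  # thermolysin is N-side: cut before L unless preceded by P
  expect_identical(find_cut_sites("GGLGG", "TLN", RULES), 2L)
  expect_identical(find_cut_sites("GPLGG", "TLN", RULES), integer(0))
  expect_error(find_cut_sites("AAA", "NOPE", RULES), "unknown enzyme")
})

test_that("ambiguity letters are never targets and never block", {
  # X is not a target: no cut around an X-only context
  expect_identical(find_cut_sites("AAXAAA", "TR", RULES), integer(0))
  # K followed by X still cuts (X does not satisfy the proline block)
  expect_identical(find_cut_sites("AAKXAA", "TR", RULES), 3L)
  # B/Z/U/O are never cleavage targets either
  expect_identical(find_cut_sites("GGBZGG", "PROK", RULES), integer(0))
  expect_identical(find_cut_sites("GGUOGG", "PROK", RULES), integer(0))
})

test_that("simultaneous digestion is the union of per-enzyme sites and tiles", {
  frag <- digest_simultaneous("AAKAARAA", c("LysC", "TR"), RULES)
  expect_identical(frag$sequence, c("AAK", "AAR", "AA"))
  expect_identical(frag$start, c(1L, 4L, 7L))

  frag2 <- digest_simultaneous("AAAA", "TR", RULES)
  expect_identical(frag2$sequence, "AAAA")

  expect_error(digest_simultaneous("AAAA", character(0), RULES), "empty enzyme")

  set.seed(421)
  seqs <- random_sequences(60, 3:30,
                           c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))
  for (s in seqs) {
    frag <- digest_simultaneous(s, c("TR", "CTR", "TLN"), RULES)
    expect_identical(paste(frag$sequence, collapse = ""), s)
  }
})

test_that("two-step workflows emit level-0/level-1 events with correct lineage", {
  p <- data.frame(accession = "P1", sequence = "AAFKAA")
  ev <- run_workflow(p, "TR-CTR", RULES)
  l0 <- ev[ev$level == 0, ]
  l1 <- ev[ev$level == 1, ]
  expect_identical(l0$peptide_sequence, c("AAFK", "AA"))
  expect_identical(l0$start, c(1L, 5L))
  expect_true(all(l0$parent_peptide_sequence == ""))
  expect_identical(l1$peptide_sequence, c("AAF", "K", "AA"))
  expect_identical(l1$start, c(1L, 4L, 5L))
  expect_identical(l1$parent_peptide_sequence, c("AAFK", "AAFK", "AA"))
  expect_identical(unique(l1$parent_enzymes), "TR")

  # single-step: one level-0 event covering the protein when nothing cuts
  ev2 <- run_workflow(data.frame(accession = "P2", sequence = "AAAA"),
                      "TR", RULES)
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$peptide_sequence, "AAAA")
  expect_identical(ev2$level, 0L)

  # "+" workflow equals simultaneous digestion by definition
  s <- "AAKAARAAFKA"
  ev3 <- run_workflow(data.frame(accession = "P3", sequence = s),
                      "LysC+TR", RULES)
  frag <- digest_simultaneous(s, c("LysC", "TR"), RULES)
  expect_identical(ev3$peptide_sequence, frag$sequence)
  expect_identical(ev3$start, frag$start)
})

test_that("every event satisfies its positional and sub-fragment invariants", {
  fx <- generate_fixture(fixture_spec(seed = 11, n_proteins = 6))
  events <- digest_all(fx$proteins, default_workflows(), RULES)
  seqs <- stats::setNames(fx$proteins$sequence, fx$proteins$accession)
  with_pos <- substring(seqs[events$protein_accession], events$start,
                        events$start + nchar(events$peptide_sequence) - 1)
  expect_identical(unname(with_pos), events$peptide_sequence)
  # level 0 <=> parent fields empty; level 1 => substring of parent
  expect_identical(events$level == 0L, events$parent_peptide_sequence == "")
  l1 <- events[events$level == 1L, ]
  expect_true(all(mapply(grepl, l1$peptide_sequence,
                         l1$parent_peptide_sequence, fixed = TRUE)))
})

test_that("digest_all treats accessions as part of event identity", {
  p2 <- data.frame(accession = c("A1", "A2"),
                   sequence = rep("AAKAARAA", 2), stringsAsFactors = FALSE)
  ev <- digest_all(p2, list("TR"), RULES)
  expect_identical(nrow(ev), 6L)
  expect_setequal(unique(ev$protein_accession), c("A1", "A2"))
  expect_identical(nrow(digest_all(p2[0, ], list("TR"), RULES)), 0L)
})

test_that("re-digesting any output fragment with the same enzymes is idempotent", {
  set.seed(99)
  for (s in random_sequences(25, 5:25, c("K", "R", "P", "Q", "F", "L", "A"))) {
    frag <- digest_simultaneous(s, c("TR", "PEP"), RULES)
    for (f in frag$sequence) {
      again <- digest_simultaneous(f, c("TR", "PEP"), RULES)
      expect_identical(again$sequence, f)
    }
  }
})

test_that("engine agrees with the brute-force oracle (exhaustive then sampled)", {
  alphabet <- c("K", "P", "Q", "F")
  # exhaustive over all bonds for short sequences
  for (len in 1:6) {
    for (s in all_sequences(len, alphabet)) {
      for (code in c("TR", "CTR", "TLN", "PROK")) {
        expect_identical(find_cut_sites(s, code, RULES),
                         as.integer(oracle_sites(s, code)),
                         label = paste(s, code))
      }
    }
  }
  # seeded sample of longer sequences, all six enzymes, plus a two-step run
  set.seed(7)
  for (s in random_sequences(300, 7:12, alphabet)) {
    for (code in c("TR", "CTR", "PEP", "TLN", "LysC", "PROK")) {
      expect_identical(find_cut_sites(s, code, RULES),
                       as.integer(oracle_sites(s, code)))
    }
    got <- run_workflow(data.frame(accession = "S", sequence = s),
                        "PEP-CTR+TR", RULES)
    want <- oracle_two_step(s, "PEP", c("CTR", "TR"))
    expect_identical(got[got$level == 1, ]$peptide_sequence, want$sequence)
    expect_identical(got[got$level == 1, ]$start, want$start)
  }
})
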