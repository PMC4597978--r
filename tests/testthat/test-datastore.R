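ds_toy <- build_datastore(toy_proteins(), toy_epitopes())

test_that("build deduplicates peptides by sequence and keeps all events", {
  # FQQPQPQQ region is shared by TOY1 and TOY2: one peptide record, >= 2 events
  p2 <- data.frame(accession = c("A", "B"),
                   sequence = rep("GGFQQPQPQQAGG", 2), stringsAsFactors = FALSE)
  ds <- build_datastore(p2, workflows = list("TLN"))
  expect_identical(sum(ds$peptides$sequence == "FQQPQPQQ"), 1L)
  ev <- ds$digestion_events
  expect_identical(sum(ev$peptide_sequence == "FQQPQPQQ"), 2L)
  expect_true(nrow(ds$peptides) <= nrow(ev))
  expect_error(build_datastore(
    data.frame(accession = c("A", "A"), sequence = c("AAA", "CCC"))),
    "duplicate")
  # empty epitope set: empty match tables, the rest populated
  ds0 <- build_datastore(p2, workflows = list("TR"))
  expect_identical(nrow(ds0$protein_epitope_matches), 0L)
  expect_identical(nrow(ds0$peptide_epitope_matches), 0L)
  expect_gt(nrow(ds0$peptides), 0L)
})

test_that("event totals are conserved over the protein x workflow cross product", {
  per_run <- 0L
  for (i in seq_len(nrow(toy_proteins()))) {
    for (w in default_workflows()) {
      per_run <- per_run +
        nrow(run_workflow(toy_proteins()[i, ], w, RULES))
    }
  }
  expect_identical(nrow(ds_toy$digestion_events), per_run)
})

test_that("filter chains are conjunctive, ordered and report step counts", {
  joined <- cbind(ds_toy$protein_epitope_matches,
                  ds_toy$proteins[match(ds_toy$protein_epitope_matches$target_id,
                                        ds_toy$proteins$accession),
                                  c("organism", "protein_type")],
                  ds_toy$epitopes[match(ds_toy$protein_epitope_matches$epitope_id,
                                        ds_toy$epitopes$epitope_id),
                                  c("cell_type", "disease")])
  chain <- list(list(column = "organism", value = "triticum"),
                list(column = "disease", value = "celiac"),
                list(column = "cell_type", value = "T cell", exact = TRUE),
                list(column = "protein_type", value = "gliadin"))
  out <- filter_chain(joined, chain)
  counts <- attr(out, "step_counts")
  expect_identical(length(counts), 4L)
  expect_true(all(diff(counts) <= 0))        # monotone narrowing
  expect_identical(unname(counts[4]), nrow(out))
  # equivalent to the single-pass conjunctive filter
  direct <- joined[grepl("triticum", tolower(joined$organism), fixed = TRUE) &
                   grepl("celiac", tolower(joined$disease), fixed = TRUE) &
                   joined$cell_type == "T cell" &
                   grepl("gliadin", tolower(joined$protein_type), fixed = TRUE), ]
  expect_identical(out, direct, ignore_attr = TRUE)
  # identity and error cases
  expect_identical(nrow(filter_chain(joined, list())), nrow(joined))
  expect_error(filter_chain(joined, list(list(column = "nope", value = "x"))),
               "unknown filter column")
})

test_that("mass search honours display, absolute and ppm modes", {
  hits <- mass_search(ds_toy, 1000.4847)
  expect_true("FQQPQPQQ" %in% hits$sequence)
  expect_identical(nrow(mass_search(ds_toy, 0.0)), 0L)
  expect_error(mass_search(ds_toy, 1000, tolerance = -1), "negative")
  disp <- mass_search(ds_toy, 1000.4847, "display")
  ppm <- mass_search(ds_toy, 1000.4847, "ppm", tolerance = 10)
  expect_true(all(disp$peptide_id %in% ppm$peptide_id))
  abs0 <- mass_search(ds_toy, 1000.4847, "absolute", tolerance = 0.0005)
  expect_setequal(abs0$peptide_id, disp$peptide_id)
})

test_that("specificity summaries agree with brute-force event recomputation", {
  expect_error(peptide_specificity_summary(ds_toy, "WWWW"), "unknown peptide")
  # two proteins, one species, one copy each
  p2 <- data.frame(accession = c("A", "B"),
                   sequence = rep("GGFQQPQPQQAGG", 2),
                   organism = "Triticum aestivum", protein_type = "alpha gliadin",
                   genotype = c("g1", "g2"), stringsAsFactors = FALSE)
  ds2 <- build_datastore(p2, workflows = list("TLN"))
  row <- peptide_specificity_summary(ds2, "FQQPQPQQ")
  expect_identical(row$n_proteins, 2L)
  expect_identical(row$n_species, 1L)
  expect_identical(row$n_peptides_in_protein, 1L)
  expect_identical(row$n_genotypes, 2L)
  # peptide occurring twice within one protein
  p1 <- data.frame(accession = "A",
                   sequence = "GGFQQPQPQQAGGFQQPQPQQAGG", stringsAsFactors = FALSE)
  ds1 <- build_datastore(p1, workflows = list("TLN"))
  expect_identical(
    peptide_specificity_summary(ds1, "FQQPQPQQ")$n_peptides_in_protein, 2L)
  # oracle: recompute every count from the event table for a repeated peptide
  summ <- peptide_specificity_summary(ds_toy, "PQQPF")
  expect_gt(nrow(summ), 0)
  for (i in seq_len(nrow(summ))) {
    wf <- summ$workflow_id[i]
    lvl <- length(parse_workflow(wf)$steps) - 1L
    ev <- ds_toy$digestion_events
    ev <- ev[ev$peptide_sequence == "PQQPF" & ev$workflow_id == wf &
             ev$level == lvl, ]
    occ <- unique(ev[, c("protein_accession", "start")])
    expect_identical(summ$n_proteins[i],
                     length(unique(occ$protein_accession)))
    expect_identical(summ$n_peptides_in_protein[i],
                     as.integer(max(table(occ$protein_accession))))
  }
})

test_that("peptide count matrices have consistent margins and scope behaviour", {
  m <- peptide_count_matrix(ds_toy)
  inner <- m[rownames(m) != "Sum", colnames(m) != "Sum", drop = FALSE]
  expect_identical(sum(inner), unname(m["Sum", "Sum"]))
  expect_identical(unname(m["Sum", "Sum"]), nrow(ds_toy$digestion_events))
  expect_equal(unname(rowSums(inner)), unname(m[rownames(m) != "Sum", "Sum"]))
  # empty scope: all-zero matrix with the full dimensions
  m0 <- peptide_count_matrix(ds_toy, filters = list(
    list(column = "organism", value = "zebrafish")))
  expect_identical(dim(m0), dim(m))
  expect_identical(sum(m0), 0L)
  # unique-peptide mode can only shrink cells
  mu <- peptide_count_matrix(ds_toy, unique_peptides = TRUE)
  expect_true(all(mu <= m))
  # hand-count on a tiny fixture: one protein, one workflow
  p1 <- data.frame(accession = "A", sequence = "AAKAARAA",
                   protein_type = "alpha gliadin", stringsAsFactors = FALSE)
  ds1 <- build_datastore(p1, workflows = list("TR"))
  m1 <- peptide_count_matrix(ds1)
  expect_identical(unname(m1["alpha gliadin", "TR"]), 3L)
})

test_that("epitope density divides matches by proteins-with-matches per group", {
  # group with 2 proteins: 6 matches on one, 0 on the other -> density 6
  p <- data.frame(accession = c("A", "B"),
                  sequence = c("QQQQQQQGG", "GGGGGGGGG"),
                  protein_type = "alpha gliadin", genome = "A",
                  stringsAsFactors = FALSE)
  eps <- validate_epitopes(data.frame(epitope_id = "E1", sequence = "QQ",
                                      cell_type = "T cell",
                                      disease = "celiac disease"))
  ds <- build_datastore(p, eps, workflows = list("TR"))
  d <- epitope_density(ds)
  expect_identical(nrow(d), 1L)
  expect_identical(d$n_matches, 6L)
  expect_identical(d$n_proteins, 1L)
  expect_equal(d$density, 6)
  # duplicating a matchless protein leaves density unchanged
  p3 <- rbind(p, data.frame(accession = "C", sequence = "GGGGGGGGG",
                            protein_type = "alpha gliadin", genome = "A"))
  ds3 <- build_datastore(p3, eps, workflows = list("TR"))
  expect_equal(epitope_density(ds3)$density, d$density)
  # groups with no matches are absent, not 0/0
  expect_identical(nrow(epitope_density(ds, cell_type = "B cell")), 0L)
  # distinct-epitope mode bounded by row-count mode
  dd <- epitope_density(ds_toy, distinct_epitopes = TRUE)
  dr <- epitope_density(ds_toy)
  expect_true(all(dd$n_matches <= dr$n_matches))
})

test_that("CSV export round-trips and rebuilds are byte-identical", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "peptides.csv")
  export_csv(ds_toy$peptides, f)
  back <- read_csv_table(f)
  expect_equal(back, ds_toy$peptides, ignore_attr = TRUE)
  # header-only file for an empty table
  f0 <- file.path(tmp, "empty.csv")
  export_csv(ds_toy$peptides[0, ], f0)
  expect_identical(length(readLines(f0)), 1L)
  # embedded commas are quoted
  fq <- file.path(tmp, "quoted.csv")
  export_csv(data.frame(x = "a,b", y = 1), fq)
  expect_identical(read_csv_table(fq)$x, "a,b")
  # rebuild determinism: identical inputs -> byte-identical exports
  d1 <- file.path(tmp, "store1"); d2 <- file.path(tmp, "store2")
  export_datastore(build_datastore(toy_proteins(), toy_epitopes()), d1)
  export_datastore(build_datastore(toy_proteins(), toy_epitopes()), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and the serialized store reloads into an equivalent object
  ds_back <- read_datastore(d1)
  expect_equal(ds_back$peptides, ds_toy$peptides, ignore_attr = TRUE)
  expect_equal(ds_back$digestion_events, ds_toy$digestion_events,
               ignore_attr = TRUE)
})
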