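---
title: "In silico prolamin digestion, mass annotation and epitope mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico prolamin digestion, mass annotation and epitope mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolampep)
```

## Scope and assumptions

`prolampep` models *complete* proteolytic digestion: every predicted cut is
executed, there are no missed cleavages, no kinetics, no pH interpolation, no
enzyme-concentration effects, and no post-translational modifications or
disulphide topology. These are the right assumptions for designing and
interpreting peptide-marker and epitope-survival analyses, where the question
is "what can this workflow produce", not "in what yield". A missed-cleavage
option is deliberately absent: for repetitive prolamins it multiplies the
peptide space combinatorially without changing the reachability questions
this package answers.

## The cleavage engine

An enzyme rule is `(side, targets, blocking contexts)`. For the bond between
residues $i$ and $i+1$ of a sequence $s$:

* a C-side rule fires when $s_i \in$ targets (the specificity letter is P1);
* an N-side rule fires when $s_{i+1} \in$ targets (the letter is P1');
* the bond is suppressed when any blocking context holds; a context is a
  conjunction of `position = letter-set` terms over P2, P1, P1', P2'.

The baseline table (`inst/extdata/cleavage_rules_baseline.tsv`) encodes the
commonly used simplifications of the published specificity matrices: TR after
K/R unless P1' = P; CTR (low specificity) after F/L/M/W/Y unless P1' = P; PEP
(pH 1.3) after F/L unless P1' = P; TLN before A/F/I/L/M/V unless P1 = P; LysC
after K; PROK after A/E/F/I/L/T/V/W/Y. Published positional-exception
matrices with wider context (Keil-style P4–P2' rules) fit the same schema, so
fidelity is a *data* choice: supply another table to `enzyme_rules(path)` and
its name is carried in every datastore's metadata. Acceptance-grade tests
deliberately depend only on the baseline rules above.

**Unknown residues.** `X` (and B/Z/U/O) is never a cleavage target and never
satisfies a blocking context. Both choices are conservative and together make
digestion of partially sequenced entries deterministic: a bond next to `X` is
cut only when a *known* residue triggers it (`AAKXAA` is cut after K because
X does not activate the proline block; `AAXAAA` is never cut by trypsin).

**Simultaneous and sequential digestion.** A `+`-joined step cuts at the
union of the member enzymes' sites — equivalent to digesting with each enzyme
to completion in the same tube. A `-` separates the at most two steps of a
sequential workflow. Step-1 fragments are level-0 events; step-2 products are
level-1 events with `parent_enzymes`/`parent_peptide_sequence` lineage and
absolute protein coordinates. Two design points were genuinely open:

* `LysC+TR+CTR` is run as a single simultaneous three-enzyme step, exactly as
  its `+` notation reads.
* Step-2 fragments that the second enzyme set leaves uncut are still emitted
  as level-1 events (an "identity cut"). This keeps each level a complete
  tiling of the protein — the level-max peptide set is the workflow's final
  product list, and parent lineage is populated for every step-2 row.

Both level-0 and level-1 fragment sets therefore tile the protein exactly
(no gaps, no overlaps); this is asserted property-style in the test suite.
Fragments are emitted down to single residues: nothing in the digestion
chemistry filters by length, so length thresholds belong in queries, not in
the engine.

## Mass annotation

Peptide masses are residue-mass sums plus one water; [M+H]+ adds one proton
(1.007276 Da). The shipped constants are the IUPAC residue masses (e.g.
G 57.02146, P 97.05276, Q 128.05858, F 147.06841 Da monoisotopic), water
18.010565 Da. The anchor check — [M+H]+ of FQQPQPQQ = 1000.4847 at 4
decimals, shared by all permutations of the F₁P₂Q₅ composition — is a
release-blocking test of the table.

Two mass columns are stored per peptide, neutral monoisotopic and protonated
monoisotopic, because list-view conventions for "[M+H]" labels are ambiguous
in the wild; storing both removes the guesswork. Display and the default
mass-search mode round to 4 decimals (matching how printed values and search
boxes behave); the unrounded double is what is stored and exported, and the
`absolute` (Da) and `ppm` search modes compare unrounded values. Sequences
containing X/B/Z/U/O have undefined (`NA`) masses; U and O have defined
masses chemically and can be enabled by supplying a custom table row, but the
default refuses to mass what the curation could not identify. `#UA` counts
only literal `X`, the convention for unrecognized residues.

## Epitope mapping

Matching is case-normalized exact equality — 100% identity, no deamidation
(Q→E) or substitution variants, which are downstream-analysis territory.
Overlapping and repeated occurrences are all recorded; in prolamin repeats a
pentamer can legitimately occur a dozen times per protein, and the density
statistic counts match rows unless `distinct_epitopes = TRUE`. Identical
(sequence, cell type, disease) records from different assays collapse to one
representative (lowest epitope id) for matching; assay provenance stays in
the epitope table. A peptide-level match requires the epitope to lie intact
inside a single final peptide, so for complete digestion the rule is crisp:
an epitope survives a workflow iff no cut site falls strictly inside it —
for the baseline rules that is a property of the epitope's own sequence.

## The datastore and its queries

`build_datastore()` assembles six cross-keyed tables (proteins, peptides,
epitopes, digestion events, protein- and peptide-level epitope matches). An
embedded in-memory representation with deterministic CSV serialization was
chosen over a database server: the problem is desk-scale, and byte-identical
rebuilds from identical inputs (content-hash ids, no build timestamp in the
metadata) make provenance trivially checkable — the test suite diffs two
independent builds byte for byte.

Decisions a user should know:

* **Event identity** is (protein accession, workflow, level, start, peptide
  sequence, parent peptide sequence). "Unique events" therefore keep
  protein–peptide multiplicity: the same peptide at two positions, or in two
  proteins, is two events.
* **`peptide_count_matrix()`** counts digestion events by default (the large
  totals convention) and unique peptide sequences with
  `unique_peptides = TRUE`; matrix dimensions come from the whole datastore,
  so a filter that excludes everything yields an all-zero matrix, not a
  zero-dimension one.
* **`peptide_specificity_summary()`** counts occurrences at the workflow's
  *final* level (level-0 for one-step, level-1 for two-step workflows): an
  intermediate fragment that step 2 destroys is not a product of the
  workflow. `n_peptides_in_protein` is the maximum copy number over source
  proteins, counting distinct (protein, start) occurrences.
* **`epitope_density()`** divides matches by the number of proteins *with at
  least one match* in the group — the normalization that removes
  database-composition bias — and omits groups with no matching protein
  rather than reporting 0/0. Without expression data the value is prevalence,
  not allergenicity.
* **Filters** are ordered, conjunctive, case-insensitive substring by default
  (`exact = TRUE` per filter for equality), with the running row count after
  each step in `attr(, "step_counts")`.

## The fixture generator

`generate_fixture()` emulates the structure the analyses rely on: proteins
built from 4–8 mutated copies of family-specific repeat units (alpha/gamma/
omega gliadin and HMW glutenin x-type motifs) between unique flanks carrying
2–6 cysteines; 12 proteins over 5 Triticeae species/genomes; a 2% point
substitution rate inside repeats (substitution only — no indels — so planted
coordinates stay exact); and a 6-epitope panel planted twice each, including
two K/R-bridged epitopes designed to be destroyed by trypsin. Values not
fixed by the emulated world were chosen once as field-realistic (repeat
counts and flank lengths bracket real prolamin domain sizes; 12 proteins keep
the full 15-workflow cross product fast) and are not tuned against tests.

The ground-truth manifest is produced by *independent naive scanners*
(character-by-character loops, a literal bond-by-bond transcription of the
six rules) rather than by the engine: it lists every epitope occurrence —
planted or emergent from the repeats, flagged — every single-enzyme cut
site, and each epitope's trypsin resistance. What a green manifest-recovery
test establishes is agreement between two independent implementations on
sequences with realistic repeat structure; what it cannot establish is
fidelity to any particular curated protein release, real allele frequencies,
or expression levels, none of which the generator attempts.

## Numerical and degenerate-input choices

* Positions are 1-based and inclusive everywhere; cut site $i$ is the bond
  between residues $i$ and $i+1$.
* Empty sequences are errors for digestion and mass calculation; a length-1
  sequence has no bonds and digests to itself.
* Mass comparisons in tests use exact rounding for the 4-dp anchor and
  explicit small tolerances (≤ 1e-9 Da) for algebraic identities.
* Ids are FNV-1a 32-bit content hashes; the (remote) peptide-id collision is
  disambiguated deterministically in sequence sort order.
* The brute-force digestion oracle is exercised exhaustively over all
  sequences up to length 6 on the {K, P, Q, F} alphabet (every bond of 5,460
  sequences) and on a seeded random sample at lengths 7–12; full exhaustive
  enumeration to length 12 (~2×10⁷ sequences) exceeds a sensible interpreted
  runtime and is a scale-down of the same check, not a different one.

## Known limitations

Two-step workflows only (matching the notation's `-`); no partial digestion;
no isotope envelopes or charge states beyond +1; linear epitopes only (no
conformational B-cell epitopes, no MHC-binding prediction); substring
semantics of interactive filter UIs vary, so both substring and exact modes
are provided rather than claiming either is canonical.
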