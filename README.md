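# prolampep

Multi-enzyme in silico digestion and epitope mapping for prolamin proteins.

## The problem

Cereal seed storage proteins — the prolamins: gliadins, glutenins, hordeins,
secalins, avenins — are rich in proline and glutamine, organized as short
repetitive sequence blocks, and are the triggers of celiac disease and several
wheat allergies. Their P/Q-rich repeats make them nearly invisible to trypsin,
the default protease of MS-based proteomics, so practical workflows use other
enzymes (chymotrypsin, pepsin, thermolysin, LysC, proteinase K) alone, together
or in consecutive steps. `prolampep` is for the proteomics or immunology
practitioner who needs to know, *before* touching an instrument:

* which peptides a given digestion workflow will produce from a set of
  prolamin sequences, and from which protein, at which position, via which
  parent fragment;
* what each peptide weighs ([M], monoisotopic, [M+H]+), and which peptides a
  detected singly-charged monoisotopic mass could correspond to;
* which linear T-/B-cell epitopes occur in which proteins, and which survive a
  digestion intact inside a single peptide;
* how specific a peptide is for a species, genotype or protein type, and how
  epitope-dense each protein family is per genome.

## The model

**Digestion.** Each enzyme is a row in an editable rule table: a side
(C-terminal or N-terminal of the scissile bond), a set of target residues, and
optional blocking contexts over P2/P1/P1'/P2' (Schechter–Berger positions).
The shipped baseline: trypsin `TR` cuts after K/R unless before P; chymotrypsin
(low specificity) `CTR` after F/L/M/W/Y unless before P; pepsin pH 1.3 `PEP`
after F/L unless before P; thermolysin `TLN` before A/F/I/L/M/V unless after P;
`LysC` after K unconditionally; proteinase K `PROK` after A/E/F/I/L/T/V/W/Y
unconditionally. A simultaneous multi-enzyme step cuts at the **union** of the
enzymes' sites; a sequential workflow (`"PEP-CTR+TR"` = pepsin, then CTR+TR on
every pepsin fragment) emits level-0 events (direct protein products) and
level-1 events (products of a step-1 peptide, with parent lineage and absolute
coordinates). The default panel is the 15 workflows `CTR`, `CTR-PEP`, `CTR-TR`,
`LysC`, `LysC+TR`, `LysC+TR+CTR`, `PEP`, `PEP-CTR`, `PEP-CTR+TR`, `PEP-TR`,
`PROK`, `TLN`, `TR`, `TR-CTR`, `TR-PEP`.

**Masses.** For a peptide with residue set *r*: monoisotopic mass
M = Σ m_mono(r) + m(H₂O), [M+H]+ = M + m(proton), average mass likewise with
average constants. `X` (unknown residue, counted in the `#UA` column) and the
ambiguity letters B/Z/U/O make the masses undefined rather than silently wrong.

**Epitopes.** Matching is exact 100%-identity substring search, overlapping
occurrences included — essential in repeat regions. An epitope "survives" a
digestion iff it lies intact inside a single peptide. Epitope density per group
= (matches passing a filter) ÷ (proteins in the group with ≥ 1 passing match).

## Worked example

```r
library(prolampep)

proteins <- data.frame(
  accession    = c("EX1", "EX2"),
  sequence     = c("GGFQQPQPQQAGGKPQPQLPYPQK", "GGTPQQPQQQFGG"),
  protein_type = c("alpha gliadin", "gamma gliadin"),
  organism     = c("Triticum aestivum", "Hordeum vulgare"))
epitopes <- validate_epitopes(data.frame(
  epitope_id = "E1", sequence = "PQPQLPYPQ", cell_type = "T cell",
  is_core = TRUE, disease = "celiac disease"))

ds <- build_datastore(proteins, epitopes)
ds
#> <peptide datastore>
#>   proteins: 2   peptides: 20   epitopes: 1
#>   digestion events: 87   (workflows: 15, rule set: cleavage_rules_baseline)
#>   epitope matches: 1 on proteins, 3 on peptides
```

A mass spectrometrist observes m/z 1000.4847 (singly charged) and asks which
peptides it could be:

```r
mass_search(ds, 1000.4847)[, c("sequence", "protonated_monoisotopic_mass")]
#>    sequence protonated_monoisotopic_mass
#> 3  FQQPQPQQ                     1000.485
#> 16 PQQPQQQF                     1000.485
```

Two isobaric peptides (same F₁P₂Q₅ composition, [M+H]+ = 1000.4847 at 4
decimals). How specific is the first one, and which workflow yields it?

```r
peptide_specificity_summary(ds, "FQQPQPQQ")
#>   peptide_sequence workflow_id n_proteins n_peptides_in_protein n_species n_types n_genotypes
#> 1         FQQPQPQQ         TLN          1                     1         1       1           0
```

Only thermolysin releases it, from one protein of one species — a usable
marker peptide. Finally, the celiac T-cell epitope density per protein family:

```r
epitope_density(ds, group_by = "protein_type", cell_type = "T cell")
#>    protein_type n_matches n_proteins density
#> 1 alpha gliadin         1          1       1
```

The planted 9-mer core epitope `PQPQLPYPQ` sits in the alpha gliadin; gamma
gliadin has no match, so (per the definition) it is absent from the table
rather than reported as 0/0.

## Command line

A thin CLI wraps the same functions (`digest`, `build`, `mass-search`,
`match-epitopes`, `specificity`, `density`, `export`, `make-fixtures`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","prolampep.R",package="prolampep"))')
Rscript $CLI make-fixtures --seed 42 --outdir fx
Rscript $CLI build --fasta fx/proteins.fasta --annotations fx/annotations.csv \
                   --epitopes fx/epitopes.csv --outdir store
Rscript $CLI mass-search --store store --mass 1000.4847
```

## Synthetic fixtures

`generate_fixture(fixture_spec(seed = ...))` builds a seeded, fully offline
prolamin-like test world — repeat-unit proteins with unique cysteine-bearing
flanks, annotations over Triticeae species/genomes, a toy epitope panel
(including deliberately cleavable K/R-bridged epitopes) — together with a
ground-truth manifest of every epitope occurrence, every single-enzyme cut
site, and each epitope's trypsin resistance, produced by independent naive
scanners so the engine can be oracle-tested.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed package,
the singly-protonated monoisotopic masses of two printed 8-residue prolamin
peptides (FQQPQPQQ and QQQQQPPF) by digesting designed precursor proteins
with the default engine and reading the datastore's mass annotations:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/prolamin-digestion.Rmd` for the methods account: rule-table
semantics, defaults and their rationale, fixture design, numerical choices
and limitations.
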