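---
title: "Screening an organellar proteome for ACE-inhibitory tripeptides"
author: "tripepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening an organellar proteome for ACE-inhibitory tripeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripepscan)
```

## The problem and the model

Red algae such as dulse (*Palmaria*) are protein-rich, and hydrolysates of
their proteins inhibit angiotensin I converting enzyme (ACE), the protease
whose inhibition lowers blood pressure. Short peptides carry most of that
activity, and curated databases record tripeptides with measured IC50
values (the concentration inhibiting half of ACE activity; lower is more
potent). The working assumption of in-silico screening is that a peptide's
activity travels with its sequence: if a potent tripeptide occurs inside a
protein, a suitable protease could liberate it from that protein too.

`tripepscan` implements that screen for an annotated organellar genome,
whose protein coding genes (PCGs) are the dominant protein source in a red
algal plastid:

1. extract the translated PCGs from a GenBank record (or protein FASTA plus
   an annotation table);
2. classify each gene under a curated 7-category schema (genetic system,
   ribosomal proteins, photosystems, ATP synthesis, metabolism, transport,
   unknown), with photosystems subdivided into phycobilisomes, photosystem
   I, photosystem II, cytochrome complex and redox system;
3. profile amino-acid composition per category;
4. filter the tripeptide database to IC50 strictly below a threshold and
   scan every protein for every retained tripeptide, counting all
   (including overlapping) occurrences;
5. tabulate matches by C-terminal class — ACE prefers substrates and
   inhibitors with particular C-terminal residues, so tripeptides are
   grouped as XXP, XXY, XXA, XXL, XXW, XXG, XXR, XXV, XXF, XXK, XXN, with
   XXX as the catch-all — against the functional grouping;
6. express enrichment as the peptide density, `100 * matches / residues`
   ("Peptide/AA (%)"), per group;
7. annotate each match with digestive releasability; and
8. optionally compare two proteomes cell by cell and as peptide sets.

## Parameters that matter

* **IC50 threshold** (`filter_by_ic50`, default 20 uM): strict `<`,
  matching the "less than" selection rule; a peptide exactly at the
  threshold is excluded. Duplicate database entries collapse to the
  minimum IC50, i.e. the most potent report of that sequence.
* **Counting mode** (`scan_proteome`): `positions` (default) counts every
  positional occurrence — each is a distinct candidate fragment a protease
  could release; `unique_pairs` counts each (peptide, protein) pair once.
  The published tallies do not state which convention they used, so both
  are first-class and comparisons refuse to mix them.
* **Overlaps**: always counted. A tripeptide starting at offset *i* never
  masks one at *i + 1*; this is the conservative choice when enumerating
  candidate fragments. Windows containing any non-standard residue never
  match.
* **Gene duplicates** (`dedupe_genes`, default off): genes present in two
  annotated copies (e.g. inside repeated rRNA-operon regions) stay
  distinct records by default; the flag collapses identical
  (symbol, sequence) pairs.
* **Rounding**: densities print at 2 decimals and compositions at 1,
  rounded half *up* (`round_half_up`), the commercial convention the
  published tables use — base R's round-half-to-even would disagree with
  several printed values. Rounding is display-only; internal values keep
  full precision.

## The classification schema

The 205-gene schema ships as an editable TSV
(`inst/extdata/plastid_gene_schema.tsv`) rather than code, because it is a
curation: users screening another genome supply their own file. Matching
is case-insensitive (annotation casing varies between deposits), symbols
missing from the schema fall back to Unknown/"Unique ORFs" with a warning,
and `validate_schema()` reports the per-subcategory tally so a schema can
be audited against its source. One curation note: the source material
lists *psbH* under photosystem II in its gene inventory but also shows a
*psbH* row inside a photosystem I column of a per-protein table; the
shipped schema assigns *psbH* to photosystem II only.

## Genome parsing choices

GenBank 1-based inclusive coordinates are converted to 0-based half-open
at the parser boundary and nowhere else. A deposited `/translation`
qualifier is authoritative; if it disagrees with the conceptual
translation of the coordinates, the deposited sequence is kept and a
warning logged. CDS features without a translation are translated under
the bacterial/plastid genetic code (NCBI table 11), literally, codon by
codon: no initiator-codon remapping to methionine. Literal translation
keeps synthetic fixtures exactly round-trippable; for real records, which
carry `/translation`, the choice only affects the consistency warning.
Internal stops in a conceptual translation flag the record instead of
dropping it, so annotation problems surface downstream rather than
silently shrinking the proteome.

## The digestion model

Digestive proteases generate peptide C-termini according to their
cleavage specificities: pepsin after Asp, Glu, Leu, Phe, Trp or Tyr;
chymotrypsin after Phe, Trp or Tyr; elastase after Ala, Gly, Ile, Leu,
Ser or Val; prolyl endopeptidase after Pro. (One source rendering of the
pepsin set prints "Aps"; it is read as Asp.) A matched tripeptide is
**C-releasable** by every enzyme whose set contains its last residue.
Because a released fragment needs two boundaries, the package adds a
minimal N-boundary rule — the hit starts at the protein N-terminus, or
the residue immediately before it is cleavable by any configured enzyme —
and calls a hit **fully releasable** when both boundaries are open. The
N-boundary rule is this package's model extension, not a published
procedure, and it is deliberately minimal: a binary site model with no
missed cleavages, no pH or kinetic efficiency, and no P1' exclusion rules
(no proline blocking). Specificities are config-driven YAML, so trypsin or
thermolysin can be added; releasability is monotone in the enzyme panel by
construction.

## The synthetic-data generator

Real inputs for the headline numbers are not redistributable: the screened
database is a dated snapshot of a curated resource, and the deposited
genome annotation lives in a sequence archive. The generator therefore
produces proteomes whose *statistical shape* matches the study system —
7 categories of proteins with uniform lengths, i.i.d. residues from a
configurable background composition, and planted tripeptide occurrences
with an exact ledger:

* Plants are placed at uniformly drawn offsets with at least one
  background residue between consecutive plants. In **accidental-free**
  mode the background alphabet excludes every residue used by a planted
  peptide, so any window other than a planted one contains at least one
  background residue and can never spell a planted peptide: the ledger
  count is provably the true count. Overlap behaviour of the matcher is
  exercised separately with hand-written micro-sequences (e.g. `AAA` in
  `AAAA`), which the generator deliberately never produces.
* One integer seed drives a single explicit stream, and the caller's RNG
  state is saved and restored, so fixtures are byte-reproducible.
* `make_paper_like_fixture()` builds the default test world: about 20
  proteins and 2,000 residues across all 7 categories — the study
  proteome at roughly one-hundredth scale, a size at which the whole
  suite re-runs in seconds — and a 10-peptide database. Its 4 catch-all
  (XXX) peptides are the published ones (LVQ, LVE, IWH, GPM); the 6
  fillers (IPP, VPP, HLP, MEG, WIL, QGV) are synthetic and were chosen so
  the 10 peptides use only 10 distinct residues, leaving a 10-letter
  background alphabet in accidental-free mode. Composition-convergence
  checks use 100 proteins of 500 residues (50,000 residues, matching the
  real proteome's scale), where the binomial standard error per residue
  frequency is about 0.1 percentage points against a 0.5-point test
  tolerance.

What the generator does **not** emulate: codon usage, real motif
clustering (in real proteins tripeptide occurrences are far from i.i.d.),
homology between the two compared proteomes, length-composition
correlations, and non-standard residues. Passing the synthetic suites
therefore demonstrates that the machinery counts, classifies and
aggregates correctly — not that any particular real proteome is enriched
for active peptides.

## Validation against the published numbers

The study's absolute counts (751 matches in the study proteome, 742 in
the comparator) depend on the full deposited annotation and database
snapshot, so they cannot be recomputed at desk scale. What can be — and
is, in `tests/testthat/test-acceptance.R` and `analysis/05` — is every
quantity derivable from the printed tables, which ship under
`inst/extdata/` as clearly labelled literature values:

* all 21 printed peptide-density values follow from their printed
  numerators and denominators under half-up rounding;
* cross-table totals agree (photosystem subcategories sum to 177; the
  comparator's categories sum to 742; category residue totals sum to
  50,333; database classes sum to 89 with 4 catch-all peptides);
* one documented inconsistency is asserted *as published*, not repaired:
  the study table's 12 class rows sum to 753 against its printed grand
  total of 751. Similarly, the source prints both 192,409 and 192,410 nt
  for the same genome; `summarize_genome()` reports whatever the record
  contains and does not arbitrate.

The matcher itself is validated property-style: equivalence with an
independent regex-lookahead oracle on hundreds of random proteomes in both
counting modes, additivity of tabulation over disjoint protein sets, and
cell-for-cell ledger recovery on accidental-free fixtures across all three
groupings.

## Degenerate inputs and tie-breaks

Empty peptide tables, hit-free scans and empty categories produce empty
(all-zero) tables, not errors; densities of empty groups print 0.00 while
a zero residue total is an error for the scalar `peptide_density()`. Scan
output ordering is deterministic (protein input order, then position, then
peptide), which makes diffs and checksums meaningful. Classification is
total by construction; schema violations (duplicate symbols) are errors at
load, not at use.

## A worked example

```{r example}
gen <- make_paper_like_fixture(seed = 42)
peps <- filter_by_ic50(gen$peptides, 20)
hits <- scan_proteome(peps, gen$proteins)
tab <- tabulate_hits(hits, gen$proteins, grouping = "category")
tab
rel <- annotate_releasability(hits, gen$proteins)
mean(rel$fully_releasable)
```

## Limitations

* Matching is exact: no near-matches, no di-/tetra-peptides (the
  tripeptide restriction is deliberate, to avoid over-counting), and no
  activity prediction for unlisted sequences — IC50 values are looked up,
  never extrapolated.
* The releasability model is a binary boundary test, not a proteolysis
  simulation; it cannot rank enzymes or predict yields.
* Whether a published grand total counts positional occurrences or unique
  peptide-protein pairs is not stated in the source; both modes are
  provided, and internally consistent totals are reported rather than any
  constant reproduced by construction.
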