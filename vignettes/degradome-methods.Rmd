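---
title: "Methods: building and annotating a proteolytic degradome atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and annotating a proteolytic degradome atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neurofilament proteins (the heavy, medium and light chains NfH/NfM/NfL,
alpha-internexin and peripherin) reach body fluids as proteolytic
fragments, and essentially all quantitative neurofilament biomarker assays
measure some subset of those fragments. Which fragments exist, which are
shared between the five subunits and which are subunit-specific determines
what an antibody pair or a mass-spectrometric assay can and cannot claim
to measure. This package computes that fragment landscape exhaustively:
every peptide that can arise from the known endoprotease and chemical
cleavage specificities, with all partial (missed-cleavage) products
retained.

## Cleavage-site model

A cleavage site is an inter-residue bond; we report it by the 1-based index
of the residue N-terminal to the bond (P1). Specificity is modelled as
context patterns over the slots P6..P2' around the scissile bond, with
required residue sets, forbidden residue sets, alternative patterns per
reagent, and veto (exception) patterns — the grammar used by the
PeptideCutter documentation, including the Keil-rule exception table for
trypsin, the caspase tetrapeptide motifs and the pH-dependent pepsin
variants (counted as two reagents). The packaged table
(`inst/extdata/cleavage_rules.tsv`) is the source of truth: it is plain
TSV, human-auditable, and a discrepancy against a reference site list is
fixed by editing the table, not the scanner.

Two boundary conventions are implemented:

* **compat** (default): positions `1..L` are admitted; a pattern may match
  at the last residue when its C-terminal slots are unconstrained or
  forbidden-only. An unfilled slot (before residue 1 or after residue `L`)
  satisfies a forbidden constraint and fails a required one. This is the
  convention that reproduces the published per-position site lists shipped
  in `inst/extdata/published_site_positions.tsv` (e.g. the C-terminal
  lysine of NfH is listed there as a site).
* **strict**: positions `1..L-1` only, so that every site corresponds to a
  physical bond. A site at `L` adds no enumeration boundary either way, so
  the two modes differ only in the reported site count `x`.

### Calibration against the published site lists

With the default table the scanner reproduces the published position lists
for NfH, INA and PRP exactly (positions and per-position enzyme
multiplicities), and NfM exactly in positions with a single multiplicity
difference at position 439, where both LysN and proline-endopeptidase
match the `K-P-K` context but the published list counts one enzyme.

The published NfL list is a different matter. It is reproduced *exactly* —
every position and every multiplicity — only if thermolysin, trypsin and
staphylococcal peptidase I are excluded and proteinase K is truncated
after position 512. Those reagents demonstrably fired in the other four
published lists, so the published NfL run used a reduced reagent set,
inconsistent with its siblings. This package applies one rule table
uniformly to every record; under the full table NfL has `x = 491` distinct
sites rather than the published 457. Downstream consequences (the
theoretical degradome total, the site-count-versus-length regression and
the NfL pool means shift accordingly) are accepted rather than patched,
and the acceptance suite asserts the published values where they are
reproducible and leaves them failing where they are not.

## Degradome enumeration

For `x` cleavage sites the boundary set is `{0}`, the in-sequence sites,
and `{L}`; every ordered boundary pair yields one fragment, excluding the
intact protein, giving

> Z = (x + 1)(x + 2) / 2 − 1

possible products. `count_possible()` evaluates the formula;
`enumerate_fragments()` materialises the fragments and is property-tested
against a brute-force double loop. When a site coincides with the last
residue (compat mode) it adds no boundary, so the enumerated count can be
lower than `Z`; both numbers are reported, labelled theoretical and
enumerated.

Deduplication operates at two levels, because repeated sequence (e.g. the
KSP-repeat regions of NfH/NfM) makes identical peptides arise from
different coordinates: within an isoform, coordinate duplicates collapse
to one distinct sequence (first occurrence kept, copies counted); across
isoforms, each distinct sequence carries the set of isoforms whose
degradome contains it. Sequences present in all panel members form the
pan set (reported at `min_len >= 5` by default — shorter shared peptides
exist but are too uninformative to report, though they stay in the atlas);
sequences present in exactly one member are the unique set, the natural
candidates for subunit-specific assays. Pan output is sorted by
descending length, ties broken lexicographically, so the longest shared
sequence is always first.

Scale: the five-isoform panel yields ~1.06 million coordinate fragments
and ~1.05 million distinct per-isoform sequences; the build holds them in
memory (a few hundred MB) and completes in well under a minute on one
CPU. Fragment ids are `"{isoform}:{start}-{end}"`; no attempt is made to
reproduce any external id numbering.

## Peptide properties

Properties are functions of the sequence alone; coordinate duplicates
share values, and the property table has one row per distinct per-isoform
sequence (the pools that the published summary statistics describe).
`annotate_atlas()` computes composition-dependent indices from cumulative
sums along the parent sequence, so each fragment costs O(1) regardless of
length; `peptide_properties()` recomputes the same quantities from the
peptide string, and the two routes are asserted equal in the tests.

* **Molecular mass**: sum of average residue masses plus one water
  (average masses match linear-TOF resolution; monoisotopic is available
  via `property_config(mass = "monoisotopic")`). `mz = mw + 1.008`
  ([M+H]+, positive mode).
* **Boman index**: length-normalised sum of per-residue binding-potential
  values (side-chain water/cyclohexane transfer free energies, kcal/mol,
  hydrophilic positive; proline, lacking a side-chain analog, scores 0).
  Values above 2.48 flag high interaction propensity. The sign convention
  is fixed by the threshold semantics: charged, assay-friendly pools
  average near 3.
* **Aliphatic index**: Ikai's relative-volume formula
  `(100/L)(nA + 2.9 nV + 3.9 (nI + nL))`; above 70 = thermostable.
* **Instability index**: `10/L` times the sum of Guruprasad dipeptide
  weights (DIWV); below 40 = stable; single residues score 0 (no
  dipeptides). Length-1 and length-2 peptides are computed literally from
  the formulas — the pools include every fragment, with no minimum-length
  exclusion.
* **GRAVY**: mean Kyte–Doolittle hydropathy.
* **Charge / pI**: Henderson–Hasselbalch over D, E, C, Y, H, K, R and the
  free termini. The default pKa set is Bjellqvist-style (the set common pI
  calculators use); EMBOSS values are available as a preset, because no
  single set is canonical. The charge column is evaluated at pH 7.0 by
  default — with that pH and pKa set the five-panel pool means agree with
  the published charge column to the printed precision, which is why those
  defaults were kept; pH 7.4 and the brain extracellular window
  (6.47–7.19) are the presets of interest for tissue questions. The pI is
  solved by bisection on (0, 14) to 0.001 pH units; monotonicity of charge
  in pH guarantees convergence.

Reproduction of the published pool table under these conventions: for
NfH, NfM, INA and PRP every index mean and threshold fraction matches the
printed values at printed precision; NfL means shift slightly (aliphatic
78.6 vs 80.0) because its pool is built from the full rule set, as
discussed above. Published pool sizes differ from ours by 0.2–1.3%
for the four consistent isoforms because the exact published
deduplication rule is not stated (and by ~16% for NfL, whose pool is
larger under the full rule set); pool sizes are therefore reported but
not asserted.

## Pool statistics and screening

`summarize_pool()` reports means, SDs and the threshold fractions.
`compare_pools()` uses Welch's unpaired t for two groups and one-way
ANOVA for three or more, with raw exact p values (no multiple-testing
correction, matching how such comparisons are conventionally reported for
these pools). A paired test is not meaningful between peptide pools of
unequal size, which is why the unpaired Welch form is used even where a
paired test is nominally described for two-group settings; group
comparisons on pools this large are significance calls, not effect
estimates. `sites_vs_length_regression()` is ordinary least squares of
site count on sequence length, with the F-test computed directly so a
perfect fit degenerates to p = 0.

`flag_aggregation_prone()` implements the aggregation screen as the
conjunction: instability < 40, aliphatic > 70, Boman < 2.48, and pI
inside the ambient window (default 6.6–7.9, the neuronal pH range) — a
peptide that is stable, weakly interacting and near-neutral where it
lives is the aggregation candidate. No aggregation-nucleation model is
shipped: `classify_apr()` delegates to a user-registered classifier and
errors when none is configured, keeping the workflow runnable with any
external predictor without silently standing in for one.

## Perturbations

`mutation_differential()` rebuilds the mutant record's degradome under the
same rules. *Gained* is defined against the complete wild-type atlas (all
isoforms), because the natural question is which mutant peptides are new
to the whole reference resource; *lost* are wild-type sequences of the
mutated isoform found neither in the mutant pool nor elsewhere in the
panel. Both are exact set differences, verified against brute-force
recomputation on toys. For a substitution at position p, only fragments
overlapping p or using a changed boundary can differ; everything outside
the context window is preserved verbatim (property-tested).

`inhibition_differential()` removes one reagent and rebuilds: site maps
and fragment sets shrink monotonically, and per-isoform, per-index
direction calls (up / down / unchanged) summarise the profile shift. The
direction-call significance level defaults to 1e-4 — the strictest level
used in the published direction matrices — rather than a looser nominal
0.01, so that a direction is only called on overwhelming evidence in
pools of 10^5 peptides; it is configurable.

Mutation grammar: `"G336S"` (substitution, reference residue verified
and mismatches refused), `"del@88"` / `"del@88-90"`, `"ins@88:AAA"`.
Nucleotide-level events are represented only by their protein-level
consequence. The NfM G336S substitution (position 336 carries the
glycine; a variant position sometimes quoted as 236 carries serine in the
canonical sequence and cannot be the site of a G-to-S change) yields
150,516 mutant-only distinct products against the full wild-type atlas
under the uniform rule table; the previously reported figure of 153,377
is 1.9% higher and could not be reproduced under any counting convention
we tried (distinct or coordinate level, with or without the NfL pool),
consistent with the NfL rule-set inconsistency documented above.

## Validation layer

`fragment_at()` answers whether a coordinate span is a boundary-delimited
member of a degradome. `match_sequences()` checks reported cleavage
products: exact-sequence membership, coordinate lookup, and — because
published products often have loosely reported termini — identity-level
containment within a panel protein. A reference whose printed sequence
and printed coordinates disagree (the packaged list contains one: a
24-residue published sequence recorded under a 20-residue span) is
reported as a conflict with both results, never reconciled silently; its
C-terminal boundary is not a cleavage site under any reagent, so the
24-mer can only ever be an identity-level, not an exact-fragment, match.
`match_mz()` matches observed peak lists against computed [M+H]+ values
(default tolerance 0.1% of m/z, appropriate for linear-TOF data;
configurable in Da or ppm) and flags isoform-unique candidates.
Repository-scale validation is reduced to list-level matching of
user-supplied peptide or peak lists; no downloading or raw-spectrum
processing is in scope.

## Synthetic data

`make_toy_fixtures()` generates small proteins (8–60 residues) for the
test surface: one with no cleavage sites (drawn from a G/S/Q alphabet
inert under the default table), one with a designed multiplicity-2 site,
and the rest random over the full alphabet. These toys exercise
combinatorics, dedup and perturbation logic at hand-checkable scale. They
do not emulate real protein composition (no low-complexity repeats, no
domain structure, uniform residue usage), so passing toy tests shows
correctness of the set operations, not realism of the peptide pools; the
realism checks are the whole-panel comparisons against the published
tables in the acceptance suite.

## Problem sizes and tolerances used in the tests

The oracle suites run 1000 random enumeration toys and 25 random
site-scan toys per run; the five-isoform acceptance path builds the full
atlas once (shared across tests), annotates ~1.05 million peptides, and
runs one complete mutation differential. Mass agreement with an
independent calculator is asserted to 0.01 Da, instability to 2 decimals,
charge and pI to 0.05 (the oracle uses slightly different terminal pKa
handling), and the pI bisection tolerance is 0.001.

## Known limitations

* Specificity rules cover the reagents of the packaged table; proteases
  absent from it (calpains, the CRL3–gigaxonin/USP15 route) are absent
  from the atlas, and cleavage is all-or-none — no kinetics, no
  probabilistic efficiency, no PTM modulation of cleavage.
* Uniqueness and pan classes are exact-sequence statements within the
  panel; similarity-level cross-reactivity (alignment against a full
  proteome) is out of scope.
* Properties ignore post-translational modifications; a phosphorylated
  serine changes both mass and charge in reality but not here.
* The published reference tables shipped for calibration contain the
  internal inconsistencies documented above; where they conflict with the
  uniform method, the package follows the method and says so.
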