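---
title: "Quantifying tRNA–synthetase binding surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tRNA–synthetase binding surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnasurf)
library(tibble)
```

trnasurf turns a co-crystal structure of a transfer RNA bound to its
aminoacyl-tRNA synthetase (aaRS) into a quantitative, comparable description
of the binding surface, and pairs that description with an evolutionary
conservation profile of the tRNA positions. This vignette explains the
models behind each step, the parameters that matter, and the choices made
where the methodology was genuinely open.

## The interface model: minimum atom-set distance

Whether a ribonucleotide and an amino acid "interact" is decided by the
minimum atom-set distance

$$\mathrm{distance}(X, Y) \;=\; \min\{\, d(x, y) : x \in X,\ y \in Y \,\},$$

where $X$ is the set of all atoms of the amino acid, $Y$ the set of all
atoms of the ribonucleotide, and $d$ the Euclidean distance in Å. A pair
interacts when this distance is **at or below 3.3 Å** (equality counts;
comparisons carry a $10^{-9}$ float slack). The threshold is a property of
the method, selected by sweeping 2.0–5.0 Å in 0.1 Å steps
(`threshold_sweep()`) and inspecting where the interface stabilizes: below
3.3 Å true interface residues drop out; above it, residues beyond the
contact surface (and eventually the complementary strand of paired stems)
leak in. The mean Cα–Cα spacing of a folded protein, about 3.8 Å, is a
natural upper bound. The threshold remains a parameter everywhere
(`find_contacts(model, threshold = )`).

Hydrogens, when deposited, participate in the distance calculation — the
definition is over *all* atoms — and can be excluded with
`keep_hydrogens = FALSE` at parse time, since most crystal structures lack
them and mixing policies across a corpus shifts counts. Waters and
non-covalent ligands (including the amino-acid or AMP substrate in the
catalytic pocket) belong to neither $X$ nor $Y$: the model is about the
tRNA polymer against the enzyme polymer.

The implementation computes the full ribonucleotide × amino-acid
set-distance matrix by vectorized block operations
(`set_distance_matrix()`); every downstream quantity — contact lists,
sweeps, per-position profiles, summary counts — is a view of this one
matrix, which makes internal consistency (e.g. sweep counts at 3.3 Å equal
`find_contacts()` counts) structural rather than accidental. Tests hold the
production path bit-identical to an exhaustive double loop over residue
pairs.

## Structures: parsing policies that move counts

Interface counts are only comparable across entries under a fixed parsing
policy. The policies, all explicit arguments with these defaults:

* **First biological assembly.** Synthetases often function as dimers whose
  functional unit exists only after applying the crystallographic symmetry
  operators (REMARK 350 BIOMT records). When assemblies are declared, the
  *first* one is reconstructed (`apply_first_assembly()`); operator 1
  transforms in place, later operators generate copies under fresh chain
  labels. Without BIOMT records the asymmetric unit is used as-is.
* **One tRNA, all protein chains.** If the assembly contains several tRNA
  copies, the first tRNA chain in file order is analyzed — symmetry copies
  show essentially identical interaction patterns, which the test suite
  verifies on constructed duplicates. All protein chains count, so dimer
  partners contribute to the amino-acid totals.
* **Alternate locations.** The highest-occupancy altloc wins; ties break by
  altloc character order. This is the dominant community convention; the
  depositing experiment does not dictate one.
* **Chain typing at 90% purity.** A chain is tRNA (protein) when at least
  90% of its residues are ribonucleotides (amino acids), which tolerates
  modified residues (pseudouridine, 4-thiouridine, selenomethionine, ...)
  recognized through a shipped vocabulary that also maps them to parent
  bases. Unknown residue names become `other` and are excluded with a
  message. HETATM residues bearing a *standard* amino-acid name are treated
  as free substrate ligands, not polymer.
* **First MODEL only**, and mmCIF input is rejected rather than guessed at.

Totals ("of 73 ribonucleotides") count residues *present in the crystal*,
because the denominators describe what the structural experiment could see.

## Surface residues

The enzyme's surface universe is defined by relative accessible surface
area: per-residue ASA divided by a per-residue-type theoretical maximum.
ASA is computed by Shrake–Rupley sphere sampling — 960 deterministic
golden-spiral points per atom, probe radius 1.4 Å, Bondi van der Waals
radii — on the protein component alone (the tRNA removed), since the
surface universe is a property of the enzyme; `context = "complex"` keeps
all occluders. An isolated residue exceeds its in-chain reference maximum,
so RSA is capped at 1.

The selection criterion is printed in this field as "RSA < 20%", although
the usual convention calls a residue *exposed* at RSA ≥ 20%. Both
directions are first-class (`surface_residues(direction = "below")` is the
default, mirroring the printed inequality) and the choice is surfaced
rather than silently "fixed" — flipping it changes the normalization
universe, not the contact counts.

## Universal coordinates and the fifteen regions

Cross-complex comparison needs a common coordinate system: the universal
(Sprinzl) tRNA numbering, positions 1–76 with optional D-loop insertions
17a/20a/20b and `e`-prefixed labels for long variable arms. Positions are
assigned from the cloverleaf secondary structure
(`assign_from_secondary_structure()`): the acceptor stem 5′ side takes
1–7, the two inter-stem residues 8–9, the D-stem 10–13 / 22–25 around the
D-loop, position 26, the anticodon stem 27–31 / 39–43 around the 7-nt
anticodon loop 32–38 (center = 35), the variable region from 44, the
T-stem 49–53 / 61–65 around the 7-nt T-loop 54–60, the acceptor 3′ side
66–72, and the discriminator plus CCA 73–76.

Two fill rules are declared conventions, because the universal rule leaves
unusual loop sizes open:

* **D-loop.** The 8-nt core carries 14–21. Surplus nucleotides insert as
  17a, then 20a, then 20b; when the loop carries the conserved G18–G19,
  the allocation that keeps G,G at 18–19 is preferred. Deficits drop 17
  first, then 20. The rules are deterministic and enumerated in tests for
  loop lengths 6–11.
* **Variable region.** Up to 5 nucleotides map to 44–48. Longer V-arms
  (Ser/Leu/Tyr-type) keep 44–48 for the first five and label the overflow
  e1, e2, ... 5′→3′. Since `e`-positions are excluded from all region
  statistics, only their count matters, so the package does not reproduce
  the full historical e-numbering grid.

Secondary structure is an *input* (dot-bracket or scanner-style `>`/`<`
strings); covariance-model gene finding is out of scope. A tRNA is
*canonical* when every arm is within the universal bounds (7 bp acceptor
stem, 3–4 bp D-stem, 5 bp anticodon and T-stems, 7-nt anticodon and
T-loops, ...); `is_canonical()` returns the violation list instead of a
bare flag.

Crystallized tRNAs are often incomplete or engineered, so crystal sequences
are matched to their full-length genomic originals by global alignment
(match +1, mismatch −1, gap open −4, extension −1 per position, i.e. a
length-$k$ gap costs $4 + k$ — the convention of the alignment backend,
adopted so the implementation and the independent dynamic-programming
oracle in the tests agree exactly). Crystal positions inherit the labels of
their aligned original positions (`transfer_labels()`); a best-hit library
search (`find_original_sequence()`) stands in for a full sequence-database
search, with an 85% identity floor instead of an E-value cutoff — the
libraries involved are small enough for exhaustive scoring.

The fifteen regions S1–S15 partition positions 1–76: acceptor stem S1
(1–7) and S14 (66–72), inter-stem S2 (8–9) and S6 (26), D-stem S3 (10–13)
and S5 (22–25), D-loop S4 (14–21), anticodon stem S7 (27–31) and S9
(39–43), anticodon loop S8 (32–38), variable region S10 (44–48), T-stem
S11 (49–53) and S13 (61–65), T-loop S12 (54–60), CCA S15 (73–76).

## Region scores, missing data, clustering

The per-region interacting score sums the number of interacting amino
acids per ribonucleotide over the region and normalizes by the number of
ribonucleotides in the region. Crystallographically undetermined positions
are excluded from the sum, and a region with **25% or more** undetermined
positions (inclusive) is itself reported undetermined. The normalization
denominator is the *determined* position count by default: the wording
"normalized to the number of ribonucleotides in the sequence region"
admits either reading, and determined-only is the one consistent with
"undetermined positions were excluded from the calculation"; the
full-length denominator is available as `denominator = "all"`. With the
default, the identity $\sum_r \text{score}_r \times n^{det}_r = $ (total
interacting incidence over determined, non-`e` positions) holds exactly
and is property-tested.

Across complexes, the score vectors form a complexes × 15 matrix with
missing entries. Distances are one minus the Pearson correlation over the
regions determined in **both** vectors (pairwise-complete observations,
`stats::cor(use = "pairwise.complete.obs")` — checked against a longhand
recomputation). A pair sharing fewer than 3 regions, or with zero variance
in the shared set, has no defined distance; such distances are imputed
with the matrix maximum before linkage so incomparable complexes merge
last, and the imputation is logged. Clustering is complete linkage
(furthest neighbor) via `stats::hclust`, with rows pre-sorted by accession
so ties resolve deterministically; the merge sequence is tested against a
naive agglomerative reference. One representative complex per cognate
amino acid — fewest undetermined positions, ties to the lower accession —
keeps over-represented complexes from dominating; a group whose best
representative still exceeds 3 undetermined positions is kept but flagged,
since dropping it silently would bias the corpus.

For display, scores are normalized per domain of life to the domain's
maximum (`normalize_heat_ranks()`), so 1.0 means "the strongest
region–enzyme interaction seen in that domain".

## Conservation: per-position entropy in nine ranks

Within one isoacceptor group (tRNAs charged with the same amino acid —
never across groups, whose anticodons differ by construction), sequences
are stacked positionally on their universal labels; no heuristic multiple
alignment is run, the numbering *is* the alignment. Records must pass
three filters (`filter_records()`): not a pseudogene, canonical cloverleaf,
bases only A/U/G/C. Identical (species, isoacceptor, sequence) triplets
collapse to one — genomic copy number is not evidence of conservation —
while *distinct* sequences of one species are all kept (a
`one_per_species` switch covers the stricter reading).

Per position $l$, conservation is Shannon entropy over the base
frequencies $f(b,l)$ of the non-gap observations:

$$H(l) = -\sum_{b \in \{A,C,G,U\}} f(b,l)\, \log_2 f(b,l),$$

with $0 \log 0 = 0$; gaps are skipped, not counted as a fifth symbol.
$H$ ranges 0 (one base observed) to 2 bits (uniform). The 3′ CCA (labels
74–76, added post-transcriptionally and not always genomically encoded)
and `e`-labels are excluded; optional labels missing from a sequence are
gaps there.

The entropy is binned into **nine ranks**: equal-width bins over the
theoretical range [0, 2] bits, rank 9 = the bin containing 0 (most
conserved), rank 1 = the bin containing 2 (most variable), boundary values
falling to the more-conserved rank. The named color scheme of this field's
conservation displays fixes the orientation; the *edges* are a declared
convention, as the display tools in circulation use a different, data-
dependent binning. Region-level summaries are means of ranks with their
standard errors, and `interaction_vs_conservation()` pairs them with the
region interaction scores. Published region averages from any specific
sequence-database snapshot are snapshot-dependent; the package's contract
is to emit the per-position and per-region tables so they can be
recomputed against any snapshot.

## The synthetic study system

Everything above is testable without downloads because the generator
plants ground truth:

* `make_synthetic_complex()` realizes a blueprint of `n_rib`
  ribonucleotides (minimal P/C1′/N9/O2′ atom sets, valid PDB records) and
  `n_aa` alanines on a 30 Å lattice with ±0.3 Å jitter, then translates
  each planted pair so its minimum atom-set distance equals the target
  *exactly* (the amino acid's anchor atom sits precisely `d` beyond the
  ribonucleotide's extreme atom along x, every other atom strictly
  farther). Non-planted pairs are ≥ 13 Å apart by construction, planted
  distances are capped at 12 Å, and one residue cannot carry two planted
  contacts — the generator refuses infeasible geometry rather than
  emitting a fixture whose manifest might lie. Undetermined positions are
  simply omitted from the emitted structure but kept in the assignment.
* `make_synthetic_trna_set()` draws sequences independently per position
  from blueprint base distributions (plus optional gap probabilities), so
  the analytic entropy of every column is known in closed form
  (`blueprint_entropy()`) and estimator recovery can be checked at 3σ
  using the delta-method standard error plus the first-order plug-in bias
  bound $(k-1)/(2n\ln 2)$.

What the fixtures deliberately do **not** emulate: stereochemically
plausible geometry, base pairing in 3D, crowded interfaces where one
residue touches many, altloc/occupancy pathologies beyond the constructed
cases, or covariation between positions. Passing tests therefore
demonstrate the *bookkeeping and the mathematics* are right — thresholds
applied inclusively, masks propagated, estimators unbiased — not that any
biological conclusion holds; for that the pipeline must be run on real
deposited structures, for which it carries the exact policies above.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately small
instances — complexes of 10–30 ribonucleotides against 10–20 amino acids
(100 seeded replicates for the generator-as-oracle check), sequence sets
of 500 for entropy recovery and 4000 for the uniform-limit check, corpora
of 6 complexes for clustering — sizes at which the exhaustive oracles are
instant while every code path is exercised. Real entries (~80 nt × ~900
aa) take seconds through the same vectorized path.

Degenerate inputs are decided, not accidental: an empty atom set is a
domain error for `set_distance`; an all-gap column has no entropy and
coverage 0; a region with no determined positions is undetermined rather
than 0; a clustering in which *every* pairwise distance is undefined
aborts; entropy values outside [0, 2] beyond float slack are an error
rather than clamped silently. Non-right-handed BIOMT rotations are applied
with a warning — mirror operators in deposited files are almost always
deposition errors worth surfacing, but refusing them would block the
entry entirely.
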