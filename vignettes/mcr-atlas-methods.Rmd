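---
title: "Methods: mining and characterizing archaeal MCR complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing archaeal MCR complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcratlas)
```

# Scope and scientific background

Methyl-coenzyme M reductase (MCR) catalyzes the final step of
methanogenesis and, run in reverse, the first step of anaerobic methane
oxidation. The enzyme is an (αβγ)₂ hexamer with a molecule of the
nickel tetrapyrrole coenzyme F430 in each of its two active sites.
MCR homologs (ECRs/ACRs) occur across uncultured archaeal lineages —
ANME clades and alkane-oxidizing ANKA — whose enzymes can only be
studied through heterologous expression in a methanogenic host.

`mcratlas` implements the computational backbone of such a study as a
tested pipeline: (i) mining *mcr* operons from genome annotations and
homology-search tables; (ii) deconvoluting native electrospray
charge-state series into intact-complex masses and assigning subunit
stoichiometries; (iii) quantifying host-versus-recombinant subunit
chimerism from label-free peptide peak areas, with post-translational
modification bookkeeping; (iv) quantifying coenzyme F430 and active-site
occupancy; and (v) scoring docking models with CAPRI-style interface
RMSD. Wet-lab protocols, the homology/docking engines themselves
(tblastn, CheckM, RosettaCM/RosettaDock), and phylogenetic inference are
out of scope: their tabular and PDB outputs are this package's inputs.

# Operon mining

## Model and thresholds

Genomes enter the analysis when CheckM-style completeness is strictly
above 80% and contamination strictly below 10%. Homology hits (tblastn
outfmt-6 tables, queried with the five MCR subunits A, B, C, D, G from
two reference methanogens) are kept when the E-value is at most 1e-5 —
equality is retained, only strictly larger values are excluded. Each
subject gene takes the subunit of its highest-bitscore hit; ties break
by lowest E-value and then alphabetically, so assignment is
deterministic. The paper trail for a multi-hit gene is preserved in the
`best_bitscore`/`best_evalue` columns.

Operon recognition chains subunit-assigned genes that share a contig
and strand: with 1-based inclusive coordinates, the gap between
adjacent genes is `start_next − end_prev − 1`, and a pair is merged iff
that gap is strictly smaller than 250 bp. Genes without a subunit
assignment are invisible to the chaining. On the minus strand the
member list is reversed so the reported pattern always reads 5′→3′ on
the coding strand. Patterns map onto canonical architectures by exact
match (`BDCGA`, `BDGA`, `BGA`, `BAG`); everything else — permutations,
singletons, or chains with repeated subunits such as `BGABGA` — is
`unusual` rather than being split heuristically.

Design choices where conventions genuinely diverged:

* **Overlapping genes** (negative gap) merge with the gap clamped to 0;
  a negative intergenic distance should never split a real operon.
* **Complete-set counting** (`has_complete_set`) asks for at least one
  gene each assigned A, B, and G *anywhere in the genome*, not within a
  single operon — a genome with *mcrB…G* on one contig and *mcrA*
  elsewhere still encodes the catalytic set. The per-genome copy count,
  by contrast, counts operon calls containing at least one of A/B/G.
* **Category labels** (methanogen / ANME-1 / ANME-2 / ANKA / unknown)
  come from a user-supplied mapping file; inferring metabolism from
  taxonomy is deliberately not attempted.

## Verification strategy

The chaining algorithm is checked against a brute-force oracle that
starts from singleton clusters and merges any mutually adjacent pair
below the threshold until a fixpoint — a deliberately different
formulation — on 200 seeded synthetic genomes, including split operons.
Property tests cover the strict 249/250 bp boundary, strand symmetry
(mirroring a contig and flipping strands preserves every pattern), and
monotonicity (raising the gap threshold never shrinks an operon;
lowering the E-value cutoff never adds assignments).

# Native mass spectrometry

Each charge-state peak converts to a neutral mass as
`mass = z·(m/z) − z·m_proton`, and a series is summarized by the mean
and sample (n−1) standard deviation across peaks; a single peak reports
sd 0. The proton mass defaults to 1.007276 Da; a config switch restores
the integer-proton form of the formula, whose difference (~2 Da at
~288 kDa) is far below the 0.1 kDa precision at which such masses are
reported. The n−1 denominator is a choice the data cannot distinguish
at n = 4–5 peaks.

Charge inference automates manual assignment for consecutive series:
the spacing of the two highest-m/z peaks fixes the charge of the
lower-m/z one via `z = round((mz_high − m_proton)/(mz_high − mz_low))`,
and candidate consecutive ladders near that estimate are scored by the
relative dispersion of implied masses. A wrong ladder inflates the
dispersion to roughly 1/z (percent scale), while 5 ppm m/z noise keeps
the correct one near 5·10⁻⁶, so the default acceptance ceiling of 10⁻³
separates the two regimes by orders of magnitude rather than sitting
near either.

Stoichiometry assignment enumerates all copy-number vectors within
per-component bounds, applies group-sum constraints (e.g. tagged and
untagged γ subunits jointly filling exactly two G slots), keeps
compositions within the mass tolerance (default 0.1% of the observed
mass, matching 0.1 kDa reporting at ~288 kDa), and ranks by absolute
mass deviation with a lexicographic tie-break. The enumeration is
capped (10⁶ candidates) and refuses oversized spaces rather than
silently truncating. The F430 mass enters as a configured constant;
tests use synthetic component masses so no literature mass is baked in
as truth.

Sequence masses use standard average (ExPASy) or monoisotopic (Unimod)
residue tables plus water and optional modification deltas — average
for intact complexes, monoisotopic for peptide-level work.

# Chimerism quantification

A heterologously expressed MCR can incorporate the untagged host
ortholog of a subunit. Identified peptides are attributed by exact
substring membership in the host and recombinant ortholog sequences:
host-unique, recombinant-unique, shared, or unmapped. Digestion rules
are not simulated — identifications arrive pre-digested from an
upstream search engine. The host fraction per construct is the ratio
of combined host-unique peak areas to total origin-unique area, and
results are reported as mean ± sample SD across constructs, the form
in which chimerism figures are quoted (e.g. 30 ± 6% host McrG).
Shared (ortholog-identical) peptides are excluded from the ratio: the
upstream engine attributes their area to both proteins, and counting
them on either side would double-count signal; exclusion is the
conservative label-free convention.

The ratio-of-sums estimator is exactly scale invariant and, on
lognormal area noise at the study's spread (σ_log = 0.5, ~30 peptides
per side), its bias is an order of magnitude below the Monte-Carlo
standard error of 1000 replicates — the property the test suite
asserts.

PTM bookkeeping reports, for each expected site (thioglycine,
1-N-methylhistidine, 5-(S)-methylarginine, 2-(S)-methylglutamine),
whether a covering peptide carries the expected mass shift within a
0.01 Da tolerance (`detected`), is covered without it
(`not_detected`), or is never covered (`no_coverage`).

# Cofactor quantification

F430 concentration follows Beer–Lambert at 430 nm with
ε = 22,500 M⁻¹cm⁻¹ and a 1 cm path. Quantification uses 430 nm — the
free-cofactor absorbance maximum to which the extinction coefficient
refers — although the holoenzyme absorbs maximally at 425 nm; the
wavelength is recorded in output metadata. Occupancy divides the
cofactor:complex molar ratio by the two active sites of the (αβγ)₂
architecture; a ratio more than 5% above two sites triggers a
super-stoichiometric warning. Because a "reduced F430 content" can be
read either as per-complex occupancy or as total yield, both the
occupancy and its complement (reduction) are reported rather than
collapsing the two readings. HPLC quantification fits an ordinary
least-squares line through authentic-standard points and inverts
unknown areas through it.

# Docking-model quality

The interface of a two-group complex is every residue with at least
one heavy atom (all elements except H/D) within 8 Å — inclusive, "at
most" — of a heavy atom of the other group. I_rmsd detects the
interface **on the reference only** (the CAPRI convention; computing
it on the model would let a bad model choose its own, flattering
interface), matches heavy atoms by (chain, residue number, atom name)
with unmatched atoms dropped and counted, superposes the matched set
with SVD-based Kabsch (reflection-corrected, so rotations are always
proper), and reports the post-superposition RMSD. Quality classes bin
I_rmsd half-open: [0,1) high, [1,2) medium, [2,4) acceptable, [4,∞)
incorrect — the class boundaries themselves fall to the lower-quality
class, a convention fixed here because strict inequalities on both
sides leave the boundary undefined. Collinear coordinate sets are
refused (the rotation is not identifiable), and alternate locations
resolve to the highest-occupancy conformer.

The independent test oracle recomputes I_rmsd by an O(n²) all-pairs
interface scan and quaternion-eigenvalue superposition — a different
algorithm on both steps — and agreement is required within 10⁻⁶ Å.
Rigid invariance is asserted under random rotations/translations of
model and reference alike. Ligand-proximal listing (e.g. residues
within 8 Å of F430) uses the same inclusive heavy-atom rule.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of one seed, fanned out to fixed
per-stage substreams so adding a stage never perturbs another's data.
The defaults encode the study conditions:

| block | default | rationale |
|---|---|---|
| operon gaps | uniform 20–240 bp | inside the 250 bp rule, typical archaeal intergenic spacing |
| split gaps | 250–800 bp | at/beyond the rule, forcing a split |
| true-hit E-values | 10⁻¹⁸⁰–10⁻²⁰ | orthologs of a highly conserved enzyme |
| decoy E-values | 10⁻⁴·⁹–10⁰ | above the 1e-5 retention cutoff |
| complex mass / charges | 288,400 Da at z 28–32 | the reported complex-I window |
| m/z noise | 0 (configurable ppm) | peak lists are already centroided upstream |
| host fraction | 0.30, σ_log 0.5, 3 constructs, 30 peptides/side | the reported McrG chimerism and typical label-free spread |
| ε₄₃₀ | 22,500 M⁻¹cm⁻¹ | the quantification constant |
| toy complex | 2×30 residues, strands ~5 Å apart | small enough for O(n²) oracles, real contact interface |

Synthetic genomes plant one operon each with configurable architecture
mix, decoy genes, QC-failing genomes, and operon splits; sequences are
random over standard alphabets (no real database sequences are
embedded), and peptide "proteomes" are assembled around the planted
peptides so substring classification provably recovers the planted
origins. What the simulator does **not** emulate: phylogenetic
structure among genomes, codon/composition bias, chromatographic or
spectral peak shapes, isotope envelopes, tryptic digestion chemistry,
and real protein geometry beyond a contact interface. Passing tests
therefore demonstrate algorithmic correctness against planted truth
and printed anchors — not robustness to annotation errors, search-engine
misidentifications, or detector artifacts in real data.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for interactive runs:
200 genomes for oracle equivalence, 120 for planted recovery, 1000
replicates for deconvolution bias and host-fraction bias, 150 series
for charge recovery, 500 stoichiometry cases against exhaustive
enumeration, and toy complexes of 60 residues. Genome-scale results
(the 1070-genome QC set and 307 *mcr*⁺ genomes of the source survey)
require the GTDB r95 archaeal genome download and are not recomputed
here; the QC and counting rules they rest on are exercised exactly at
the smaller scale. Docking-energy scores (Rosetta REU) depend on an
external engine and are likewise out of scope.

Numerical conventions collected in one place: sample (n−1) SDs
everywhere a dispersion is reported (0 for n = 1); strict QC
inequalities; inclusive E-value and interface cutoffs; strict 250 bp
gap rule; boundary I_rmsd values to the lower-quality class;
deterministic tie-breaks (bitscore → E-value → alphabet for subunits,
|Δmass| → lexicographic counts for compositions); overlap gaps clamped
to 0; altloc by highest occupancy.

# A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1)
manifest <- run_pipeline(cfg)
str(manifest$outputs$scan$rows)
```

The manifest records the config snapshot, per-stage row counts, and
MD5 checksums of every file written; rerunning the same config yields
byte-identical tables.
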