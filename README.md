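# mcratlas

Tools for studying methyl-/alkyl-coenzyme M reductase (MCR/ACR)
complexes of archaea — the enzymes that make and anaerobically oxidize
methane. The package is aimed at microbiologists and biochemists who
mine *mcr* gene clusters from genome collections and characterize
heterologously expressed MCR complexes, and it covers five analysis
stages behind one seeded, fully testable pipeline:

1. **Operon mining** — genome QC (completeness > 80%, contamination
   < 10%), E-value filtering of tblastn-style hits (keep E ≤ 1e-5),
   best-bitscore subunit assignment, chaining of same-contig/same-strand
   *mcr* genes when the intergenic gap is < 250 bp, architecture
   classification (*mcrBDCGA*, *mcrBDGA*, *mcrBGA*, *mcrBAG*, unusual),
   and per-genome *mcr* copy counting.
2. **Native mass spectrometry** — charge-state deconvolution
   (mass = z·(m/z) − z·m_H⁺, mean ± sd across a series), automatic
   charge inference for consecutive series, and subunit-stoichiometry
   assignment by bounded enumeration with group-sum constraints
   (e.g. tagged + untagged γ filling exactly two G slots).
3. **Chimerism quantification** — host vs. recombinant subunit
   fractions from combined label-free peptide peak areas of
   origin-unique peptides, plus PTM site bookkeeping (thioglycine and
   the three methylation sites of McrA).
4. **Cofactor quantification** — coenzyme F430 by Beer–Lambert
   (ε₄₃₀ = 22,500 M⁻¹cm⁻¹) and HPLC standard curves; active-site
   occupancy of the two-site (αβγ)₂ complex.
5. **Docking-model QC** — CAPRI-style interface detection at 8 Å,
   Kabsch superposition, interface RMSD (I_rmsd), quality classes
   (high < 1 Å ≤ medium < 2 Å ≤ acceptable < 4 Å ≤ incorrect), and
   ligand-proximal residue listing.

A synthetic-data module generates seeded fixtures with planted ground
truth for every stage (GFF3, BLAST tabular, CSV peak/peptide tables,
PDB toy complexes), and `run_pipeline()` orchestrates the stages with a
deterministic manifest. See `vignettes/mcr-atlas-methods.Rmd` for the
full methods account.

## Worked example

```r
library(mcratlas)

# mine operons from a seeded synthetic genome set
sim    <- gen_genome_set(sim_config(seed = 42, genome = list(n_genomes = 6)))
mining <- mine_operons(sim$genomes, sim$features, sim$hits)
mining$operons[, c("genome_id", "strand", "n_genes", "pattern", "label")]
#>    genome_id strand n_genes pattern    label
#> 1 synth_g001      +       3     BGA   mcrBGA
#> 2 synth_g002      +       5   BDCGA mcrBDCGA
#> 3 synth_g003      +       3     BGA   mcrBGA
#> 4 synth_g004      +       5   BDCGA mcrBDCGA
#> 5 synth_g005      -       3     BGA   mcrBGA
#> 6 synth_g006      -       3     BAG   mcrBAG
```

Each row is one called gene cluster; `pattern` is the subunit order
read 5′→3′ on the coding strand, and `label` its canonical
architecture. All six genomes carry a complete catalytic set (A, B, G)
in one copy (`mining$summary`).

```r
# deconvolute a native charge-state series (planted 288,400 Da,
# z = 28..32, 5 ppm m/z noise), inferring charges from peak spacing
peaks <- gen_charge_series(sim_config(seed = 42,
                                      mass = list(ppm_noise = 5)))$peaks
est <- deconvolve_series(infer_charges(peaks$mz))
est
#> mass 288399.9 +/- 0.8 Da (n = 5 peaks)

# assign a stoichiometry: two G-slots shared by tagged (h) and
# untagged (gamma) subunits
comps <- component_spec(
  name      = c("alpha", "beta", "h", "gamma", "f430"),
  mass_da   = c(66200, 48100, 29400, 24800, 500),
  min_count = c(2, 2, 0, 0, 0), max_count = c(2, 2, 2, 2, 2),
  group     = c(NA, NA, "G", "G", NA))
match_stoichiometry(est, comps, group_sums = c(G = 2))
#>   alpha beta h gamma f430 total_mass_da   delta_da
#> 1     2    2 2     0    2        288400 -0.1188389
```

The deconvoluted mass recovers the planted value to ~1 Da, and the
matcher identifies the α₂β₂h₂f₂ composition (both G slots tagged, both
active sites loaded with F430) as the only composition within the 0.1%
mass tolerance.

```r
# F430 content: a 1.4:1 cofactor:complex ratio means 70% site
# occupancy, i.e. a 30% reduction from the full two-site complement
occupancy(1.4e-5, 1.0e-5)$reduction_pct
#> [1] 30
```

A command-line wrapper over the same functions is installed at
`inst/scripts/mcr-atlas.R` (`scan` for operon mining from files, `run`
for the configured pipeline).

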