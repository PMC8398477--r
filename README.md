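# nppipe

Neuropeptides — short signaling peptides released from larger precursor
proteins — orchestrate reproduction, feeding and development in
invertebrates. In mollusks such as the Pacific oyster, they are mined from
transcriptome assemblies of the nervous system (the visceral ganglia in
particular) by homology searching, then validated by predicting how each
neuropeptide precursor protein (NPP) is proteolytically processed and by
matching the predicted products against peptidomic mass-spectrometry data,
and finally related to physiology by testing their expression across the
reproductive cycle.

`nppipe` packages that entire workflow for R users working on
invertebrate neuropeptide repertoires:

* **Discovery** — six-frame ORF extraction (`find_orfs()`), a transparent
  von Heijne-style signal-peptide predictor (`predict_signal_peptide()`),
  and Smith–Waterman/BLOSUM62 homology screening against a panel of known
  NPP queries with a Karlin–Altschul E-value threshold
  (E = K·m·n·e^(−λS), default E ≤ 1.3) plus an NPP feature filter
  (`screen_candidates()`).
* **Processing** — prohormone convertase cleavage at mono-/dibasic K/R
  sites, mature-peptide derivation with C-terminal amidation (sacrificial
  Gly, −0.98402 Da) and N-terminal pyroglutamate (−17.02655 Da)
  annotation, and partially processed extended forms
  (`annotate_precursor()`, `partially_processed_forms()`).
* **MS confirmation** — monoisotopic neutral masses with variable
  modifications, candidate enumeration (mature or no-enzyme substring
  mode), matching at 30 ppm precursor / 0.05 Da fragment tolerance, and
  reversed-sequence target-decoy FDR filtering at 0.1%
  (`monoisotopic_mass()`, `build_candidates()`, `match_peptides()`,
  `fdr_filter()`).
* **Expression** — TPM normalization (columns sum to 10⁶), PCA,
  Euclidean hierarchical clustering, per-NPP one-way ANOVA with Tukey HSD
  letters over the four gametogenesis stages, and classification of
  significant profiles into groups I (early-high, declining), II
  (stage-3 peak) and III (stage-2 trough) (`tpm()`, `de_scan()`,
  `classify_profile()`).
* **Synthetic truth** — seeded generators for precursors, transcripts,
  MS observations and 26-pool stage/sex count matrices, so every stage is
  testable against known ground truth (`gen_precursor()`,
  `gen_transcripts()`, `gen_ms_observations()`, `gen_counts()`).

## Worked example

```r
library(nppipe)

# A synthetic two-peptide precursor with known processing truth
tr <- gen_precursor(n_peptides = 2, p_amidated = 1, p_pyroglu = 1, seed = 42)
tr$sequence
#> [1] "MKLIFIILFLDSESQCQPQNDGKRQTHCCVQ"

ann <- annotate_precursor(tr$sequence, id = "demo")
ann
#> precursor demo (31 aa): signal 1-14, 1 site(s), 2 peptide(s)
#>   pyroGlu-QCQPQND-amide
#>   pyroGlu-QTHCCVQ
```

The predictor found the signal peptide (residues 1–14), the dibasic KR
site, the sacrificial glycine marking the first peptide as amidated, and
the glutamine starts marking both peptides as pyroglutamate-competent.
The theoretical neutral mass of the first mature product, with both of
its modifications applied:

```r
monoisotopic_mass(ann$peptides$seq[1], pyroglu = TRUE, amide = TRUE)
#> [1] 813.3076
```

Processing a propeptide of the oyster GNamide family reproduces its known
products — a pyroglutamylated, amidated decapeptide and the downstream
peptide:

```r
sites <- find_cleavage_sites("QTFGWGGAGNGKRSSFA")
derive_peptides("QTFGWGGAGNGKRSSFA", 0L, sites)
#>          seq start end amidated pyroglu n_cys  evidence
#> 1 QTFGWGGAGN     1  10     TRUE    TRUE     0 predicted
#> 2       SSFA    14  17    FALSE   FALSE     0 predicted
```

Assembly summaries follow the standard Nx convention:

```r
contig_stats(c(5, 4, 3, 2, 1))
#> 5 contigs, 15 bases total; N50 = 4, N90 = 2
```

The whole simulated pipeline — precursors, transcripts, ORFs, screen,
processing, MS matching, expression — runs end to end, bit-reproducibly,
from one seed:

```r
run_pipeline(pipeline_config(seed = 1), outdir = "nppipe_run")
```

A thin command-line front end with the same stages as subcommands is
installed at `inst/scripts/nppipe` (e.g. `nppipe run --seed 1 --outdir
out`, `nppipe screen --queries panel.fasta --targets orfs.fasta`).

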