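---
title: "Methods and design notes for the nppipe pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the nppipe pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppipe)
```

## Scope

`nppipe` implements the computational workflow used to characterize
neuropeptide precursor proteins (NPPs) in the visceral ganglia (VG) of the
Pacific oyster: homology screening of candidate proteins from an assembled
transcriptome, prediction of prohormone convertase processing with
post-translational modifications, confirmation of predicted peptides
against mass-spectrometry (MS) observations, and identification of NPPs
whose expression varies across the reproductive cycle. Every stage can be
exercised on synthetic data with known ground truth, which is how the
package tests itself.

## Homology screening

Candidate proteins come from six-frame translation of transcript contigs
(`find_orfs()`): all maximal stop-to-stop (or ATG-to-stop) translations in
the standard genetic code, with ambiguous codons translating to `X`. The
module reports all frames rather than choosing one open reading frame per
contig — real contigs contain frameshifted or untranslated homologous
stretches, and the downstream screen is the arbiter of what is kept. The
default minimum ORF length is 60 residues; the simulated pipeline lowers
it to 30 because its compact three-peptide precursors are 40–60 residues
long.

Candidates are aligned against a panel of known NPP queries with
Smith–Waterman local alignment (BLOSUM62, affine gaps with the BLAST
convention that a gap of length $L$ costs $11 + L$). The tBLASTn search of
the original workflow — protein queries against a translated nucleotide
database — is realized as ORF extraction followed by protein–protein
alignment, which has the same screen semantics and is fully testable.
Significance uses the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with the published ungapped BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$) as configurable defaults; the E-value
acceptance threshold is 1.3.

A hit is only accepted when the target displays the features of an NPP:

* a predicted signal peptide,
* at least one potential convertase cleavage site in the propeptide,
* a precursor length within 150 residues.

The length criterion is a *soft* filter by default (`length_mode =
"soft"`): a target that exceeds 150 residues survives when its homology is
very strong ($E \le E_{max}/100$). Several well-established large
precursors (nesfatin-like, egg-laying-hormone-like) would be discarded by
a literal hard cutoff, so the hard filter is available but not the
default.

## Signal-peptide heuristic

The screen needs presence calls and a plausible cleavage coordinate, not a
reproduction of SignalP's neural network, so `predict_signal_peptide()`
uses a transparent von Heijne-style heuristic with the classic tripartite
architecture:

* **n-score** — 1 when a basic residue (K/R) occurs in positions 1–5,
  else 0.5;
* **h-score** — the maximum mean Kyte–Doolittle hydropathy over any
  window of ≥ 8 residues between position 2 and three residues before the
  candidate cleavage point (the hydrophobic core);
* **c-score** — 1 when the residues at −1 and −3 from the cleavage point
  are small (A, G, S, C, T), the signal-peptidase substrate rule.

Candidate cleavage positions 10–45 are scanned. A position is valid when
its c-score is 1 and its h-score reaches 1.6 (the default threshold, in
hydropathy units where leucine scores 3.8). Among valid positions the
*earliest* is reported, reflecting that the c-region directly follows the
hydrophobic core; the reported presence score is the maximum per-position
combined score, which makes the score monotone under substitutions that
reduce hydropathy. Both thresholds are exposed as parameters.
Discrepancies against SignalP on real sequences are expected; the
heuristic is calibrated only to be reliable on the package's own
precursor model (≥ 95% exact cleavage recovery in the test suite).

## Prohormone processing

`find_cleavage_sites()` marks every maximal run of two or more K/R
residues as one dibasic/multibasic site (runs are never split into
overlapping sites) and, optionally, isolated K/R as monobasic sites.
Monobasic sites are annotate-only by default: the figures' convention in
this field marks them as *possible* cleavages, and MS evidence can promote
them; `cut_monobasic = TRUE` turns them into cut sites. Multibasic runs
are cut once, after the last basic residue, consistent with furin/PC
specificity; whether the enzyme also trims basic residues left at the new
N-terminus varies between documented precursors, so the single-cut rule is
a deliberate, configurable simplification.

`derive_peptides()` takes the segments between the signal peptide, the
cut sites, and the C-terminus, excluding the basic residues. A segment of
two or more residues ending in glycine and followed by a cut site loses
that sacrificial glycine and is flagged amidated (−0.98402 Da downstream);
a segment starting with glutamine is flagged pyroglutamate-competent
(−17.02655 Da downstream; glutamate cyclization is not modeled because the
MS search space of the original workflow lists N-terminal Q only). A
C-terminal segment can only be amidated when `allow_terminal_amide` is
set, because no downstream basic site exists to donate at the terminus. A
segment that is exactly `"G"` is kept as a peptide rather than consumed as
an amide donor — amidation requires a non-empty body — which keeps the
reconstruction invariant intact on adversarial inputs.

Every annotation satisfies a *reconstruction invariant*: concatenating the
signal peptide, peptide bodies, sacrificial glycines and cut-site motifs
reproduces the precursor exactly (`check_reconstruction()` verifies this
from the parts alone, and `annotate_precursor()` refuses to return an
object that fails it). `partially_processed_forms()` enumerates extended
forms spanning up to `max_missed_sites` uncleaved sites, as such forms are
routinely detected by MS.

## Mass matching

Neutral monoisotopic masses are computed from a compiled-in residue table
(standard atomic masses; water 18.010565 Da) with the four variable
modifications of the original search: carbamidomethyl-Cys (+57.02146),
Met oxidation (+15.99491), N-terminal Gln pyroglutamate (−17.02655) and
C-terminal amidation (−0.98402), capped at three modifications per
peptide. The search is over neutral masses throughout — charge
deconvolution is assumed upstream — and candidates are either the
predicted mature peptides plus extended forms and ≤ 3-residue terminal
truncations (`mode = "mature"`), or all precursor substrings of length
4–60 (`mode = "no_enzyme"`, mirroring a no-enzyme database search).

Precursor matching uses a 30 ppm relative tolerance; fragment matching
uses an absolute 0.05 Da tolerance on b/y ladders under a documented
proton-neutral convention: $b_i = \sum_{k \le i} m_k + p$ and
$y_i = \sum_{k > L-i} m_k + w + p$ with $p = 1.00794 - 0.00055 = 1.00739$,
so $b_i + y_{L-i} = M + 2p$ exactly (asserted in the tests). The match
score is deliberately simple and interpretable — fragment coverage minus
scaled precursor error,
$\text{frag matched}/(2(L-1)) - |\text{ppm}|/(10 \cdot \text{tol})$ —
rather than an attempt to reproduce a proprietary search engine score.
Mass alone cannot rank near-isobaric candidates (reversal preserves mass,
and K/Q or I/L-containing substrings collide within 30 ppm), so FDR
control is meaningful only when observations carry fragments; the
simulated pipeline therefore attaches b/y fragment lists by default.
Decoys are reversed-sequence candidates; the estimated FDR at a score
cutoff is decoys-above divided by targets-above (decoys first within
ties), monotonized into q-values, with the default cutoff at 0.1%.

## Expression analysis

Counts are normalized to TPM (per sample: counts divided by
transcript length in kb, rescaled to sum to $10^6$), with the expression
categories used for the assembly summary: below 1 TPM is "not expressed or
very low", above 60 TPM is "highly expressed". Global structure uses PCA
(SVD of the centered samples × genes matrix, sign fixed by the largest
loading) and agglomerative hierarchical clustering with Euclidean
distance; the linkage method is not specified in the source workflow, so
average linkage — a robust default for expression profiles — is the
configurable default.

Each NPP transcript is tested with a one-way ANOVA on the reproductive
stage factor followed by Tukey's HSD, summarized as a compact letter
display (insert-and-absorb algorithm, letters assigned from the highest
stage mean). Sexes are pooled within stage by default because no
sex-biased NPP expression was observed in the source data, making sex a
negative control; a stage-by-sex factor is available. The ANOVA runs on
$\log_2(\text{TPM}+1)$ by default for variance stabilization — the
original analysis does not state its scale, so a raw-TPM mode is provided
and neither is asserted as "the" original. Raw ANOVA p-values at
$\alpha = 0.05$ drive the headline significance calls, mirroring the
source analysis; Benjamini–Hochberg adjusted values are reported alongside
in the `p_bh` column.

Significant genes are sorted into the three stage-profile groups, with
tolerance $\tau$ equal to 5% of the range of the four stage means:

* **I** — maximum at stage 0/1 and a decline through stage 2 to stage 3
  (within $\tau$);
* **II** — maximum at stage 3;
* **III** — minimum at stage 2, with both the stage-0/1 side and stage 3
  exceeding it by more than $\tau$.

The groups are made disjoint by the precedence I > II > III; profiles
matching none of the shapes are `none`.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the package tests
itself:

* `gen_precursor()` builds precursors with the canonical architecture
  (Met + basic n-region, ≥ 8-residue hydrophobic core without alanine,
  a c-region with small residues at −1/−3, peptide bodies free of basic
  residues, sacrificial glycines before amidated boundaries, Gln starts
  for pyroglutamate-competent peptides). Terminal residues of
  non-modified bodies avoid G and Q so the processing truth is
  unambiguous.
* `gen_transcripts()` reverse-translates with uniform synonymous codons,
  random UTRs and strands; the last three 5'-UTR bases are an in-frame
  stop so the maximal ATG-to-stop frame starts at the true start codon.
* `gen_ms_observations()` applies relative Normal noise (default
  8 ppm SD) to theoretical masses and 0.01 Da noise to fragments. Decoy
  observations are rejection-sampled > 200 ppm away from *every*
  mature-mode candidate mass derivable from the truths (a superset of the
  truth peptide masses), so decoy exclusion at 30 ppm is a construction
  guarantee rather than a coin flip.
* `gen_counts()` draws negative-binomial counts (log-normal baselines,
  default dispersion 0.05) over the 26-pool design — 3 undifferentiated
  stage-0 pools, 4 male pools each at stages 1 and 2, 3 at stage 3, and
  4 female pools at each of stages 1–3 — with geometric stage-multiplier
  profiles for groups I ($f, f^{2/3}, f^{1/3}, 1$), II ($1,1,1,f$) and
  III ($f,f,1,f$) and no sex effect. The 96-transcript panel of interest
  is embedded among 900 stage-invariant background genes: TPM is a
  relative measure, and without a realistically large denominator the
  differential panel members would induce compositional artifacts in the
  null genes that the real whole-transcriptome normalization does not
  have.

These generators do **not** emulate assembly artifacts (chimeras,
fragmented ORFs), SignalP-discordant signal peptides, retention-time or
isotope-envelope structure in MS, correlated gene expression, or
library-size imbalance. Passing tests therefore demonstrate the
correctness of the algorithms under the stated model, not performance on
real oyster data.

## Numerical choices and problem sizes

Tolerances and tie-breaks: Nx reports the contig that reaches the
cumulative threshold; TPM columns are checked to $10^{-6}$ relative;
PCA signs are fixed by the largest-magnitude loading; clustering ties
follow `stats::hclust`'s deterministic order; equal match scores are
broken by smaller absolute ppm error; zero within-group variance with
equal means defines $F = 0$, $p = 1$. All generators take an explicit
seed and are bit-reproducible.

The test-suite problem sizes are the package's own choices for a fast,
sharp suite: 500 precursors for the processing round trip, 100 truths
plus 100 shuffled decoys for the screen, 100 random pairs for the
alignment and mass oracles, 25 precursors with 100 mass decoys (and ten
8-precursor replicates for FDR), a 2000-gene null and the 96-gene/25-DE
panel for expression. `scripts/acceptance.R` recomputes the same
quantities end to end from a single command-line seed.

## Known limitations

The signal-peptide heuristic is not SignalP and will disagree with it on
real proteins; E-values use ungapped constants with gapped alignments, so
they are calibrated only relative to the configurable threshold; the
single-cut rule at multibasic runs is one of several observed processing
outcomes; D-amino-acid isomerization is mass-neutral and undetectable
here; disulfide pairing is not predicted (cysteines are only counted).
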