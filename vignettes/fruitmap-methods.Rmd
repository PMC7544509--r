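---
title: "Methods: pooled-cross mapping, selection tests and growth morphometrics"
author: "fruitmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-cross mapping, selection tests and growth morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitmap)
```

fruitmap reimplements, as one tested toolkit, the computational steps of a
forward-genetics study of fruit shape in *Capsella*: mapping an EMS-induced
recessive mutation from phenotype-pooled sequencing, predicting the protein
consequence of the splice-acceptor lesion, asking whether the candidate gene
evolves under selection, quantifying fruit shape and cell growth, and
scanning a candidate substrate for SUMO-acceptor sites.  Every analysis has
a matching synthetic-data generator, so the full pipeline runs end to end
with no external data.  This vignette records the models, the defaults, and
the choices made where the design was genuinely open.

## Bulked segregant analysis of a recessive EMS mutant

### The Mendelian pool-frequency model

A single-locus recessive mutation in an F2 (the focal locus of a BC~3~F~2~
still segregates 1:2:1; the backcrosses clean the rest of the genome)
partitions the population by phenotype.  Under full penetrance the
phenotypically mutant class is all homozygous mutant, so the mutant allele
is at frequency 1 in the mutant pool; the phenotypically wild-type class is
1/3 homozygous wild type and 2/3 heterozygous, so the mutant allele sits at
$\tfrac{2}{3}\cdot\tfrac{1}{2} = \tfrac{1}{3}$ in the wild-type pool.
`expected_pool_frequency()` returns these expectations exactly (33.3% and
100%).

### The three-criterion filter

`filter_candidates()` screens pooled SNPs by:

1. **substitution type** — EMS induces G:C→A:T transitions, so only G>A and
   C>T records (reference-strand image of the same lesion) are retained
   (`is_ems_type()`);
2. **pool genotypes** — a heterozygous call in the wild-type pool and a
   homozygous-alternate call in the mutant pool
   (`classify_pool_genotype()`, frequency-band calls);
3. **pool frequencies** — $|f_{WT} - 1/3| \le$ `wt_tol` and
   $f_{Mu} \ge 1 -$ `mu_tol`.

Criteria 2 and 3 overlap operationally; they are flagged independently so
the audit trail mirrors the three-part screen.  Genotype calling from
pooled reads is done by frequency bands because no per-individual genotypes
exist in pooled data; a pooled "heterozygous" call simply means both
alleles are credibly present.

**Tolerances.** `wt_tol = 0.10` and `mu_tol = 0.05` by default.  At 100×
depth the binomial standard deviation of a 1/3 frequency is about 0.047, so
0.10 is roughly a 2-SD band on read sampling alone.  Note that a finite
pool adds composition variance on top of read sampling: with 90 individuals
per pool the number of heterozygotes among the wild-type pool is itself
binomial, adding ≈0.025 SD, for a combined SD of ≈0.053.  The exact
probability that the causal site falls inside the 0.10 band at 100× is
0.940 — the band is a ~1.9-SD screen, deliberately permissive per criterion
and sharpened by requiring all three criteria jointly.  `min_depth = 20`
suppresses calls from almost-uncovered sites.

**Ranking.** Surviving candidates are ordered by
$|f_{WT} - 1/3|$; the study only reports surviving candidates, so the
ranking is this package's own convenience.

### What the cross simulator emulates

`simulate_cross()` draws F2 genotypes 1:2:1, assigns phenotype by the
fully penetrant recessive rule (penetrance is a config field, default 1),
samples `pool_size = 90` individuals per phenotype without replacement,
and draws per-site read counts binomially at fixed `depth = 100` with a
symmetric miscall rate (default 0.001, a typical post-filter Illumina
error).  `depth = Inf` is a deterministic diagnostic mode that returns
population-expectation frequencies, reproducing the analytic 1/3 and 1
exactly.  Background SNPs are labelled negatives of two kinds so each
filter criterion is exercised on its own: unlinked EMS-type SNPs (alleles
independent of phenotype; pool frequencies near 1/2, rejected by the
frequency criterion) and, when `ems_fraction < 1`, non-EMS substitutions
given causal-like frequencies (rejected only by the type criterion).  The
simulator does **not** model linkage along chromosomes, so it cannot
produce the gradient of allele-frequency distortion around a causal locus
that real BSA data show; filter behaviour at linked loci is outside its
reach.  Read-level artefacts (mapping bias, indel noise) are likewise not
modelled.

### Splice-acceptor consequence prediction

`predict_splice_consequence()` models acceptor loss minimally: the mutated
acceptor AG is dead, and the spliceosome uses the nearest downstream AG
within a 300-nt window (no splice-strength scoring — the simplest rule
consistent with a 7-bp downstream cryptic site).  The removed coding bases
shift the frame iff their count is not a multiple of 3; the re-spliced CDS
is translated to the first stop, giving the predicted product length and
premature-stop position.  If no AG exists in the window the outcome is
flagged (`no_acceptor`) instead of predicted — exon skipping and intron
retention are deliberately not modelled.  `predict_frameshift_protein_length()`
applies the same translate-to-first-stop logic to simple coding deletions
(e.g. a CRISPR 1-bp deletion yielding a 77-aa product).  Coordinates are
1-based inclusive throughout (VCF/GFF3 convention); minus-strand gene
models are normalised to transcription orientation at construction.

## Selection tests on 0-fold and 4-fold sites

### Site classification

Only the two extreme degeneracy classes are used: 0-fold sites (every
change is non-synonymous) proxy non-synonymous sites, 4-fold sites proxy
synonymous sites; 2-fold/3-fold positions are counted in neither.  This is
stricter than codon-model Ka/Ks and makes the ratios simple per-site rates.
`codon_degeneracy()` is built once from the standard genetic code and is
checked in the tests against an independent substitute-and-translate
oracle over all 61 sense codons.

### Counting and the MK table

`count_poly_div()` walks an in-frame ingroup alignment plus one outgroup
sequence codon by codon.  Site class is taken from the degeneracy of the
position in the ingroup majority (consensus) codon; a site segregating in
the ingroup increments Pn/Ps, a site monomorphic in the ingroup but
different from the outgroup increments Dn/Ds.  Sites both polymorphic and
divergent count as polymorphic only (the classical McDonald–Kreitman
convention).  Codons containing a gap or ambiguity character in any
sequence are excluded whole — classification needs an unambiguous codon
context, so exclusion is at codon rather than column granularity.  No
multiple-hit correction is applied; at moderate divergence raw proportions
are adequate for this desk-scale analysis, and estimates will sit slightly
below codeml-style values at saturating divergence.

`mk_test()` reports, per gene: $P_n/P_s = (P_n/L_0)/(P_s/L_4)$,
$K_a/K_s = (D_n/L_0)/(D_s/L_4)$ ($\omega$), the neutrality index
$NI = (P_n/P_s)/(D_n/D_s)$, the direction of selection
$DoS = D_n/(D_n+D_s) - P_n/(P_n+P_s)$ (positive under adaptive excess of
fixed differences, negative under segregating constraint), and the
two-sided Fisher exact p of the 2×2 table $[[D_n, D_s], [P_n, P_s]]$
(`stats::fisher.test`; the tests verify it against exhaustive
hypergeometric enumeration on all tables with margins ≤ 30).  Ratios with
zero denominators are returned as `NA` with a flag, never imputed.

### The covariate-matched empirical null

Selection statistics vary with recombination rate, gene density and
expression, so a focal gene's $\omega$ is compared with genes matched on
those three covariates.  The source analysis says only "comparable" and
"similar"; `match_genes()` makes this operational as absolute bands of
±0.5 pooled SD per covariate (configurable), with the focal gene excluded
and a warning flag when fewer than `min_matches = 100` genes qualify.
`empirical_two_sided_p()` uses the add-one rank estimator
$p = \min\!\big(1,\, 2\min\big(\tfrac{\#\{x \le obs\}+1}{n+1},
\tfrac{\#\{x \ge obs\}+1}{n+1}\big)\big)$, which counts ties on both sides
and can never return 0.  Undefined statistics among the matched genes are
dropped and counted.

### The count simulator and calibration regimes

`simulate_mk_counts()` draws the four MK cells from independent Poissons:
$P_s \sim \mathrm{Pois}(\theta l_4)$, $D_s \sim \mathrm{Pois}(d\, l_4)$,
$P_n \sim \mathrm{Pois}(\theta l_0 f_{poly})$,
$D_n \sim \mathrm{Pois}(d\, l_0 f_{div})$, with acceptance factors
$f = 1$ neutral and $f < 1$ purifying.  The defaults describe a
Capsella-like setting: genes with $l_0 = 600$, $l_4 = 200$ (a ~300-codon
gene), per-site synonymous diversity $\theta = 0.02$ and divergence
$d = 0.10$ to the outgroup.  Covariates are drawn from truncated normals
(recombination ~cM/Mb, density ~genes per 50-kb window, expression ~log2
units) and can be correlated with per-gene constraint
(`covariate_effect`, `f_poly_range`) to give matching signal to exploit.

One point deserves emphasis: **Fisher's exact test is conservative in
sparse tables.**  At the realistic per-gene defaults (expected cells
roughly 12/4/60/20) the neutral rejection rate at $\alpha = 0.05$ is well
below 5%.  The calibration check therefore runs the neutral simulation in
a data-rich regime — expected 50 events in each cell
($l_0 = l_4 = 2000$, $\theta = d = 0.025$) — where the exact conditional
test attains its nominal size; think of it as the aggregated/long-gene
limit.  Both facts are properties of the test, not of this implementation.

## Fruit and cell-growth morphometrics

### Shoulder index

`shoulder_index()` computes $\theta = \arctan((L_1 - L_2)/W)$ in degrees
from the two measured extents and the fruit width.  The landmark
definitions and units of $L_1$, $L_2$, $W$ follow the prior morphometric
protocol of the field and are treated here as abstract lengths in a common
unit; $\theta$ is 0 for symmetric fruit, positive when $L_1 > L_2$, odd
under swapping the extents, and reported in degrees because the index is
an angle.

### Growth tensors from tracked polygons

A cell tracked between two time points is a pair of corresponding vertex
lists (correspondence is required input — cell relations were curated
manually in the source imaging pipeline, and no automatic point matching is
attempted).  `fit_growth()` centres both vertex sets and solves the least
squares problem $Y \approx XA^\top$ for the 2×2 affine matrix $A$; the
principal stretches $\lambda_1 \ge \lambda_2$ are the singular values of
$A$.  Growth anisotropy is reported as the ratio
$\lambda_1/\lambda_2 \ge 1$ by default; the normalised alternative
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ is available via
`anisotropy_measure = "fractional"` since heat-map tools differ and the
source tool's internal formula is not public.  The **area ratio** is
computed from the polygon areas (shoelace formula), not from
$\det A$, so merging or division artefacts cannot bias it.  Nearly
collinear t0 vertices are a rank-deficiency error, not a silent fit.

Cells that divide between time points are merged back onto the parent
outline before fitting (`merge_daughters()`): daughters sharing a lineage
label are united along their common chord at both time points and the
correspondence is rebuilt on the outer boundary; non-adjacent "daughters"
are an error naming the parent.  Heat maps are rendered on the later time
point (`growth_heatmap()`), and every figure writes a sidecar TSV with the
exact plotted values so content can be checked without parsing pixels.

`simulate_mesh()` deforms a grid of unit cells by
$A = R(\phi)\,\mathrm{diag}(s_1, s_2)\,R(\phi)^\top$ plus per-vertex
Gaussian noise (noise is keyed by vertex, so shared vertices — including
division-chord endpoints — stay coincident).  Every cell's true anisotropy
($s_1/s_2$) and area ratio ($s_1 s_2$) are known by construction; the
recovery tests use $s_1 = 1.8$, $s_2 = 1.2$ and 1% vertex noise on a
10×10 grid.  The simulator is affine-uniform: it does not emulate spatial
growth gradients, curved 2.5-D tissue surfaces, or segmentation error
beyond isotropic vertex jitter, so passing tests certify estimator
correctness, not robustness to those real-data effects.

## SUMO-consensus scanning

`scan_sumo()` reports every tetrapeptide ψ-K-X-[D/E] (acceptor lysine =
window start + 1).  The hydrophobic set ψ is not standardised in the
motif's common definition; the default `A I L M V F P C` includes alanine
— required by the canonical A-K-M-D example with the acceptor at K124 —
and excludes glycine, and the set used is recorded in every output row.
An inverted consensus ([D/E]-X-K-ψ) can be scanned behind a flag, off by
default.  `simulate_proteins()` seeds motifs into random sequences at a
Poisson rate and records its truth table by an independent regex scan, so
seeded and spontaneous matches alike are ground truth.

## Pipeline, reproducibility and numerical conventions

`run_pipeline()` executes a declarative stage list, writes each stage's
outputs (VCF/TSV/JSON/FASTA/PNG), hashes every file into a manifest, and
stores the resolved configuration beside the outputs.  Stage seeds are
derived deterministically from the global seed plus stage position, so
identical configurations yield byte-identical tables; figures are compared
through their sidecar TSVs.  `validate_inputs()` gives line-anchored
diagnostics for malformed VCF (including a missing AD FORMAT field), GFF3,
FASTA, TSV and JSON before a run.

Conventions: 1-based inclusive coordinates everywhere; pooled frequencies
are `NA` (never 0/0) at uncovered sites; undefined ratios are flagged, not
imputed; ties in consensus building break by fixed base order (A,C,G,T)
for determinism; polygon orientation is normalised counter-clockwise
before stitching; all generators are bit-reproducible under a fixed seed
and restore the caller's RNG state.

### Problem sizes used by the shipped checks

The test suite exercises: the exhaustive Fisher comparison on all 164,175
2×2 tables with margins ≤ 30; the degeneracy table on all 61 sense codons;
the BSA filter against a brute-force criterion evaluator on 10,000 random
variants; the splice predictor against a re-splice-and-translate oracle on
1,000 random gene models; MK type-I calibration on 2,000 neutral genes;
empirical-p uniformity on 1,000 replicates (Kolmogorov–Smirnov at
α = 0.01); anisotropy recovery on 100 cells; and causal-SNP recovery over
100 seeded crosses.  These sizes were chosen so the whole suite completes
in a few minutes on one CPU while keeping Monte-Carlo standard errors well
inside the asserted tolerances.

## Known limitations

* No linkage map in the cross simulator; candidate regions, SNP-index
  smoothing and linked-marker gradients are out of scope.
* Splice prediction uses nearest-AG with no strength scoring and does not
  model exon skipping or intron retention beyond flagging them.
* Ka/Ks and Pn/Ps carry no multiple-hit correction and use only the
  extreme degeneracy classes; values are not directly comparable to
  codon-model estimates.
* The growth model is a single affine map per cell; residual RMS reports
  how far a cell departs from that assumption but non-affine deformation
  is not decomposed.
* ψ-set membership for the SUMO consensus is a configuration choice;
  scanning real proteins should report the set used alongside the hits.
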