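# fruitmap

Forward-genetics studies of fruit shape in *Capsella* hinge on a chain of
computations: map an EMS-induced recessive mutation from phenotype-pooled
sequencing, predict what a splice-acceptor lesion does to the protein, ask
whether the candidate gene evolves under purifying or adaptive selection,
quantify fruit shape and cell growth, and scan a candidate substrate for
SUMO-acceptor sites.  **fruitmap** packages that chain as tested,
reusable R functions for geneticists working on pooled-mapping and
molecular-evolution analyses, together with synthetic-data generators so
every step runs (and is verified) without any external data.

## What it computes

**Bulked segregant analysis (BSA).**  For a fully penetrant recessive
locus segregating 1:2:1 in an F2, the mutant allele is expected at
frequency 1/3 (33.3%) in the phenotypically wild-type pool and 1 (100%)
in the mutant pool.  `filter_candidates()` screens pooled SNPs with three
criteria: (1) EMS substitution type (G>A / C>T); (2) heterozygous call in
the wild-type pool, homozygous-alternate in the mutant pool; (3) pool
frequencies within tolerance of the Mendelian expectations
(|f_WT − 1/3| ≤ 0.10, f_Mu ≥ 0.95 by default).

**Splice-acceptor consequence.**  `predict_splice_consequence()` breaks
an intron's acceptor AG, re-splices at the nearest downstream AG, counts
the removed coding bases, detects frameshifts (count mod 3 ≠ 0), and
translates the re-spliced CDS to the first stop —
e.g. a cryptic site 7 bp into the next exon ⇒ 7-bp deletion, frameshift,
premature termination codon.

**Selection tests.**  On 0-fold/4-fold degenerate sites:
Pn/Ps = (Pn/L0)/(Ps/L4), Ka/Ks (ω) likewise for fixed differences,
the neutrality index NI, the direction of selection
DoS = Dn/(Dn+Ds) − Pn/(Pn+Ps), the McDonald–Kreitman Fisher exact test,
and a two-sided empirical p against genes matched on recombination rate,
gene density and expression (`mk_test()`, `mk_empirical_null()`).

**Morphometrics.**  Fruit shoulder index θ = arctan((L1 − L2)/W) in
degrees (`shoulder_index()`); per-cell growth tensors from
lineage-tracked polygons by least-squares affine fits — anisotropy
λ1/λ2, polygon-area ratio, daughter-cell merging, and heat maps on the
later time point (`fit_growth()`, `merge_daughters()`,
`growth_heatmap()`).

**SUMO motifs.**  `scan_sumo()` reports every ψ-K-X-[D/E] window
(ψ hydrophobic, default set `AILMVFPC`) with the acceptor-lysine
position.

**Pipeline.**  `run_pipeline()` chains the stages with deterministic
seeding, writes VCF/TSV/JSON/FASTA outputs, and records an MD5 manifest;
`validate_inputs()` checks files up front.

## Worked example

Simulate a pooled cross (600 F2 plants, pools of 90, 100× depth, 2,000
background EMS SNPs), then filter:

```r
library(fruitmap)
x <- simulate_cross(cross_config(n_background_snps = 2000, seed = 1))
filter_candidates(x)
#> BSA filter: 1 / 2001 variants pass all three criteria
#>   criterion 1 (EMS type):        2001 pass
#>   criterion 2 (pool genotypes):  1 pass
#>   criterion 3 (frequency bands): 1 pass
#> Top candidates (by WT-pool frequency deviation):
#>  chrom      pos ref alt wt_freq mu_freq
#>   chr1 16128029   G   A    0.28       1
x$causal_id
#> [1] "chr1_16128029"
```

All 2,001 variants are EMS-type (criterion 1), but only the planted
causal G>A site also shows the het/hom-alt pool genotypes and the
33.3%/100% frequency signature — the background SNPs segregate
independently of the phenotype and sit near 50% in both pools.  (At 100×
with 90-plant pools the causal site lands inside the 0.10 frequency band
in ~94% of crosses; a missed seed is read-sampling noise, not a filter
bug.)

A McDonald–Kreitman table is summarised like this:

```r
mk_test(data.frame(Pn = 2, Ps = 8, Dn = 7, Ds = 2, L0 = 600, L4 = 200))
#> McDonald-Kreitman results for 1 gene(s)
#>   Pn=2 Ps=8 Dn=7 Ds=2
#>   Pn/Ps = 0.08333, Ka/Ks = 1.167, NI = 0.07143, DoS = 0.5778, p = 0.02301
```

The positive DoS and NI ≪ 1 say the non-synonymous excess is among fixed
differences, not polymorphism — the adaptive pattern — and the Fisher
p (0.023) says the contrast is unlikely under neutrality.

Scanning a protein carrying AKMD at residues 123–126:

```r
scan_sumo(c(CrIND_like = paste0(strrep("G", 122), "AKMD", strrep("G", 50))))
#>      protein k_pos start end tetrapeptide   motif  psi_set
#> 1 CrIND_like   124   123 126         AKMD forward ACFILMPV
```

The acceptor lysine is K124.  A fruit with extents L1 = 4.6, L2 = 3.1 and
width 2.4 has shoulder index `shoulder_index(4.6, 3.1, 2.4)` = 32.0°.

## Package layout

- `R/` — simulators (`simulate_cross`, `simulate_mk_counts`,
  `simulate_mesh`, `simulate_proteins`), BSA filter, splice prediction,
  degeneracy/MK/empirical-null statistics, growth geometry, motif scan,
  pipeline driver and file IO.
- `tests/testthat/` — unit, property and oracle-equivalence tests
  (exhaustive Fisher enumeration, substitute-and-translate degeneracy,
  brute-force filter and splice oracles, calibration checks).
- `vignettes/fruitmap-methods.Rmd` — the models, defaults, numerical
  conventions and limitations, in detail.
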