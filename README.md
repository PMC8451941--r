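# duoReg

Analysis toolkit for dissecting how two transcription factors that
recognise the **same DNA element** divide and share their genomic
targets — built around the biology of the orphan nuclear receptors
Esrrb and Nr5a2, which bind the extended half-site `TCAAGG(T/C)CA` in
mouse embryonic stem cells and redundantly sustain the binding of the
pluripotency factors Oct4, Sox2 and Nanog. It is aimed at computational
biologists who have peak sets, count matrices and differential
expression tables and want the bespoke statistics of this analysis as
tested, reusable functions.

## What it computes

* **Motif variants.** Exact and 1-mismatch scanning of the variant
  consensi `TCAAGGTCA` / `TCAAGGCCA`, trimmed-consensus scanning of
  `TCAAGG?CA` with a free seventh base, PWM log-odds scoring
  (`score = Σ_j log2 p_j(b)/q(b)`), region classes
  (T-only / C-only / both / none) and seventh-base frequency profiles
  along regions ranked by the binding ratio
  `log2((Esrrb + 0.5)/(Nr5a2 + 0.5))` (RPM).
* **Peak logic.** Replicate-reproducible peaks (coverage ≥ m replicates,
  union-span reporting), per-factor merging with co-binding (Venn)
  flags, blacklist exclusion, RPM normalisation.
* **Differential binding/expression.** A negative-binomial Wald test
  (variance `μ + αμ²`, method-of-moments dispersion shrunk to a trended
  fit, BH-FDR), plus the expression filter (≥ 20 raw counts in all
  replicates of one condition, |FC| > 1.5, FDR < 0.01).
* **Occupancy dependence classes.** Max-normalised occupancy
  (`x / max` per TF across conditions), seeded k-means++ K-means, and
  an enrichment-driven choice of k.
* **Spacing enrichment.** Motif-pair centre distances within regions
  against a uniform within-region randomised background, with Poisson
  right-tail p-values per distance bin: `p = P(X ≥ obs), X ~ Pois(exp)`.
* **Proximity enrichment.** Hypergeometric right tail
  `P(X ≥ k | N, K, n)` for DE genes within `x` bp of a region class,
  over a log grid `x ∈ [1, 10⁶]` bp.
* **Trends and cooperativity.** Exact Gaussian-process regression
  (RBF + noise) of binding change against motif composition, and a
  one-sided Wilcoxon test of `Δ = fc_double − (fc_A + fc_B) < 0`
  (greater-than-additive loss) at single-site regions.
* **Synthetic studies.** A deterministic generator
  (`syntheticStudy()`) that plants motifs, spacings, occupancy classes,
  NB counts and gene links with known truth, so every statistic above
  has a recoverable ground truth.

## Worked example

Plant a 50-bp spacing between the receptor half-site and an Oct/Sox
composite element in 30% of 2,000 synthetic regions, then recover it:

```r
library(duoReg)

st   <- syntheticStudy("spacing", seed = 101)
seqs <- regionSequences(st$genome, st$regions)
hs   <- scanTrimmedHalfsite(seqs, maxMismatch = 1)
os   <- scanConsensus(seqs, octSoxConsensus(), maxMismatch = 2,
                      motifName = "OctSox")
w    <- setNames(GenomicRanges::width(st$regions), names(st$regions))
cur  <- pairDistanceEnrichment(hs, os, w, nShuffles = 100, seed = 101)
cur
#> EnrichmentCurve (poisson): 50 distances in [5, 495] bp
#>   min p = 1.18e-205 at 55 bp (obs 333, exp 33.2)
```

The minimum Poisson p-value lands in the 50–60 bp bin — the planted
centre-to-centre spacing (50 ± 5 bp jitter) — with 333 motif pairs
observed where the randomised background expects ~33. The same object
exposes `as.data.frame(cur)` with observed, expected, `pvalue` and
`neglog10p` per distance bin.

End-to-end, from one config:

```r
runPipeline(list(preset = "full", seed = 1, outdir = "run1"))
```

writes the genome, regions, counts, motif hits, differential tables,
class assignments, spacing and proximity curves, trend and
cooperativity summaries, plus an MD5 manifest; re-running the same
config reproduces identical files.

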