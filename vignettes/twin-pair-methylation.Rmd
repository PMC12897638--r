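---
title: "Two-tier differential methylation in monozygotic twin-pair WGBS designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier differential methylation in monozygotic twin-pair WGBS designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The design and the statistical problem

twinmeth analyses whole-genome bisulfite sequencing (WGBS) of matched
monozygotic twin pairs in which one twin of each pair gestated under a
control diet (CON) and the other under maternal nutrient restriction
(RES). Monozygotic twins share a genome, so a within-pair methylation
contrast removes genetic background entirely; across pairs, the shared
gestational environment of each pair is a nuisance effect. The package
asks, per CpG: is methylation different between RES and CON, and is that
difference *replicated* across pairs?

Two tiers answer this:

1. **Group level** — all RES fetuses against all CON fetuses (n = 4 vs 4
   by default) with a beta-binomial Wald test per CpG, Benjamini–Hochberg
   (BH) correction, and the thresholds `padj <= 0.05` and
   `|methDiff| >= 0.10` (both inclusive, exactly as printed).
2. **Twin-pair consensus** — each pair tested 1-vs-1 with local smoothing,
   the same thresholds applied per pair, and a site retained only when it
   qualifies in at least *k* of *n* pairs (default 3 of 4). Concordant
   direction is *not* enforced: a retained site whose qualifying pairs
   disagree in sign is classed `mixed`.

Throughout, `methDiff` is RES minus CON, so positive values mean
hypermethylation under nutrient restriction.

## The count model

For CpG *i* in sample *j* with total depth $m_{ij}$, methylated-read
counts are modelled beta-binomially:

$$X_{ij} \sim \mathrm{BetaBin}(m_{ij},\, p_{ij},\, \varphi), \qquad
\mathrm{Var}(X_{ij}) = m_{ij}\, p(1-p)\,\bigl(1 + (m_{ij}-1)\varphi\bigr),$$

where $\varphi \in (0,1)$ is the overdispersion (intra-class
correlation) capturing extra-binomial variability between biological
replicates. The methylation ratio is the raw quotient
$\hat p = X/m$ — no smoothing, no pseudocounts; zero depth is a distinct
"no coverage" condition, never a ratio of 0.

**Coverage pre-filter.** A site is kept iff at least one group contains
at least `min_samples = 2` samples with depth `>= min_depth = 5`. We read
the qualifying-samples rule as *within a single group*, matching the
per-group coverage requirement customary for beta-binomial testing.
Filtering changes membership only, never counts, and is logged.

**Dispersion.** $\varphi$ is estimated by method of moments from
within-group variability of per-sample ratios. The expected weighted
residual sum of squares at a site is linear in $\varphi$; summing the
per-site numerator and denominator over the genome gives a
precision-weighted pooled estimate. Because the variance factor
$p(1-p)$ must itself be plugged in from the pooled ratio — whose own
sampling variance deflates it — the estimator applies a short fixed-point
bias correction (four iterations), and the result is clipped to
$[10^{-3}, 0.5]$. The genomewide estimate deliberately absorbs
pair-to-pair heterogeneity: for the group contrast that heterogeneity is
real between-sample variance and belongs in the denominator.

## The group-level Wald test

Per group, the mean methylation is the depth-weighted pooled ratio
$\hat\mu_g = \sum_i X_i / \sum_i m_i$, with variance from the
weighted-mean formula
$\sum_i w_i^2\, \hat\mu_g(1-\hat\mu_g)(1 + (m_i - 1)\varphi)/m_i$,
$w_i = m_i / M_g$. The statistic

$$z = \frac{\hat\mu_{RES} - \hat\mu_{CON}}
          {\sqrt{SE^2_{CON} + SE^2_{RES}}}$$

is referred to a standard normal, two-sided. Degenerate sites (both group
means 0 or both 1) receive $p = 1$ rather than a pseudocount — the
zero-variance guard avoids biasing extreme sites. Sites with no covered
sample in a group are flagged untestable with a reason code and excluded
from BH, never silently dropped. This is a documented approximation of
shrinkage-based WGBS testing frameworks: the contract is type-I-error
calibration and unbiased effect recovery, not bit-compatibility with any
particular implementation.

## The single-pair test and why its smoother uses shared weights

A 1-vs-1 contrast has no replicates, so evidence is pooled over CpGs
within `smooth_halfwidth = 250` bp (window 500 bp, the order of magnitude
conventional for WGBS smoothing; configurable). Three numerical choices
here were genuinely open and deserve their rationale:

* **Shared precision weights.** Both twins' smoothed levels use the same
  weights $u_s = 1/k_s$,
  $k_s = (1+(m^{CON}_s-1)\varphi)/m^{CON}_s + (1+(m^{RES}_s-1)\varphi)/m^{RES}_s$,
  so the smoothed contrast equals the $u$-weighted mean of per-site
  within-pair differences $d_s$. If instead each twin were smoothed with
  its own depth weights, the two estimates would average the window's
  heterogeneous methylation levels differently and the null contrast
  would be biased away from zero — in null simulations that inflated the
  rejection rate to roughly twice nominal. With shared weights the
  contrast is exactly zero-mean under the null whatever the local
  methylation landscape.
* **Per-site variance plug-ins.** The contrast variance is
  $\sum_s u_s^2 \mathrm{Var}(d_s) / (\sum_s u_s)^2$ with
  $\mathrm{Var}(d_s) = p_s(1-p_s)k_s$ and $p_s$ the pooled two-twin site
  ratio, de-biased for its own sampling noise. A single window-level
  $p(1-p)$ would overstate the variance whenever a window mixes
  near-0 and near-1 CpGs (Jensen's inequality) and made the test severely
  conservative. $\sum_s u_s$ plays the role of an effective window depth.
* **The reported effect is the smoothed contrast.** At single-twin depth
  the raw site difference has a standard deviation around 0.2; using it
  for the `|methDiff| >= 0.10` filter and the direction call lets noise
  scramble signs (in simulation roughly a third of consensus sites came
  out spuriously "mixed"). The smoothed contrast is the quantity the
  statistic is built on and shares its sign; the unsmoothed site
  difference is kept alongside as `site_diff`.

BH adjustment is applied separately per analysis unit: once across all
group-level sites, once within each pair — each written file gets the
same thresholds. Because smoothing correlates nearby sites, pairwise
adjusted p-values are approximate; the calibration tests use the wider
band [0.02, 0.08] for the pairwise null rejection rate (group:
[0.03, 0.07]).

## Consensus, annotation, summaries

Consensus matches sites by exact (chrom, pos) key — all pairs share one
coordinate system, so no positional fuzz is warranted. Evidence is
aggregated over qualifying pairs only: `mean_diff` (their mean
methylation difference), `min_padj` (their smallest adjusted p), and the
direction class (`hyper`/`hypo`/`mixed`).

Annotation assigns every feature category a site overlaps by at least
1 bp (a width-1 site overlaps by 1 bp or not at all). Co-annotation is
expected — an engineered locus in the synthetic annotation places an exon
of one gene inside an intron of another — which makes regional counts
non-additive. Derived labels: `genic` = exon or intron; `intergenic` =
neither gene body nor promoter, so a promoter-only site is neither genic
nor intergenic. The promoter window is TSS −2000/+200 bp on the
transcript strand — annotation providers differ and no single span is
canonical, so it is an explicit, documented parameter. Overlap queries
are strand-blind; strand only places promoters. Interval queries go
through GenomicRanges and are verified against a naive all-pairs scan in
the test suite.

Regional summaries report per-region site counts, two-decimal
proportions of the tier total (half-up rounding, fixed so that emitted
proportions are exactly recomputable from counts), unique associated gene
counts, and direction tallies; direction tallies always sum to the region
count. Top-site tables rank by `|methDiff|` descending with ties broken
by adjusted p ascending, then position — a deterministic total order —
and keep one row per site, so a gene with several strong sites repeats.

The Liver Sparing Index of a pair is
$\mathrm{LSI} = (\text{liver}_\mathrm{RES}/\text{mass}_\mathrm{RES}) /
(\text{liver}_\mathrm{CON}/\text{mass}_\mathrm{CON})$ in g per kg;
values below 1 mean relative liver loss. The severity association
(Spearman rank correlation of LSI against per-pair dmCpG burden and
against the hyper fraction `hyper/(hyper+hypo)`, mixed excluded) is
descriptive: with n = 4 pairs no p-value deserves emphasis, and the
output says so.

## Enrichment

Over-representation uses the exact hypergeometric upper tail
$P(X \ge x)$ with an *explicit* background universe. Web-service
enrichment backends use their own annotated-gene universe, which is not
reproducible offline; requiring the caller to pass the universe (for
synthetic runs, all annotated genes) is the documented substitution. BH
runs within each source collection separately, mirroring per-database
reporting; `rich_factor = intersection/term size`; top terms are ranked
by FDR with ties broken by rich factor, then term id. Gene symbols are
matched verbatim — ortholog mapping is out of scope.

## What the generator emulates — and what it does not

The generator produces the statistical structure the analysis assumes,
with ground truth for every stage:

| parameter | default | why |
|---|---|---|
| `n_pairs` | 4 | the twin-pair design size |
| `n_cpgs`, `chrom_length` | 128,000 over 2 × 800 kb | a CpG-island-dense panel (~12 bp spacing) so a 500 bp window holds ~20–40 CpGs, emulating the covered, filter-surviving fraction of a methylome |
| `mean_depth`, `depth_dispersion` | 15, 5 | negative-binomial depth, zeros allowed; depth is independent of methylation state (nothing suggests coupling) |
| `baseline_alpha/beta` | Beta(1.2, 0.8) | moderately bimodal baseline (mean 0.6) spanning the unit interval without a large fully-(un)methylated mass, at which a discrete Wald test at depth 15 goes conservative |
| `phi` | 0.05 | typical between-replicate overdispersion |
| `dm_fraction`, `effect_size` | 0.05, 0.2 | exactly `round(dm_fraction * n_cpgs)` CpGs affected |
| `dm_cluster_size` | 40 | effects come in fixed runs of consecutive CpGs (~500 bp), i.e. differentially methylated regions spanning the smoothing window; fixed length keeps the simulated DMR count, and hence single-seed direction balance, tight |
| `hyper_fraction` | 0.95 | sign drawn per cluster; the strong hypermethylation bias of the motivating design |
| `pair_severity` | 0.85–1.0 | strictly increasing per-pair effect multipliers: a severity gradient with near-saturated detection in every pair |
| `pair_effect_sd` | 0.2 | pair-level logit shift shared by both twins |
| `lsi_slope` | 0.21 | expected LSI = 1 − slope × severity: zero severity ⇒ LSI 1, most severe pair ≈ 0.79 |

Pair effects act on the logit scale; treatment effects act on the
probability scale with clipping to [0.001, 0.999], which keeps
`effect_size` directly interpretable as a methylation difference. The
truth table records the *realised* (post-clipping) per-pair effect, so
recovery checks compare against what was actually applied. One master
seed feeds independent substreams for annotation, counts, phenotypes and
gene sets, so stages regenerate independently and all outputs are
byte-reproducible.

Not simulated: reads, bisulfite-conversion error, alignment artifacts,
non-CpG contexts, sex-chromosome dosage, coverage–methylation coupling,
and spatial correlation of the *baseline* (only effects are clustered).
Passing tests therefore demonstrate statistical correctness of the
pipeline under its own model — calibration, unbiasedness, consensus
logic, determinism — not robustness to the alignment-level artifacts of
real libraries.

## Problem sizes, calibration bands and known limitations

The test suite runs null calibration at 20,000 CpGs (4 vs 4, depth 15,
φ = 0.05) and full recovery at the default 128,000 CpGs — sizes chosen
so each Monte-Carlo check has enough effective replicates (for the
consensus direction balance, the number of simulated DMR clusters is the
effective sample size) while the whole suite stays fast.

Known limitations, deliberate and documented:

* The group tier at n = 4 vs 4 is overdispersion-limited: beyond
  moderate depth the per-site |z| cannot grow, so at a 0.1–0.16
  realised effect the group tier detects few sites at desk scale. The
  group-level *effect estimates* are unbiased (the recovery tests check
  this); detection power at scale is what the consensus tier, with its
  local smoothing, supplies.
* Clipping at extreme baselines shrinks hypermethylation effects more
  than hypomethylation effects, so the detected consensus hyper fraction
  runs one to three points below the generative `hyper_fraction`.
* Pairwise adjusted p-values inherit the correlation that smoothing
  induces between neighbouring sites.
* Adjacent consensus dmCpGs are not merged into regions; region calling
  is out of scope.

## Reproducing a full run

```{r, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "twinmeth-run",
  sim = sim_config(seed = 1L))
manifest <- run_pipeline(cfg)
```

The manifest records, per stage, the parameters, output row counts, MD5
hashes and wall time; rerunning with the same configuration reproduces
every table byte for byte.
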