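---
title: "Scoring co-dysregulation of clustered miRNAs across cancers"
author: "DEMcluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring co-dysregulation of clustered miRNAs across cancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DEMcluster)
```

## The question and the model

MicroRNA genes frequently occur in genomic clusters — several hairpins
within a few kilobases, transcribed as one polycistron or from shared
regulatory elements. If cluster members are co-regulated, a tumour that
dysregulates one member should dysregulate the others *in the same
direction*. `DEMcluster` quantifies this over catalogues of differentially
expressed miRNAs (DEMs): per (miRNA, cancer type) there is one direction
call, UP, DOWN or absent, consolidated from experiment-level tables by
majority vote (exact ties carry no direction and are dropped — a
deliberately conservative reconciliation for multi-experiment inputs; with
one experiment per cancer it is lossless).

### The homogeneity statistic

For cluster $g$ and cancer $c$, let $n_{up}$ and $n_{down}$ count the
cluster members called in $c$. The cancer is *eligible* when
$n_{up}+n_{down} \ge$ `minMembersPerCancer` (default 2 — a single called
member cannot attest co-dysregulation), and *homogeneous* when at least
half of the called members share one direction. The cluster's summary is
the homogeneous fraction
$$ H_g = \frac{\#\{\text{eligible cancers homogeneous for } g\}}
              {\#\{\text{eligible cancers for } g\}}. $$

The denominator choice matters and is configurable in spirit: we count
*called* members, not all cluster members, because a member without a DEM
call in a cancer cannot "show" a direction there.

**A degeneracy worth knowing about.** With only two directions, the
majority always reaches half of the called members, so under the literal
"at least half" rule every eligible cancer is homogeneous and $H_g \equiv
1$: only an exact tie can break homogeneity, and only if ties are not
counted as homogeneous. The package therefore exposes
`tieIsHomogeneous`: `TRUE` (default) is the literal reading, `FALSE` is the
strict-majority variant, which is the only non-degenerate one and is what
the package's own calibration and power analyses use. Per-cancer
directions (UP / DOWN / TIE / NA) are always reported so users can see
where ties drive a score.

### The permutation null

Significance of $H_g$ comes from a marginal-preserving permutation: in each
replicate and each cancer, the UP/DOWN labels of that cancer's associated
miRNAs are uniformly permuted among those miRNAs. The association pattern
(which miRNA is a DEM in which cancer) and the per-cancer UP/DOWN totals
are preserved exactly; only the assignment of directions to miRNAs is
broken. Eligibility is a function of the association pattern alone, so
every replicate scores each cluster over the same cancer set as the
observed data. The permutation pool is *all* associated miRNAs in the
supplied matrix, cluster members and non-members alike — the matrix passed
to `homogeneityTest()` defines the universe, and callers who want a
narrower pool restrict the matrix first.

Three counting rules convert the `nPerm` (default 10,000) null fractions
into a p-value:

* `strict` — $\#\{H^{perm} > H^{obs}\}/n$: the literal "exceeding" rule;
  returns 0 for a perfect observed fraction.
* `weak` — counts $\ge$ instead.
* `add_one` — $(\#\{H^{perm} \ge H^{obs}\}+1)/(n+1)$: never zero, and a
  valid p-value under exchangeability (the $\ge$ count is the only choice
  with that guarantee, which is why `add_one` builds on it).

`p_strict` $\le$ `p_weak` always; all three are returned together with
Benjamini–Hochberg q-values, though significant-cluster counts use raw
p-values at $\alpha = 0.05$, matching how such pan-cancer screens are
usually reported. Fraction comparisons use an absolute tolerance of
$10^{-12}$ so that identical rational fractions computed by identical
arithmetic never straddle the strict/weak boundary.

### LOD enrichment

Per cancer, with $X_c$ clustered and $Y_c$ non-clustered DEMs against a
universe of $X_{all}$ clustered and $Y_{all}$ non-clustered miRNAs,
$$ LOD_c = \log_2\!\left(\frac{X_c/(X_c+Y_c)}{X_{all}/(X_{all}+Y_{all})}\right), $$
zero exactly when the cancer's clustered share equals the universe share
and invariant to jointly scaling $X_c, Y_c$. By default the universe is
derived from the supplied matrix and cluster set; the catalogued human
split $688/900$ is a documented preset, not a hard-wired constant. With a
pseudocount of 0 (the literal formula) $X_c = 0$ yields `NA`; a Haldane
correction (`pseudocount = 0.5`) is available. Because "average
enrichment" is ambiguous between the mean of per-cancer folds and
$2^{\overline{LOD}}$ — the two differ whenever the per-cancer LODs vary —
both summaries are emitted. The optional significance procedure reassigns
the clustered/non-clustered labels over the universe per replicate
(exactly $X_{all}$ labels each time); this null is this package's
construction and is flagged as such in the output metadata.

### Vote-counting meta-profile

The consistent score per miRNA is $(n_{up}-n_{down})/n_{total}$ over the
experiments reporting it, in $[-1, 1]$ with $\pm 1$ iff unanimous; the
supporting-experiment count $\max(n_{up}, n_{down})$ is reported alongside
because classical vote-counting ranks by support. `n_total` can only count
experiments that *called* the miRNA a DEM — call tables do not record
experiments that tested it and found nothing — a known limitation of
direction-only meta-profiling.

## Cluster calling

Precursors on one chromosome are chained while the inter-interval gap is
at most `maxGap`; the default 10 kb is the inter-miRNA distance convention
of public cluster catalogues and is configurable because no single value
is canonical. Gaps use 1-based inclusive coordinates
($s_2 - e_1 - 1$, measured from the rightmost end seen so far in the
chain), so overlapping precursors always chain, and the greedy sweep is
provably identical to the transitive closure of the pairwise
gap-$\le$-maxGap graph — the test suite verifies this against a brute-force
$O(n^2)$ oracle on random instances. Strand never splits a chain (sense
and antisense members co-cluster), and interruption checking is off by
default because it requires a gene annotation most workflows do not carry.
Chains of $\ge 2$ precursors become clusters; mature expansion takes the
union of each precursor's arms and drops clusters whose mature membership
falls below 2.

## The synthetic generator

`simulateDEM()` emulates the data landscape the statistics are meant for;
its defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `nMirnas` | 1588 | cancer-associated mature miRNA universe |
| `fracClustered` | 688/1588 | catalogued clustered/non-clustered split |
| `meanClusterSize` | 688/143 ≈ 4.8 | mature members per catalogued cluster |
| `minClusterSize` | 2 | cluster definition |
| `nCancers` | 19 | epithelial cancer panel size |
| `pUp` | 0.48 | breast-like balance (1833 up / 1988 down) |
| `pAssoc` | 0.5 | per-cancer DEM counts of realistic magnitude (~800) |
| `rho` | 0.8 | strong-but-imperfect co-direction, consistent with reported homogeneity levels |

Cluster sizes are truncated-geometric (minimum 2) because real catalogues
are dominated by small clusters with a long tail; the drawn sizes are
trimmed so the clustered count matches `round(fracClustered * nMirnas)`
exactly. Per (cluster, cancer) a consensus direction is drawn
Bernoulli(`pUp`); each associated member copies it with probability `rho`
and otherwise draws independently. A single seeded RNG stream drives one
`simulateDEM()` call and the caller's RNG state is restored afterwards, so
outputs are byte-reproducible.

What the generator does *not* emulate: genomic coordinates of the
simulated clusters (membership is generated directly), correlated
association between cluster members (members are associated independently
even when `rho = 1`), differential association rates between clustered and
non-clustered miRNAs (so LOD scores centre on zero by construction — LOD
machinery is validated on purpose-built matrices instead), platform
effects, and any FDR or effect-size structure. Passing tests on synthetic
data therefore demonstrate the statistics' correctness and calibration
under the stated model, not robustness to every artefact of real DEM
catalogues.

## Numerical and design notes

* **Determinism.** Every stochastic entry point takes a seed; permutation
  tests use one stream for all replicates. `runFullAnalysis()` writes a
  manifest with MD5 digests, and identical inputs + seed give
  byte-identical result files.
* **Degenerate inputs.** Clusters with no eligible cancer are skipped with
  a warning; a cancer whose associated miRNAs all share one direction is
  invariant under permutation and contributes identically to observed and
  null fractions; `nPerm = 1` is allowed and yields p in {0, 1} for the
  raw rules.
* **Calibration under discreteness.** With 19 cancers the homogeneous
  fraction takes at most ~20 values, so permutation p-values are
  discrete; the add-one rule is then slightly conservative (null rejection
  at $\alpha=0.05$ runs a few points below nominal, as the package's own
  calibration run reports) while the strict rule is anti-conservative for
  clusters whose observed fraction is 1. Users comparing clusters should
  prefer `add_one` for error control and `strict` only to mirror the
  literal exceeding-count convention.
* **Problem sizes.** The shipped analyses use universes of 1588–3400
  miRNAs, 19 cancers, and 1,000–10,000 permutations — large enough for
  ~150–300 retained clusters and stable Monte-Carlo error, small enough to
  re-run casually on a laptop.

## Limitations

Beyond the generator's simplifications above: the homogeneity statistic
treats members symmetrically (no weighting by effect size or FDR, which
the input format carries only optionally); the enrichment null reshuffles
cluster labels rather than modelling miRNA-specific detectability; and
conflicting multi-experiment calls are resolved by majority vote, which
discards genuinely tied evidence rather than modelling it.
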