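---
title: "Methods: assembly processes and relative activity from paired DNA/RNA metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly processes and relative activity from paired DNA/RNA metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seepecol)
```

## The inference chain

`seepecol` implements the analysis chain used to contrast microbial
communities between cold-seep and reference ("non-seep") sediments from
paired DNA and RNA (cDNA) metabarcoding libraries: the same physical sample
is sequenced twice, once from extracted DNA (the whole community, alive or
dead) and once from reverse-transcribed rRNA (the putatively active
community). The chain is:

1. **Pairing and rarefaction.** Only DNA samples with an RNA counterpart
   are kept (default: surface sediments, ≤ 10 cm below surface), and both
   libraries are rarefied to one common depth so RNA:DNA ratios are
   comparable.
2. **Diversity.** Alpha diversity per sample (richness, Chao1, Faith's PD,
   Pielou's evenness), Bray–Curtis beta diversity, and gamma diversity per
   habitat compared through ASV accumulation curves at an equal number of
   samples. Group effects are tested with ANOSIM; seep versus non-seep
   contrasts with two-sided Wilcoxon rank-sum tests.
3. **Assembly processes.** The abundance-weighted beta mean nearest taxon
   distance between communities \(k\) and \(m\),
   \[
   \beta\mathrm{MNTD} = \tfrac12\Big[\sum_{i_k} f_{i_k}\,
   \min_{j_m}\Delta_{i_k j_m} + \sum_{i_m} f_{i_m}\,
   \min_{j_k}\Delta_{i_m j_k}\Big],
   \]
   with \(f\) the relative abundances over the taxa present in each
   community and \(\Delta\) patristic distances, is standardized against a
   tip-shuffle null (999 randomizations by default) to give the beta
   nearest taxon index,
   \(\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{\mathrm{obs}} -
   \mu_{\mathrm{null}})/\sigma_{\mathrm{null}}\).
   \(\beta\mathrm{NTI} < -2\) indicates homogeneous selection, \(> 2\)
   heterogeneous selection, and \(|\beta\mathrm{NTI}| \le 2\) stochastic
   assembly (dispersal, drift). Using phylogenetic turnover this way is
   licensed only if niche values carry phylogenetic signal at short
   distances, which `phylo_signal()` checks with a Mantel correlogram
   before any process inference.
4. **Niche breadth.** Levins' breadth per taxon,
   \(B_j = 1/\sum_i P_{ij}^2\), over the \(N\) local communities of a
   habitat; \(B_j\) ranges from 1 (specialist) to \(N\) (uniform
   generalist).
5. **Relative activity.** Per ASV and sample pair,
   \(\mathrm{RA} = \) RNA relative abundance / DNA relative abundance on
   the rarefied tables. ASVs detected only in DNA are kept with
   \(\mathrm{RA} = 0\); "phantom" taxa detected only in RNA are excluded.
   Among abundant groups (mean relative abundance > 0.1%), those with
   significantly higher RA in seep samples (two-sided Wilcoxon,
   Bonferroni-corrected, plus a direction check on medians) are flagged
   seep-active.

## Conventions and numerical choices

* **βMNTD self-matching.** The minimum in each direction runs over the taxa
  present in the *other* community, and a taxon present in both matches
  itself at distance 0. Identical communities therefore have
  βMNTD = 0, exactly as the printed form of the equation implies.
  `bmntd()` agrees with an exhaustive double-loop evaluation to 1e-10 and
  with `picante::comdistnt(abundance.weighted = TRUE)` to machine
  precision.
* **Null model.** Tip labels are shuffled jointly across the union of taxa
  observed anywhere in the metacommunity, holding each community's
  abundances and occupancy fixed. This is the standard "taxa labels"
  scheme for βNTI. Never-observed tips keep their positions; they take part
  in no community. Pairs whose null distribution has zero spread (e.g. on a
  star phylogeny, or two samples sharing every taxon) are flagged
  `undetermined` rather than given βNTI = 0/0.
* **Chao1** uses \(S + F_1^2/(2F_2)\), switching to the bias-corrected
  denominator \(S + F_1(F_1-1)/(2(F_2+1))\) when no doubletons exist.
* **Faith's PD** uses the rooted convention (the path to the root is
  included), so a one-ASV sample has PD equal to its root-to-tip distance
  and PD is monotone under ASV addition. **Pielou's evenness** is reported
  as missing for single-taxon samples rather than 0.
* **Levins' \(P_{ij}\)** is each taxon's occupancy profile normalized to
  sum to 1 across the \(N\) communities. Profiles are computed from counts;
  since tables are rarefied to a common depth upstream this equals the
  relative-abundance version, and it makes \(B_j\) exactly invariant to
  rescaling a taxon's counts.
* **Permutation p-values** always include the observed statistic:
  \(p \ge 1/(n_{\mathrm{perm}}+1)\); ANOSIM and Wilcoxon handle ties by
  midranks; Wilcoxon is exact for ≤ 25 observations per group without
  ties and normal-approximated with continuity correction otherwise.
* **Rarefaction depth** defaults to 90% of the smallest paired sample
  total, applied at a single common depth to DNA and RNA so RA ratios are
  comparable. ANOSIM and βNTI run on rarefied tables by default; both
  choices are configurable and echoed in output headers.
* **Signal gate.** If the phylogenetic-signal check fails, the βNTI stage
  warns by default and is skipped under `strict_signal = TRUE` — process
  inference without signal is not interpretable, but the advisory default
  lets users inspect the numbers.

## What the synthetic generator emulates

No sequencing data ship with the package; every downstream stage is
exercised on `simulate_study()` metacommunities with planted, recoverable
structure:

* **Phylogenetically conserved niches.** A pure-birth tree
  (`simulate_tree()`) and Brownian-motion environmental optima
  (`evolve_optima()`), so Var(opt\(_a\) − opt\(_b\)) = rate × patristic
  distance and close relatives prefer similar environments. This is what
  gives the Mantel correlogram its short-distance signal.
* **Selection versus neutrality.** Under selection the expected relative
  abundance of ASV \(j\) in sample \(i\) is proportional to
  pool\(_j \cdot \exp(-(env_i - opt_j)^2 / 2\sigma^2_{\mathrm{niche}})\);
  under neutrality it is proportional to pool\(_j\) alone. Reads are drawn
  multinomially, so column sums equal the configured depth exactly.
* **Ecological drift.** Each sample's expected abundances are additionally
  perturbed by a lognormal factor (`drift_sdlog`). This matters: without
  drift, replicate samples from one environment are near-identical, shared
  taxa self-match at distance zero in both the observed and the null
  βMNTD, and βNTI collapses toward 0/0 no matter how strong selection is.
  Compositional turnover between replicates is what the nearest-taxon
  framework measures.
* **Study geometry.** Five habitats (ROV1–5) of equal sample size; ROV1–3
  ("seep") assembled under selection with one environmental value per
  habitat spread across the optima range — filtering within a habitat is
  then *homogeneous*, as around a seep — and ROV4–5 ("non-seep") assembled
  neutrally.
* **Planted activity.** RNA expectations equal DNA relative abundances
  times per-ASV lognormal multipliers; a configurable fraction of ASVs is
  inactive (RNA expectation exactly 0) and a configurable fraction exists
  only in RNA (phantoms, injected with Poisson(5) reads). The generator
  returns the true status per ASV, so recovery is scored against ground
  truth, not against itself. A "seep-active" group is planted by boosting
  one clade-level group's RNA expectation in seep samples only.

**Default study conditions.** 1500-tip pool, 5 samples per habitat at
read depth 1000, `sigma_niche = 0.3` against Brownian optima with roughly
unit rate (tip optima spread ≈ 2 sd), `drift_sdlog = 1`, lognormal(0, 1.5)
pool abundances. Two of these deserve comment, because βNTI's power
depends on them and a naive generator produces no detectable selection at
all:

* *Sparse occupancy.* Per-sample richness must sit well below pool
  richness (here ≈ 150–250 of 1500). When most of the pool is present in
  every sample, a randomly relabeled taxon always finds a close neighbour
  in the other community and the null cannot exceed the observation. Real
  metabarcoding pools (10⁴–10⁵ ASVs against hundreds per sample) are far
  sparser than any tractable simulation, so this is the feature of real
  data the generator must preserve.
* *Moderate drift.* `drift_sdlog` around 1 creates enough turnover for the
  statistic to see while leaving many mid-abundance taxa contributing;
  very strong drift concentrates βMNTD's abundance weights on a few taxa
  and inflates the null spread. The neutral-calibration experiments at
  high depth (10⁴ reads over a 100-tip pool) use `drift_sdlog = 2`, since
  at saturating depth weaker drift leaves replicate communities sharing
  every taxon — the degenerate case flagged `undetermined`.

What passing tests on these synthetics do **not** show: robustness to
compositional biases of PCR and primers, chimeras or denoising artefacts,
overdispersion beyond multinomial sampling (a Dirichlet-multinomial switch
is deliberately off by default so oracles stay closed-form), rRNA copy
number variation between taxa, or genuinely multivariate environmental
filtering — `env` is one abstract gradient, not seep chemistry.

## Test and experiment sizes

The packaged experiments are sized to run in minutes on one CPU: βMNTD
oracle equivalence on 50 random ≤ 12-taxon instances; null calibration on
20 seeds × 190 pairs × 199 randomizations; selection recovery on 20 seeds
of the default study at 99 randomizations; signal recovery and type-I on
20 seeds of 200-tip trees; activity recovery at depth 10⁵; ANOSIM/Mantel
type-I on 200 replicates. `n_randomizations = 999` remains the default for
real inference.

## Known limitations

* βNTI on pairs of near-identical communities is undefined (zero null
  spread); such pairs are flagged, not silently dropped or zeroed.
* The Wilcoxon on pooled ASV × pair RA observations treats observations as
  exchangeable within regions; per-ASV means (`per_asv_mean = TRUE`) are
  available when pseudo-replication across pairs is a concern.
* The stochastic fraction is not partitioned further (no Raup–Crick step):
  pairs are homogeneous selection, heterogeneous selection, or stochastic.
* Accumulation curves use random permutations of whole samples; no
  individual-based rarefaction of curves.
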