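# seepecol

Community assembly, relative activity and multi-scale diversity for paired
DNA/RNA metabarcoding of cold-seep sediments.

## The problem

Cold seeps are seafloor habitats where methane- and sulphide-rich fluids
escape the sediment, creating steep environmental contrasts with the
surrounding seabed. Sequencing the same sediment sample twice — once from
DNA (everyone, alive or dead) and once from reverse-transcribed rRNA (the
putatively active fraction) — makes it possible to ask not just *who is
there* but *who is doing something*, and which ecological processes put
them there. `seepecol` implements that inference chain for ASV count
tables, a rooted phylogeny, a taxonomy and sample metadata:

* **Diversity at three scales** — per-sample richness, Chao1
  (S + F₁²/2F₂), Faith's PD (rooted), Pielou's evenness; Bray–Curtis
  dissimilarity; per-habitat gamma diversity compared through ASV
  accumulation curves at an equal number of samples; ANOSIM for group
  effects and Wilcoxon rank-sum tests for seep vs. non-seep contrasts.
* **Assembly processes** — the abundance-weighted β-mean nearest taxon
  distance between two communities,
  βMNTD = ½[Σᵢ f_ik · min_j Δ_ij + Σᵢ f_im · min_j Δ_ij],
  standardized against a tip-shuffle null model (999 randomizations) to
  the β-nearest taxon index, βNTI = (βMNTD_obs − μ_null)/σ_null.
  βNTI < −2 means homogeneous selection, βNTI > 2 heterogeneous
  selection, |βNTI| ≤ 2 stochastic assembly. A Mantel-correlogram
  phylogenetic-signal check gates the inference.
* **Niche breadth** — Levins' B_j = 1/Σᵢ P²_ij per taxon over the N local
  communities of a habitat (1 = specialist, N = uniform generalist).
* **Relative activity** — RA = RNA:DNA ratio of relative abundances on
  tables rarefied to a common depth; RA = 0 taxa are kept (present but
  silent), RNA-only "phantom" taxa are excluded; abundant groups
  (mean relative abundance > 0.1%) with significantly higher RA in seep
  samples (Wilcoxon + Bonferroni + direction check) are flagged
  **seep-active**.
* **A synthetic metacommunity generator** — Brownian niche evolution on a
  simulated phylogeny, Gaussian environmental filtering vs. neutral
  assembly with ecological drift, and paired RNA tables with planted
  inactive/phantom/boosted-activity structure, returned with ground truth
  so every stage of the chain is testable without sequencing data.

## Worked example

A full synthetic study — five ROV habitats, ROV1–3 assembled under
environmental filtering around seep-like conditions, ROV4–5 neutrally,
with a 10× RNA activity boost planted in one taxonomic group in the seep
samples — analysed end to end:

```r
library(seepecol)

study <- simulate_study(seed = 42, active_boost = 10)
cfg <- pipeline_config(dna = study$paired$dna, rna = study$paired$rna,
                       tree = study$tree, taxonomy = study$taxonomy,
                       metadata = study$metadata, seed = 42,
                       n_randomizations = 199, n_permutations = 499)
res <- run_pipeline(cfg, out_dir = "results")

res$anosim
#>    factor     R     p
#> 1 habitat 0.948 0.002
#> 2  region 0.000 0.422
#> 3   depth    NA    NA

res$signal
#> phylogenetic signal PRESENT (shortest class r = 0.013, p = 0.002)

res$process_summary
#>   habitat n_pairs median_bnti frac_homogeneous frac_stochastic frac_heterogeneous
#> 1    ROV1      10     -3.9432              1.0             0.0                0.0
#> 2    ROV2      10     -3.5099              0.9             0.1                0.0
#> 3    ROV3      10     -3.8829              0.8             0.2                0.0
#> 4    ROV4      10      0.7286              0.0             0.8                0.2
#> 5    ROV5      10     -0.0985              0.0             1.0                0.0

res$seep_active[, c("group", "median_ra_seep", "median_ra_nonseep",
                    "adjusted_p", "seep_active")]
#>      group median_ra_seep median_ra_nonseep adjusted_p seep_active
#> 1 Class_01          0.000                 0   1.94e-11       FALSE
#> 2 Class_03          0.600                 0   4.20e-14        TRUE
#> 3 Class_02          0.000                 0   4.12e-05       FALSE
#> ...
```

Reading the output: habitat identity structures composition strongly
(ANOSIM R = 0.95) while the within-region environmental spread leaves the
coarse seep/non-seep ANOSIM near 0; the phylogenetic-signal prerequisite
holds, so βNTI is interpretable; the selection-assembled seep habitats are
dominated by homogeneous selection (median βNTI ≈ −3.5 to −3.9, 80–100%
of pairs below −2) while the neutral habitats are stochastic; and the
planted active group (`Class_03`, here) is the only one flagged
seep-active — other groups reach small p-values in the *wrong* direction
(their RA is diluted by the boosted group in seep samples) and are
correctly rejected by the direction check. `res$region_contrasts` adds
the per-index seep vs. non-seep Wilcoxon comparisons, and every stage is
also written as a `#`-headed TSV under `results/`.

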