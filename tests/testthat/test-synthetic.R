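test_that("simulate_tree produces deterministic rooted binary trees", {
  tree <- simulate_tree(3, seed = 1)
  expect_equal(ape::Ntip(tree), 3)
  expect_equal(nrow(tree$edge), 4)  # rooted binary: 2n - 2 edges
  expect_identical(ape::write.tree(simulate_tree(3, seed = 1)),
                   ape::write.tree(tree))
  expect_error(simulate_tree(2, seed = 1), "n_tips")

  big <- simulate_tree(200, seed = 2)
  d <- patristic_distances(big)
  expect_true(is.finite(mean(d)) && mean(d) > 0)
})

test_that("evolve_optima follows the Brownian variance identity", {
  tree <- simulate_tree(5, seed = 3)
  # degenerate diffusion: rate -> 0 collapses to the root value
  o0 <- evolve_optima(tree, brownian_rate = 0, seed = 1, root_value = 1.5)
  expect_true(all(o0$optima == 1.5))
  # determinism
  expect_identical(evolve_optima(tree, 1, seed = 9)$optima,
                   evolve_optima(tree, 1, seed = 9)$optima)
  # Var(opt_A - opt_B) ~ rate * patristic distance, Monte Carlo
  rate <- 2
  d <- patristic_distances(tree)
  diffs <- vapply(seq_len(1000), function(s) {
    o <- evolve_optima(tree, rate, seed = 10000 + s)$optima
    o[["ASV_0001"]] - o[["ASV_0002"]]
  }, numeric(1))
  expect_lt(abs(var(diffs) / (rate * d["ASV_0001", "ASV_0002"]) - 1), 0.15)
})

test_that("simulate_metacommunity respects depth and the selection model", {
  tree <- simulate_tree(60, seed = 4)
  niche <- evolve_optima(tree, 1, seed = 5, sigma_niche = 0.3)
  sc <- assembly_scenario("selection", n_samples = 6,
                          env_values = seq(-1, 1, length.out = 6),
                          read_depth = 2000)
  sim <- simulate_metacommunity(tree, niche, sc, seed = 6)
  expect_true(all(colSums(sim$table) == 2000))
  expect_identical(sim$metadata$env, sc$env_values)

  # sigma -> Inf flattens the Gaussian: identical to neutral, same seed
  niche_flat <- niche; niche_flat$sigma_niche <- 1e9
  sc_n <- assembly_scenario("neutral", 6, sc$env_values, read_depth = 2000)
  flat <- simulate_metacommunity(tree, niche_flat, sc, seed = 7)
  neut <- simulate_metacommunity(tree, NULL, sc_n, seed = 7)
  expect_identical(unclass(flat$table), unclass(neut$table))

  # same env, pure selection, no drift, deep sequencing: near-identical
  sc_same <- assembly_scenario("selection", 2, c(0.2, 0.2), read_depth = 1e6)
  deep <- simulate_metacommunity(tree, niche, sc_same, seed = 8)
  expect_lt(max(bray_curtis(deep$table)), 0.02)

  # env far outside every niche
  sc_far <- assembly_scenario("selection", 1, 1e6, read_depth = 2000)
  expect_error(simulate_metacommunity(tree, niche, sc_far, seed = 9),
               "sigma_niche")
})

test_that("selection produces distance decay; neutrality does not", {
  tree <- simulate_tree(80, seed = 10)
  niche <- evolve_optima(tree, 1, seed = 11, sigma_niche = 0.4)
  rho_sel <- rho_neut <- numeric(10)
  for (s in 1:10) {
    env <- seq(quantile(niche$optima, 0.1), quantile(niche$optima, 0.9),
               length.out = 8)
    sc <- assembly_scenario("selection", 8, env, read_depth = 2000)
    sim <- simulate_metacommunity(tree, niche, sc, seed = 100 + s)
    bc <- as.vector(bray_curtis(sim$table))
    de <- as.vector(dist(env))
    rho_sel[s] <- cor(de, bc, method = "spearman")
    sc_n <- assembly_scenario("neutral", 8, env, read_depth = 2000,
                              drift_sdlog = 1)
    sim_n <- simulate_metacommunity(tree, NULL, sc_n, seed = 100 + s)
    rho_neut[s] <- cor(de, as.vector(bray_curtis(sim_n$table)),
                       method = "spearman")
  }
  expect_true(all(rho_sel > 0))
  # neutral: no systematic env-distance effect
  expect_lt(abs(mean(rho_neut)), 0.15)
})

test_that("simulate_paired_rna plants activity structure verifiably", {
  tree <- simulate_tree(50, seed = 12)
  sc <- assembly_scenario("neutral", 4, 0, read_depth = 1e5)
  dna <- simulate_metacommunity(tree, NULL, sc, seed = 13)$table

  # identity activity: all multipliers 1 -> RA near 1 for well-covered ASVs
  ident <- simulate_paired_rna(dna, activity_model(0, 0), seed = 14,
                               multipliers = setNames(rep(1, nrow(dna)),
                                                      rownames(dna)))
  ra <- relative_activity(ident, rarefaction_depth = 9e4, seed = 15)
  deep <- ra[unclass(dna)[cbind(ra$asv_id, ra$dna_sample)] >= 1000, ]
  expect_true(all(abs(deep$ra - 1) < 0.25))
  expect_true(all(ident$truth$status == "active"))

  # phantoms are injected into RNA only
  ph <- simulate_paired_rna(dna, activity_model(0.2, 0.1), seed = 16)
  phantoms <- ph$truth$asv_id[ph$truth$status == "phantom"]
  expect_gt(length(phantoms), 0)
  expect_false(any(phantoms %in% rownames(ph$dna)))
  expect_true(all(phantoms %in% rownames(ph$rna)))

  # determinism and invalid fractions
  ph2 <- simulate_paired_rna(dna, activity_model(0.2, 0.1), seed = 16)
  expect_identical(unclass(ph2$rna), unclass(ph$rna))
  expect_error(activity_model(0.7, 0.5), "exceed")
})

test_that("simulate_study wires habitats, taxonomy and truth together", {
  study <- simulate_study(n_tips = 100, n_per_habitat = 3, seed = 17,
                          read_depth = 1000, n_groups = 4)
  md <- study$metadata
  expect_identical(sort(unique(md$habitat)), paste0("ROV", 1:5))
  expect_identical(unique(md$region[md$habitat %in% c("ROV4", "ROV5")]),
                   "non-seep")
  expect_setequal(study$taxonomy$asv_id, study$tree$tip.label)
  expect_equal(length(unique(study$taxonomy$group)), 4)
  expect_true(all(colSums(study$paired$dna) == 1000))
})
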