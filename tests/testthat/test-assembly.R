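test_that("patristic distances are path sums, symmetric, zero-diagonal", {
  d <- patristic_distances(abc_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("patristic distances match a path-walking oracle", {
  tree <- simulate_tree(50, seed = 60)
  d <- patristic_distances(tree)
  set.seed(61)
  for (i in 1:100) {
    ab <- sample(tree$tip.label, 2)
    expect_equal(d[ab[1], ab[2]], brute_patristic(tree, ab[1], ab[2]),
                 tolerance = 1e-12)
  }
})

test_that("bmntd matches hand-computable cases", {
  d <- patristic_distances(abc_tree())
  # identical communities: every taxon self-matches at distance 0
  ck <- c(A = 3, B = 1, C = 2)
  expect_equal(bmntd(ck, ck, d), 0)
  # single-taxon communities collapse to the pairwise distance
  expect_equal(bmntd(c(A = 1, B = 0, C = 0), c(A = 0, B = 1, C = 0), d), 2)
  # k = {A: .5, C: .5}, m = {B: 1}: hand/brute-force evaluation
  ck <- c(A = 0.5, B = 0, C = 0.5)
  cm <- c(A = 0, B = 1, C = 0)
  expect_equal(bmntd(ck, cm, d), brute_bmntd(ck, cm, d))
  expect_equal(bmntd(ck, cm, d), 0.5 * ((0.5 * 2 + 0.5 * 4) + 1 * 2))
  expect_error(bmntd(c(A = 0, B = 0, C = 0), cm, d), "empty")
})

test_that("bmntd is symmetric, scale-invariant and duplicate-insensitive", {
  tree <- simulate_tree(30, seed = 62)
  d <- patristic_distances(tree)
  set.seed(63)
  for (i in 1:20) {
    ck <- setNames(rpois(30, 1), tree$tip.label)
    cm <- setNames(rpois(30, 1), tree$tip.label)
    if (sum(ck) == 0 || sum(cm) == 0) next
    expect_equal(bmntd(ck, cm, d), bmntd(cm, ck, d))
    expect_equal(bmntd(ck * 17, cm, d), bmntd(ck, cm, d))
  }
  # splitting abundance onto a taxon at an identical tree position
  # (zero-length sibling) leaves every min-distance, hence betaMNTD, unchanged
  t2 <- ape::read.tree(text = "((A:0,A2:0):1,(B:1,C:2):0.5);")
  d2 <- ape::cophenetic.phylo(t2)
  cm <- c(A = 2, A2 = 0, B = 1, C = 0)
  cm_dup <- c(A = 1, A2 = 1, B = 1, C = 0)  # A2 sits exactly at A
  ck <- c(A = 0, A2 = 0, B = 0, C = 1)
  expect_equal(bmntd(ck, cm, d2), bmntd(ck, cm_dup, d2))
})

test_that("bmntd agrees with the independent picante implementation", {
  tree <- simulate_tree(40, seed = 2)
  set.seed(68)
  ct <- community_table(matrix(rpois(40 * 6, 2), 40, 6,
                               dimnames = list(tree$tip.label,
                                               paste0("s", 1:6))))
  d <- patristic_distances(tree)
  ours <- bmntd_all(ct, d)
  pic <- as.matrix(picante::comdistnt(t(unclass(ct)), d,
                                      abundance.weighted = TRUE))
  expect_lt(max(abs(ours$bmntd_obs -
                      pic[cbind(ours$sample_k, ours$sample_m)])), 1e-12)
})

test_that("process classification follows the betaNTI thresholds", {
  expect_identical(classify_process(-3.1), "homogeneous_selection")
  expect_identical(classify_process(0), "stochastic")
  expect_identical(classify_process(2.5), "heterogeneous_selection")
  expect_identical(classify_process(c(-2, 2)), c("stochastic", "stochastic"))
  expect_error(classify_process(NaN), "non-finite")
})

test_that("null model flags degenerate trees and centers on the null mean", {
  # star phylogeny: every tip equidistant, all randomizations identical
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- cbind(s1 = c(1L, 1L, 0L, 0L), s2 = c(0L, 0L, 1L, 1L))
  rownames(m) <- c("A", "B", "C", "D")
  res <- bnti(community_table(m), star, n_randomizations = 99, seed = 1)
  expect_true(is.na(res$bnti))
  expect_identical(res$process, "undetermined")
  expect_equal(res$null_sd, 0)
})

test_that("observed statistic is exchangeable with null draws under no structure", {
  # communities with no phylogenetic structure: rank of obs among
  # {obs} U nulls is uniform
  tree <- simulate_tree(20, seed = 64)
  n_rand <- 99
  set.seed(65)
  ranks <- vapply(1:200, function(i) {
    repeat {
      ck <- setNames(rbinom(20, 1, 0.4) * rpois(20, 3), tree$tip.label)
      cm <- setNames(rbinom(20, 1, 0.4) * rpois(20, 3), tree$tip.label)
      if (sum(ck) > 0 && sum(cm) > 0) break
    }
    res <- null_bnti(ck, cm, tree, n_randomizations = n_rand,
                     seed = 1000 + i)
    stats::pnorm(res$bnti)  # smooth surrogate of the rank
  }, numeric(1))
  # uniformity check, coarse: mean near .5, no mass collapse in the tails
  expect_lt(abs(mean(ranks, na.rm = TRUE) - 0.5), 0.06)
  expect_lt(mean(ranks < 0.05, na.rm = TRUE), 0.12)
  expect_lt(mean(ranks > 0.95, na.rm = TRUE), 0.12)
})

test_that("within_habitat_pairs enumerates pairs inside each habitat", {
  md <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:5), habitat = c("ROV1", "ROV1", "ROV1", "ROV4", "ROV4"),
    depth_cmbs = 5))
  pairs <- within_habitat_pairs(md)
  expect_equal(nrow(pairs), choose(3, 2) + choose(2, 2))
  expect_true(all(pairs$habitat %in% c("ROV1", "ROV4")))
})

test_that("niche values are abundance-weighted environmental means", {
  m <- cbind(s1 = c(2L, 4L), s2 = c(2L, 0L))
  rownames(m) <- c("a", "b")
  env <- c(s1 = 1, s2 = 3)
  nv <- niche_values(community_table(m), env)
  # a: rel (1/3, 1) -> (1/3*1 + 1*3)/(4/3) = 2.5 ; b: only s1 -> 1
  expect_equal(unname(nv["a"]), (1 / 3 * 1 + 1 * 3) / (4 / 3))
  expect_equal(unname(nv["b"]), 1)
})

test_that("phylo_signal flags zero-variance traits and finds planted signal", {
  tree <- simulate_tree(80, seed = 66)
  d <- patristic_distances(tree)
  flat <- setNames(rep(1, 80), tree$tip.label)
  sig0 <- phylo_signal(flat, d, n_permutations = 99, seed = 1)
  expect_false(sig0$signal_present)
  expect_identical(sig0$flag, "zero_variance")

  opt <- evolve_optima(tree, 1, seed = 67)$optima
  sig <- phylo_signal(opt, d, n_permutations = 199, seed = 2)
  expect_true(sig$signal_present)
  expect_warning(phylo_signal(opt[1:20], d, n_permutations = 99, seed = 3),
                 "30 taxa")
})
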