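test_that("rarefy subsamples without replacement to exact depth", {
  ct <- community_table(matrix(c(100L, 0L, 0L, 40L, 30L, 30L), ncol = 2,
                               dimnames = list(c("a", "b", "c"),
                                               c("s1", "s2"))))
  r <- rarefy(ct, 100, seed = 1)
  expect_identical(unclass(r)[, "s1"], unclass(ct)[, "s1"])  # at own depth
  r50 <- rarefy(ct, 50, seed = 1)
  expect_identical(unname(unclass(r50)[, "s1"]), c(50L, 0L, 0L))
  expect_true(all(colSums(r50) == 50))
  expect_error(rarefy(ct, 0, seed = 1), "depth")
  # below-depth samples are dropped with a warning naming them
  uneq <- community_table(cbind(s1 = c(a = 50L, b = 0L), s2 = c(a = 40L, b = 60L)))
  expect_warning(r60 <- rarefy(uneq, 60, seed = 1), "s1")
  expect_identical(colnames(r60), "s2")
})

test_that("rarefy matches the hypergeometric expectation", {
  counts <- c(a = 30L, b = 50L, c = 20L)
  ct <- community_table(cbind(s1 = counts, s2 = counts))
  n <- counts["a"]; N <- sum(counts); d <- 40
  draws <- vapply(1:500, function(s) unclass(rarefy(ct, d, seed = s))["a", "s1"],
                  integer(1))
  mu <- n * d / N
  se <- sqrt(d * (n / N) * (1 - n / N) * (N - d) / (N - 1) / 500)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("alpha diversity indices match their closed forms", {
  m <- cbind(s1 = c(5L, 3L, 1L, 1L, 2L), s2 = c(4L, 4L, 4L, 4L, 4L),
             s3 = c(9L, 0L, 0L, 0L, 0L))
  rownames(m) <- paste0("t", 1:5)
  a <- alpha_diversity(community_table(m))
  # S = 5, F1 = 2, F2 = 1 -> chao1 = 5 + 4/2 = 7
  expect_equal(a$chao1[1], 7)
  expect_equal(a$richness, c(5L, 5L, 1L))
  expect_equal(a$pielou[2], 1)          # perfectly even
  expect_true(is.na(a$pielou[3]))       # single taxon: undefined
  # bias-corrected form when F2 = 0: S + F1(F1-1)/2
  b <- alpha_diversity(community_table(
    matrix(c(1L, 1L, 3L), dimnames = list(c("x", "y", "z"), "s"))))
  expect_equal(b$chao1, 3 + 2 * 1 / 2)
})

test_that("chao1 >= richness with equality when no singletons", {
  for (s in 1:20) {
    ct <- random_table(30, 4, seed = 300 + s, lambda = 2)
    a <- alpha_diversity(ct)
    expect_true(all(a$chao1 >= a$richness))
  }
  no_singletons <- community_table(
    matrix(c(5L, 4L, 3L), dimnames = list(c("x", "y", "z"), "s")))
  a <- alpha_diversity(no_singletons)
  expect_equal(a$chao1, a$richness)
})

test_that("Faith's PD uses the rooted convention and is monotone", {
  tree <- simulate_tree(20, seed = 20)
  m <- matrix(0L, 20, 3, dimnames = list(tree$tip.label, c("all", "one", "two")))
  m[, "all"] <- 1L
  m["ASV_0001", ] <- 1L
  m["ASV_0002", "two"] <- 1L
  a <- alpha_diversity(community_table(m), tree)
  expect_equal(a$faith_pd[a$sample_id == "all"], sum(tree$edge.length))
  d_root <- ape::node.depth.edgelength(tree)[1]  # root-to-tip distance
  expect_equal(a$faith_pd[a$sample_id == "one"], d_root)
  expect_gte(a$faith_pd[a$sample_id == "two"],
             a$faith_pd[a$sample_id == "one"])
})

test_that("bray_curtis matches the elementwise formula", {
  m <- cbind(s1 = c(2L, 1L, 0L), s2 = c(0L, 1L, 3L), s3 = c(2L, 1L, 0L),
             s4 = c(0L, 0L, 5L))
  rownames(m) <- c("a", "b", "c")
  bc <- as.matrix(bray_curtis(community_table(m)))
  x <- c(2, 1, 0) / 3; y <- c(0, 1, 3) / 4
  expect_equal(bc["s1", "s2"], sum(abs(x - y)) / sum(x + y))
  expect_equal(bc["s1", "s3"], 0)          # identical composition
  expect_equal(bc["s1", "s4"], 1)          # disjoint ASV sets
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
})

test_that("accumulation curves match the analytic expectation", {
  ct <- random_table(40, 8, seed = 33, lambda = 1)
  hab <- setNames(rep("ROV1", 8), colnames(ct))
  ac <- accumulation_curve(ct, hab, n_permutations = 1000, n_sites_cap = 8,
                           seed = 7)
  counts <- unclass(ct)
  expect_equal(ac$mean_richness[1], mean(colSums(counts > 0)), tolerance = 0.05)
  # value at N exhausts the pool
  expect_equal(ac$mean_richness[8], sum(rowSums(counts) > 0))
  expect_equal(ac$sd_richness[8], 0)
  # monotone non-decreasing
  expect_true(all(diff(ac$mean_richness) >= 0))
  # hypergeometric closed form within 3 SE at 1000 permutations
  for (n in c(2, 4, 6)) {
    exp_n <- accum_expectation(counts, n)
    se <- ac$sd_richness[n] / sqrt(1000)
    expect_lt(abs(ac$mean_richness[n] - exp_n), 3 * se + 1e-9)
  }
})

test_that("gamma diversity counts total richness per habitat", {
  ct <- random_table(30, 6, seed = 44, lambda = 1)
  hab <- setNames(rep(c("ROV1", "ROV4"), each = 3), colnames(ct))
  g <- gamma_diversity(ct, hab)
  m <- unclass(ct)
  expect_equal(g$gamma_richness[g$habitat == "ROV1"],
               sum(rowSums(m[, 1:3]) > 0))
})

test_that("anosim separates separable groups and errors on singletons", {
  # all within-group distances < all between-group distances -> R = 1
  m <- cbind(a1 = c(10L, 0L, 1L), a2 = c(9L, 1L, 1L), a3 = c(10L, 1L, 0L),
             b1 = c(0L, 10L, 1L), b2 = c(1L, 9L, 1L), b3 = c(0L, 10L, 0L))
  rownames(m) <- c("x", "y", "z")
  bc <- bray_curtis(community_table(m))
  res <- anosim_test(bc, rep(c("A", "B"), each = 3), n_permutations = 199,
                     seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p, 1 / 200)
  # two identical groups of identical samples -> R = 0 under midranks
  ident <- matrix(5L, 2, 6, dimnames = list(c("x", "y"), paste0("s", 1:6)))
  bc0 <- bray_curtis(community_table(ident))
  res0 <- anosim_test(bc0, rep(c("A", "B"), each = 3), n_permutations = 99,
                      seed = 1)
  expect_equal(res0$R, 0)
  expect_error(anosim_test(bc, c("A", "A", "A", "A", "A", "B")), "single")
})

test_that("anosim R is invariant to monotone transforms of the distances", {
  ct <- random_table(25, 8, seed = 55)
  bc <- bray_curtis(ct)
  g <- rep(c("A", "B"), each = 4)
  r1 <- anosim_test(bc, g, n_permutations = 99, seed = 2)$R
  r2 <- anosim_test(bc^3, g, n_permutations = 99, seed = 2)$R
  expect_equal(r1, r2)
})
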