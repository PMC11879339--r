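# Shared fixtures and independent oracles, all built in code.

abc_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

tiny_table <- function() {
  community_table(matrix(c(5, 0, 2, 1, 0, 4), nrow = 3, byrow = TRUE,
                         dimnames = list(paste0("ASV_", 1:3), c("s1", "s2"))))
}

random_table <- function(n_asv, n_samples, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_asv * n_samples, lambda), n_asv, n_samples,
              dimnames = list(sprintf("ASV_%03d", seq_len(n_asv)),
                              sprintf("S%02d", seq_len(n_samples))))
  m[, colSums(m) == 0] <- 1L
  community_table(m)
}

# Exhaustive double-loop evaluation of the betaMNTD equation; deliberately
# naive and independent of the package's vectorized implementation.
brute_bmntd <- function(comm_k, comm_m, D) {
  ik <- names(comm_k)[comm_k > 0]
  im <- names(comm_m)[comm_m > 0]
  f_k <- comm_k[ik] / sum(comm_k[ik])
  f_m <- comm_m[im] / sum(comm_m[im])
  s1 <- 0
  for (i in ik) {
    mn <- Inf
    for (j in im) mn <- min(mn, D[i, j])
    s1 <- s1 + f_k[[i]] * mn
  }
  s2 <- 0
  for (i in im) {
    mn <- Inf
    for (j in ik) mn <- min(mn, D[i, j])
    s2 <- s2 + f_m[[i]] * mn
  }
  0.5 * (s1 + s2)
}

# Path-walking patristic distance: walks the node path between two tips and
# sums edge lengths, independent of cophenetic().
brute_patristic <- function(tree, a, b) {
  path <- ape::nodepath(tree, which(tree$tip.label == a),
                        which(tree$tip.label == b))
  total <- 0
  for (i in seq_len(length(path) - 1)) {
    u <- path[i]; v <- path[i + 1]
    row <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                   (tree$edge[, 1] == v & tree$edge[, 2] == u))
    total <- total + tree$edge.length[row]
  }
  total
}

# Analytic species-accumulation expectation:
# S_exp(n) = sum_j [1 - C(N - m_j, n) / C(N, n)]
accum_expectation <- function(counts, n) {
  N <- ncol(counts)
  occ <- rowSums(counts > 0)
  sum(1 - choose(N - occ, n) / choose(N, n))
}
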