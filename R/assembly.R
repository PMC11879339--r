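#' Pairwise patristic distances between tree tips
#'
#' @param tree a [ape::phylo] tree with branch lengths.
#' @return symmetric numeric matrix of path-length distances, zero diagonal.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  ape::cophenetic.phylo(tree)
}

# Row minima of a (sub)matrix via max.col on the negated matrix: C-level,
# far faster than apply(., 1, min) inside the randomization loop.
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

bmntd_core <- function(f_k, f_m, d_sub) {
  # d_sub: rows = taxa present in k, cols = taxa present in m
  0.5 * (sum(f_k * row_mins(d_sub)) + sum(f_m * row_mins(t(d_sub))))
}

#' Abundance-weighted beta mean nearest taxon distance (betaMNTD)
#'
#' For communities k and m,
#' `betaMNTD = 0.5 * [ sum_i f_ik min_j D_ij + sum_i f_im min_j D_ij ]`,
#' where f are relative abundances over the taxa present in that community
#' and the minimum runs over the taxa present (count > 0) in the *other*
#' community. A taxon present in both communities matches itself at
#' distance 0, so identical communities give betaMNTD = 0.
#'
#' @param comm_k,comm_m named non-negative abundance vectors (counts or
#'   relative abundances; only ratios matter). Names must index `dist`.
#' @param dist patristic distance matrix from [patristic_distances()].
#' @return a single non-negative number; symmetric in its two communities.
#' @export
bmntd <- function(comm_k, comm_m, dist) {
  ik <- names(comm_k)[comm_k > 0]
  im <- names(comm_m)[comm_m > 0]
  if (!length(ik) || !length(im)) stop("empty community", call. = FALSE)
  missing <- setdiff(c(ik, im), rownames(dist))
  if (length(missing)) {
    stop("distance matrix lacks taxa: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  f_k <- comm_k[ik] / sum(comm_k[ik])
  f_m <- comm_m[im] / sum(comm_m[im])
  bmntd_core(f_k, f_m, dist[ik, im, drop = FALSE])
}

#' All pairwise betaMNTD values of a community table
#'
#' @param table a [community_table].
#' @param dist patristic distance matrix covering the table's ASVs.
#' @param pairs optional 2-column matrix/data.frame of sample-id pairs;
#'   defaults to all unordered sample pairs.
#' @return data.frame with `sample_k`, `sample_m`, `bmntd_obs`.
#' @export
bmntd_all <- function(table, dist, pairs = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(colnames(table), 2)
    pairs <- data.frame(sample_k = cmb[1, ], sample_m = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(sample_k = as.character(pairs[[1]]),
                        sample_m = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
  }
  prep <- prep_communities(table, dist)
  obs <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- prep[[pairs$sample_k[r]]]
    b <- prep[[pairs$sample_m[r]]]
    bmntd_core(a$f, b$f, dist[a$idx, b$idx, drop = FALSE])
  }, numeric(1))
  cbind(pairs, bmntd_obs = obs)
}

prep_communities <- function(table, dist) {
  m <- unclass(table)
  missing <- setdiff(rownames(m)[rowSums(m) > 0], rownames(dist))
  if (length(missing)) {
    stop("distance matrix lacks taxa: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    idx <- rownames(m)[x > 0]
    if (!length(idx)) stop("empty community: ", colnames(m)[j], call. = FALSE)
    list(idx = match(idx, rownames(dist)), f = x[x > 0] / sum(x[x > 0]))
  })
  names(out) <- colnames(m)
  out
}

#' betaNTI via a tip-shuffle null model
#'
#' The null distribution shuffles the tip labels of the phylogeny across the
#' full taxon pool of the table (equivalently, jointly permutes the rows and
#' columns of the patristic matrix), holding abundances and occupancy fixed,
#' and recomputes betaMNTD for every pair at each randomization. The beta
#' nearest taxon index is the standardized deviation
#' `(observed - null mean) / null sd`. Pairs whose null distribution has
#' zero spread (e.g. a star phylogeny) are flagged and classified
#' `undetermined`.
#'
#' @param table a [community_table].
#' @param tree phylogeny covering the table's ASVs (or a precomputed
#'   patristic matrix).
#' @param n_randomizations null draws (>= 99; 999 for final inference).
#' @param seed integer seed.
#' @param pairs optional 2-column sample-pair specification (see
#'   [bmntd_all()]); use [within_habitat_pairs()] to restrict inference to
#'   pairs inside each ROV.
#' @return data.frame of class `assembly_result`: one row per pair with
#'   `bmntd_obs`, `null_mean`, `null_sd`, `n_randomizations`, `bnti`,
#'   `process`.
#' @export
bnti <- function(table, tree, n_randomizations = 999, seed = 1,
                 pairs = NULL) {
  if (n_randomizations < 99) stop("n_randomizations must be >= 99",
                                  call. = FALSE)
  dist <- if (inherits(tree, "phylo")) patristic_distances(tree) else tree
  res <- bmntd_all(table, dist, pairs = pairs)
  prep <- prep_communities(table, dist)
  # shuffle tip labels across the union of taxa observed in the
  # metacommunity (never-observed tips keep their positions: they take no
  # part in any community)
  observed <- sort(match(rownames(table)[rowSums(table) > 0],
                         rownames(dist)))
  np <- nrow(res)
  nulls <- matrix(NA_real_, nrow = np, ncol = n_randomizations)
  set.seed(seed)
  perm <- seq_len(nrow(dist))
  for (r in seq_len(n_randomizations)) {
    perm[observed] <- sample(observed)
    for (p in seq_len(np)) {
      a <- prep[[res$sample_k[p]]]
      b <- prep[[res$sample_m[p]]]
      nulls[p, r] <- bmntd_core(a$f, b$f,
                                dist[perm[a$idx], perm[b$idx], drop = FALSE])
    }
  }
  res$null_mean <- rowMeans(nulls)
  res$null_sd <- apply(nulls, 1, stats::sd)
  res$n_randomizations <- n_randomizations
  res$bnti <- ifelse(res$null_sd > 0,
                     (res$bmntd_obs - res$null_mean) / res$null_sd, NA_real_)
  res$process <- ifelse(is.na(res$bnti), "undetermined",
                        classify_process(ifelse(is.na(res$bnti), 0, res$bnti)))
  class(res) <- c("assembly_result", "data.frame")
  res
}

#' betaNTI for a single pair of communities
#'
#' @param comm_k,comm_m named abundance vectors over a shared taxon set.
#' @param tree phylogeny (or patristic matrix) covering both communities.
#' @inheritParams bnti
#' @return a one-row `assembly_result` data.frame.
#' @export
null_bnti <- function(comm_k, comm_m, tree, n_randomizations = 999,
                      seed = 1) {
  taxa <- union(names(comm_k), names(comm_m))
  m <- cbind(k = comm_k[taxa], m = comm_m[taxa])
  m[is.na(m)] <- 0
  rownames(m) <- taxa
  bnti(community_table(m), tree, n_randomizations = n_randomizations,
       seed = seed)
}

#' Classify the ecological assembly process from betaNTI
#'
#' betaNTI < -2: significantly less phylogenetic turnover than the null
#' expectation (homogeneous selection); betaNTI > 2: significantly more
#' (heterogeneous selection); |betaNTI| <= 2: stochastic processes such as
#' dispersal and ecological drift.
#'
#' @param bnti numeric vector of finite betaNTI values.
#' @return character vector: `homogeneous_selection`, `stochastic` or
#'   `heterogeneous_selection`.
#' @export
classify_process <- function(bnti) {
  if (any(!is.finite(bnti))) stop("non-finite betaNTI", call. = FALSE)
  ifelse(bnti < -2, "homogeneous_selection",
         ifelse(bnti > 2, "heterogeneous_selection", "stochastic"))
}

#' Within-habitat sample pairs
#'
#' @param metadata a [sample_metadata] data.frame.
#' @param samples optional subset of sample ids to pair.
#' @return data.frame `sample_k`, `sample_m`, `habitat` of all unordered
#'   pairs inside each habitat.
#' @export
within_habitat_pairs <- function(metadata, samples = NULL) {
  if (is.null(samples)) samples <- metadata$sample_id
  md <- metadata[metadata$sample_id %in% samples, ]
  out <- lapply(split(md$sample_id, md$habitat), function(s) {
    if (length(s) < 2) return(NULL)
    cmb <- utils::combn(s, 2)
    data.frame(sample_k = cmb[1, ], sample_m = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  hab <- rep(names(out), vapply(out, function(x) if (is.null(x)) 0L
                                else nrow(x), integer(1)))
  res <- do.call(rbind, out)
  res$habitat <- hab
  rownames(res) <- NULL
  res
}

#' Summarize assembly processes per habitat
#'
#' @param result an `assembly_result` from [bnti()] with a `habitat` column
#'   (present when `pairs` came from [within_habitat_pairs()]), or any
#'   grouping vector of the same length.
#' @param habitat optional explicit grouping.
#' @return data.frame of per-habitat pair counts, median betaNTI and the
#'   fraction of pairs per process class.
#' @export
process_fractions <- function(result, habitat = result$habitat) {
  if (is.null(habitat)) habitat <- rep("all", nrow(result))
  out <- lapply(split(result, habitat), function(d) {
    data.frame(n_pairs = nrow(d),
               median_bnti = stats::median(d$bnti, na.rm = TRUE),
               frac_homogeneous = mean(d$process == "homogeneous_selection"),
               frac_stochastic = mean(d$process == "stochastic"),
               frac_heterogeneous = mean(d$process == "heterogeneous_selection"))
  })
  data.frame(habitat = names(out), do.call(rbind, out), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Abundance-weighted niche value per ASV
#'
#' The environmental "position" of each ASV: the mean of an environmental
#' variable across samples, weighted by the ASV's relative abundance. Used
#' as the trait in the phylogenetic-signal prerequisite check.
#'
#' @param table a [community_table].
#' @param env numeric environmental value per sample (named, or in the
#'   column order of `table`).
#' @return named numeric vector over ASVs present in the table.
#' @export
niche_values <- function(table, env) {
  rel <- relative_abundance(table)
  if (!is.null(names(env))) env <- env[colnames(table)]
  stopifnot(length(env) == ncol(table))
  w <- rowSums(rel)
  keep <- w > 0
  (rel %*% env)[keep, 1] / w[keep]
}

#' Phylogenetic-signal check by Mantel correlogram
#'
#' Tests, per phylogenetic-distance class, whether between-ASV differences
#' in niche value correlate with phylogenetic distance. A significantly
#' positive correlation in the shortest distance class licenses the use of
#' phylogenetic turnover (betaMNTD/betaNTI) for ecological inference.
#'
#' @param niche named numeric niche values per ASV (e.g. [niche_values()] or
#'   the generating optima of synthetic data).
#' @param dist patristic distance matrix covering `names(niche)`.
#' @param n_classes number of distance classes (NULL = Sturges default).
#' @param n_permutations Mantel permutations per class.
#' @param seed integer seed.
#' @return object of class `signal_correlogram`: list with `classes`
#'   (data.frame: `class_index`, `n_dist`, `mantel_r`, `p`),
#'   `signal_present` (positive and p < 0.05 in the shortest class) and
#'   `flag` (e.g. zero-variance niche values).
#' @export
phylo_signal <- function(niche, dist, n_classes = NULL,
                         n_permutations = 999, seed = 1) {
  taxa <- names(niche)
  if (length(taxa) < 30) {
    warning("fewer than 30 taxa; phylogenetic-signal test is unreliable",
            call. = FALSE)
  }
  missing <- setdiff(taxa, rownames(dist))
  if (length(missing)) stop("distance matrix lacks taxa", call. = FALSE)
  if (stats::var(niche) == 0) {
    return(structure(list(classes = NULL, signal_present = FALSE,
                          flag = "zero_variance"),
                     class = "signal_correlogram"))
  }
  d_niche <- stats::dist(niche)
  d_phylo <- stats::as.dist(dist[taxa, taxa])
  set.seed(seed)
  mc <- vegan::mantel.correlog(d_niche, D.geo = d_phylo, n.class =
                                 if (is.null(n_classes)) 0 else n_classes,
                               nperm = n_permutations, mult = "holm")
  res <- as.data.frame(mc$mantel.res)
  classes <- data.frame(class_index = res[, "class.index"],
                        n_dist = res[, "n.dist"],
                        mantel_r = res[, "Mantel.cor"],
                        p = res[, "Pr(Mantel)"], row.names = NULL)
  tested <- which(!is.na(classes$p))
  signal <- length(tested) > 0 &&
    classes$mantel_r[tested[1]] > 0 && classes$p[tested[1]] < 0.05
  structure(list(classes = classes, signal_present = signal, flag = NULL),
            class = "signal_correlogram")
}

#' @export
print.signal_correlogram <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("phylogenetic signal: flagged (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf("phylogenetic signal %s (shortest class r = %.3f, p = %.4g)\n",
                if (x$signal_present) "PRESENT" else "absent",
                x$classes$mantel_r[1], x$classes$p[1]))
  }
  invisible(x)
}
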