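#' Rarefy a count table to a common depth
#'
#' Subsampling without replacement (hypergeometric) per sample. Samples with
#' fewer reads than `depth` are dropped with a warning listing them.
#'
#' @param table a [community_table].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed.
#' @return a [community_table] in which every retained sample sums exactly
#'   to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "community_table"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  depth <- as.integer(depth)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  if (any(!keep)) {
    warning("dropped below-depth sample(s): ",
            paste(colnames(table)[!keep], collapse = ", "), call. = FALSE)
  }
  m <- unclass(table)[, keep, drop = FALSE]
  set.seed(seed)
  # rrarefy heuristically warns when the smallest count exceeds 1; counts
  # here are already validated integers, so that warning is noise
  r <- withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  community_table(r)
}

chao1_index <- function(x) {
  x <- x[x > 0]
  s <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity (richness, Chao1, Faith's PD, Pielou)
#'
#' Chao1 is `S + F1^2 / (2 F2)` with the bias-corrected denominator
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` when no doubletons exist. Faith's PD
#' uses the rooted convention (the path to the root is included, so a
#' single-ASV sample gets its root-to-tip distance and PD stays monotone
#' under ASV addition). Pielou's evenness `(-sum p log p) / log S` is
#' reported as NA for single-taxon samples.
#'
#' @param table a [community_table].
#' @param tree optional phylogeny covering all ASVs present in the table;
#'   when NULL, `faith_pd` is NA.
#' @return data.frame with columns `sample_id`, `richness`, `chao1`,
#'   `faith_pd`, `pielou`.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  stopifnot(inherits(table, "community_table"))
  m <- unclass(table)
  richness <- colSums(m > 0)
  chao1 <- apply(m, 2, chao1_index)
  shannon <- apply(m, 2, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  pielou <- ifelse(richness >= 2, shannon / log(richness), NA_real_)
  faith <- rep(NA_real_, ncol(m))
  if (!is.null(tree)) {
    present <- rownames(m)[rowSums(m) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing)) {
      stop("tree lacks tip(s): ", paste(utils::head(missing, 5),
                                        collapse = ", "), call. = FALSE)
    }
    faith <- picante::pd(t(m), tree, include.root = TRUE)$PD
  }
  data.frame(sample_id = colnames(m), richness = as.integer(richness),
             chao1 = chao1, faith_pd = faith, pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on within-sample relative abundances, so differing library sizes
#' do not inflate the dissimilarity.
#'
#' @param table a [community_table] with at least 2 samples.
#' @return a [stats::dist] over samples, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (ncol(table) < 2) stop("need >= 2 samples", call. = FALSE)
  vegan::vegdist(t(relative_abundance(table)), method = "bray")
}

#' Gamma diversity (total ASV richness) per habitat
#'
#' @param table a [community_table].
#' @param habitats named character vector (sample_id -> habitat) or a
#'   [sample_metadata] data.frame.
#' @return data.frame with columns `habitat`, `n_samples`, `gamma_richness`.
#' @export
gamma_diversity <- function(table, habitats) {
  hab <- habitat_lookup(habitats, colnames(table))
  out <- lapply(split(colnames(table), hab), function(s) {
    m <- unclass(table)[, s, drop = FALSE]
    data.frame(n_samples = length(s),
               gamma_richness = sum(rowSums(m) > 0))
  })
  data.frame(habitat = names(out), do.call(rbind, out), row.names = NULL,
             stringsAsFactors = FALSE)
}

habitat_lookup <- function(habitats, sample_ids) {
  if (inherits(habitats, "data.frame")) {
    habitats <- stats::setNames(habitats$habitat, habitats$sample_id)
  }
  hab <- habitats[sample_ids]
  if (anyNA(hab)) {
    stop("no habitat for sample(s): ",
         paste(sample_ids[is.na(hab)], collapse = ", "), call. = FALSE)
  }
  hab
}

#' ASV accumulation curves per habitat
#'
#' Random-permutation species accumulation (the `specaccum` "random"
#' method), truncated at a common number of sites so habitats with unequal
#' sampling are compared at an equal number of samples.
#'
#' @param table a [community_table].
#' @param habitats named vector (sample_id -> habitat) or [sample_metadata].
#' @param n_permutations random site orderings (>= 100).
#' @param n_sites_cap report curves up to this many sites; defaults to the
#'   smallest habitat size.
#' @param seed integer seed.
#' @return object of class `accumulation_curve`: a data.frame with columns
#'   `habitat`, `n_sites`, `mean_richness`, `sd_richness`, `flagged`.
#' @export
accumulation_curve <- function(table, habitats, n_permutations = 100,
                               n_sites_cap = NULL, seed = 1) {
  if (n_permutations < 100) stop("n_permutations must be >= 100",
                                 call. = FALSE)
  hab <- habitat_lookup(habitats, colnames(table))
  groups <- split(colnames(table), hab)
  if (is.null(n_sites_cap)) n_sites_cap <- min(lengths(groups))
  set.seed(seed)
  res <- lapply(names(groups), function(h) {
    s <- groups[[h]]
    m <- t(unclass(table)[, s, drop = FALSE])
    if (length(s) < 2) {
      return(data.frame(habitat = h, n_sites = 1L,
                        mean_richness = sum(m > 0), sd_richness = 0,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    sa <- vegan::specaccum(m, method = "random",
                           permutations = n_permutations)
    k <- seq_len(min(n_sites_cap, length(sa$sites)))
    data.frame(habitat = h, n_sites = as.integer(sa$sites[k]),
               mean_richness = sa$richness[k], sd_richness = sa$sd[k],
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' @export
plot.accumulation_curve <- function(x, ...) {
  habs <- unique(x$habitat)
  cols <- grDevices::hcl.colors(length(habs), "Dark 3")
  graphics::plot(NA, xlim = range(x$n_sites),
                 ylim = c(0, max(x$mean_richness + x$sd_richness)),
                 xlab = "Number of samples", ylab = "Cumulative ASV richness",
                 ...)
  for (i in seq_along(habs)) {
    xi <- x[x$habitat == habs[i], ]
    graphics::lines(xi$n_sites, xi$mean_richness, col = cols[i], lwd = 2)
    graphics::arrows(xi$n_sites, xi$mean_richness - xi$sd_richness,
                     xi$n_sites, xi$mean_richness + xi$sd_richness,
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("bottomright", legend = habs, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group distances. R near 1
#' means groups are well separated; near 0, no separation. The permutation
#' p-value includes the observed statistic: p >= 1/(n_permutations + 1).
#'
#' @param dist a [stats::dist] over samples (e.g. from [bray_curtis()]).
#' @param grouping factor/character of group labels, one per sample; every
#'   group must have >= 2 members.
#' @param n_permutations number of label permutations.
#' @param seed integer seed.
#' @return list with `R`, `p`, `n_permutations`, and the underlying
#'   [vegan::anosim] fit in `$fit`.
#' @export
anosim_test <- function(dist, grouping, n_permutations = 999, seed = 1) {
  grouping <- as.factor(grouping)
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) with a single member: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  fit <- vegan::anosim(dist, grouping, permutations = n_permutations)
  list(R = unname(fit$statistic), p = fit$signif,
       n_permutations = n_permutations, fit = fit)
}
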