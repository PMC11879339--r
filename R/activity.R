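#' Per-ASV relative activity (RNA:DNA ratio) on rarefied tables
#'
#' Both tables are rarefied to a single common depth, then for every sample
#' pair RA = (RNA relative abundance) / (DNA relative abundance), a proxy of
#' relative metabolic activity. ASVs detected only in DNA are kept with
#' RA = 0 (inactive but present, e.g. dead or dormant cells); "phantom"
#' taxa detected only in RNA are recorded but excluded from every RA
#' summary.
#'
#' @param paired a [paired_community()].
#' @param rarefaction_depth common depth; the default is 90% of the smallest
#'   sample total across both libraries.
#' @param seed integer seed for the rarefaction.
#' @return data.frame of class `activity_table` with columns `asv_id`,
#'   `pair_key`, `dna_sample`, `rna_sample`, `ra`, `status`
#'   (active/inactive/phantom). Attribute `rarefaction_depth` records the
#'   depth used. Phantom rows carry `ra = NA`.
#' @export
relative_activity <- function(paired, rarefaction_depth = NULL, seed = 1) {
  stopifnot(inherits(paired, "paired_community"))
  if (is.null(rarefaction_depth)) {
    rarefaction_depth <- floor(0.9 * min(colSums(paired$dna),
                                         colSums(paired$rna)))
  }
  dna_r <- rarefy(paired$dna, rarefaction_depth, seed = seed)
  rna_r <- rarefy(paired$rna, rarefaction_depth, seed = seed + 1)
  pairs <- paired$pairs
  keep <- pairs$dna_sample %in% colnames(dna_r) &
    pairs$rna_sample %in% colnames(rna_r)
  if (!any(keep)) stop("no pairs survive rarefaction at depth ",
                       rarefaction_depth, call. = FALSE)
  pairs <- pairs[keep, , drop = FALSE]
  asvs <- union(rownames(dna_r), rownames(rna_r))
  d <- matrix(0L, length(asvs), nrow(pairs), dimnames = list(asvs, NULL))
  r <- d
  d[rownames(dna_r), ] <- unclass(dna_r)[, pairs$dna_sample]
  r[rownames(rna_r), ] <- unclass(rna_r)[, pairs$rna_sample]
  rel_d <- d / rarefaction_depth
  rel_r <- r / rarefaction_depth
  out <- lapply(seq_len(nrow(pairs)), function(j) {
    in_dna <- rel_d[, j] > 0
    in_rna <- rel_r[, j] > 0
    idx <- which(in_dna | in_rna)
    status <- ifelse(!in_dna[idx], "phantom",
                     ifelse(in_rna[idx], "active", "inactive"))
    ra <- ifelse(in_dna[idx], rel_r[idx, j] / rel_d[idx, j], NA_real_)
    data.frame(asv_id = asvs[idx], pair_key = pairs$key[j],
               dna_sample = pairs$dna_sample[j],
               rna_sample = pairs$rna_sample[j],
               ra = ra, status = status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "rarefaction_depth") <- rarefaction_depth
  class(res) <- c("activity_table", "data.frame")
  res
}

#' Abundant groups of a community
#'
#' Groups (class or phylum level) whose mean relative abundance across
#' samples is strictly above the threshold (default 0.1%).
#'
#' @param table a [community_table].
#' @param taxonomy a [taxonomy_map()] covering the table's ASVs.
#' @param threshold relative-abundance threshold (fraction, default 0.001).
#' @return character vector of abundant group names; the full per-group
#'   mean relative abundances are attached as attribute `"summary"`.
#' @export
abundant_groups <- function(table, taxonomy, threshold = 0.001) {
  grp <- group_of(rownames(table), taxonomy)
  rel <- relative_abundance(table)
  by_group <- rowsum(rel, grp)
  means <- rowMeans(by_group)
  means <- sort(means, decreasing = TRUE)
  out <- names(means)[means > threshold]
  attr(out, "summary") <- data.frame(group = names(means),
                                     mean_rel_abundance = unname(means),
                                     stringsAsFactors = FALSE)
  out
}

group_of <- function(asv_ids, taxonomy) {
  g <- taxonomy$group[match(asv_ids, taxonomy$asv_id)]
  g[is.na(g)] <- "unclassified"
  g
}

#' Identify seep-active groups from relative activity
#'
#' For each abundant group, pools the RA values of its ASVs (one observation
#' per ASV x sample pair, RA = 0 included, phantoms excluded) by region and
#' runs a two-sided Wilcoxon rank-sum test; p-values are Bonferroni-adjusted
#' across the groups tested. A group is seep-active when its adjusted p is
#' below `alpha` AND its seep median RA exceeds the non-seep median (the
#' direction check keeps significantly *less* active groups out).
#'
#' @param activity an `activity_table` from [relative_activity()].
#' @param taxonomy a [taxonomy_map()].
#' @param metadata [sample_metadata]; regions are looked up by pair key.
#' @param abundant character vector of groups to test (from
#'   [abundant_groups()]).
#' @param alpha significance level (default 0.05).
#' @param per_asv_mean pool per-ASV mean RA instead of ASV x pair
#'   observations.
#' @param manual_include groups to flag seep-active regardless of the test;
#'   recorded in the `manual` column, never applied silently.
#' @return data.frame of class `group_activity_summary`: per group the
#'   region medians, `p`, `adjusted_p`, `seep_active`, `manual`.
#' @export
seep_active_groups <- function(activity, taxonomy, metadata, abundant,
                               alpha = 0.05, per_asv_mean = FALSE,
                               manual_include = NULL) {
  act <- activity[activity$status != "phantom", , drop = FALSE]
  idx <- match(act$pair_key, metadata$sample_id)
  idx[is.na(idx)] <- match(act$dna_sample,
                           metadata$sample_id)[is.na(idx)]
  if (anyNA(idx)) stop("metadata lacks entries for some pairs",
                       call. = FALSE)
  act$region <- metadata$region[idx]
  act$group <- group_of(act$asv_id, taxonomy)
  rows <- lapply(abundant, function(g) {
    d <- act[act$group == g, , drop = FALSE]
    if (per_asv_mean && nrow(d)) {
      agg <- stats::aggregate(ra ~ asv_id + region, data = d, FUN = mean)
      d <- agg
    }
    x <- d$ra[d$region == "seep"]
    y <- d$ra[d$region == "non-seep"]
    if (!length(x) || !length(y)) {
      message("group skipped (region without RA observations): ", g)
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(group = g, n_seep = length(x), n_nonseep = length(y),
               median_ra_seep = stats::median(x),
               median_ra_nonseep = stats::median(y),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable groups", call. = FALSE)
  res$adjusted_p <- bonferroni(res$p)
  res$seep_active <- res$adjusted_p < alpha &
    res$median_ra_seep > res$median_ra_nonseep
  res$manual <- res$group %in% manual_include
  class(res) <- c("group_activity_summary", "data.frame")
  res
}

#' Jitter plot of per-ASV relative activity by group and region
#'
#' One panel layout in base graphics: RA (square-root scale) of every ASV x
#' pair observation, jittered within group, seep and non-seep side by side,
#' dashed reference line at RA = 1.
#'
#' @param activity an `activity_table`.
#' @param taxonomy a [taxonomy_map()].
#' @param metadata [sample_metadata] for the region lookup.
#' @param groups groups to display (default: all groups present).
#' @param ... passed to [graphics::plot()].
#' @return the plotted data, invisibly.
#' @export
plot_group_activity <- function(activity, taxonomy, metadata,
                                groups = NULL, ...) {
  act <- activity[activity$status != "phantom", , drop = FALSE]
  act$region <- metadata$region[match(act$pair_key, metadata$sample_id)]
  act$group <- group_of(act$asv_id, taxonomy)
  if (is.null(groups)) groups <- sort(unique(act$group))
  act <- act[act$group %in% groups, ]
  gi <- match(act$group, groups)
  off <- ifelse(act$region == "seep", -0.18, 0.18)
  set.seed(0)
  graphics::plot(gi + off + stats::runif(nrow(act), -0.12, 0.12),
                 sqrt(act$ra), xaxt = "n", xlab = "",
                 ylab = expression(sqrt("relative activity (RNA:DNA)")),
                 col = ifelse(act$region == "seep", "#00000080", "#d9541e80"),
                 pch = 16, cex = 0.5, ...)
  graphics::axis(1, at = seq_along(groups), labels = groups, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = 1, lty = 2)
  graphics::legend("topright", legend = c("seep", "non-seep"),
                   col = c("#000000", "#d9541e"), pch = 16, bty = "n")
  invisible(act)
}

#' Levins' niche breadth
#'
#' For taxon j over N local communities, `B_j = 1 / sum_i P_ij^2`, where
#' P_ij is taxon j's occupancy profile: its relative abundance in community
#' i normalized so the profile sums to 1 across the N communities. B ranges
#' from 1 (specialist, present in a single community) to N (uniform
#' generalist). The community-level value is the abundance-weighted mean of
#' B over the taxa present in each sample.
#'
#' @param table a [community_table].
#' @param scope sample ids defining the metacommunity (>= 2 samples);
#'   default: all samples of the table.
#' @return list of class `niche_breadth`: `taxa` (data.frame `asv_id`, `B`),
#'   `samples` (data.frame `sample_id`, `community_B`), `N`.
#' @export
levins_breadth <- function(table, scope = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(scope)) scope <- colnames(table)
  if (length(scope) < 2) stop("scope must contain >= 2 samples",
                              call. = FALSE)
  sub <- ct_samples(table, scope)
  m <- unclass(sub)
  storage.mode(m) <- "double"
  tot <- rowSums(m)
  keep <- tot > 0
  # occupancy profile from counts: tables are rarefied to equal depth
  # upstream, and count-based profiles make B exactly invariant to
  # rescaling a taxon's counts
  p <- m[keep, , drop = FALSE] / tot[keep]
  b <- 1 / rowSums(p^2)
  rel <- relative_abundance(sub)
  comm <- vapply(seq_len(ncol(rel)), function(j) {
    w <- rel[keep, j]
    if (sum(w) == 0) return(NA_real_)
    sum(w * b) / sum(w)
  }, numeric(1))
  structure(list(taxa = data.frame(asv_id = rownames(rel)[keep], B = unname(b),
                                   stringsAsFactors = FALSE),
                 samples = data.frame(sample_id = colnames(rel),
                                      community_B = comm,
                                      stringsAsFactors = FALSE),
                 N = length(scope)),
            class = "niche_breadth")
}
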