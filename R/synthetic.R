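#' Simulate a pure-birth phylogeny over synthetic ASVs
#'
#' Deterministic given the seed. Tip labels are `ASV_0001`, `ASV_0002`, ...
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @param birth speciation rate of the pure-birth process.
#' @return a rooted binary [ape::phylo] tree with positive branch lengths.
#' @export
simulate_tree <- function(n_tips, seed, birth = 1) {
  if (n_tips < 3) stop("n_tips must be >= 3", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  tree$tip.label <- sprintf("ASV_%04d", seq_len(n_tips))
  tree
}

#' Evolve environmental optima on a tree by Brownian motion
#'
#' Each tip receives an environmental optimum evolved root-to-tip under
#' Brownian motion, so that close relatives have similar optima: the
#' phylogenetic signal that downstream turnover inference requires.
#' Var(opt_a - opt_b) = brownian_rate * patristic distance(a, b).
#'
#' @param tree a [ape::phylo] tree with branch lengths.
#' @param brownian_rate Brownian variance per unit branch length (>= 0).
#' @param seed integer seed.
#' @param sigma_niche Gaussian niche tolerance stored in the model (same
#'   units as the optima).
#' @param root_value trait value at the root.
#' @return a `niche_model` list: `optima` (named per tip), `sigma_niche`,
#'   `brownian_rate`.
#' @export
evolve_optima <- function(tree, brownian_rate, seed, sigma_niche = 1,
                          root_value = 0) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) <= 0) {
    stop("tree must have positive total branch length", call. = FALSE)
  }
  if (brownian_rate < 0) stop("brownian_rate must be >= 0", call. = FALSE)
  if (sigma_niche <= 0) stop("sigma_niche must be > 0", call. = FALSE)
  set.seed(seed)
  optima <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(brownian_rate),
                            root.value = root_value)
  structure(list(optima = optima, sigma_niche = sigma_niche,
                 brownian_rate = brownian_rate),
            class = "niche_model")
}

#' Describe an assembly scenario for the metacommunity generator
#'
#' @param process one of `"selection"`, `"neutral"`, `"mixed"`.
#' @param n_samples number of local communities to draw.
#' @param env_values environmental value per sample (finite numerics,
#'   recycled to `n_samples`).
#' @param read_depth sequencing depth per sample (>= 100).
#' @param pool_meanlog,pool_sdlog lognormal parameters of the regional pool
#'   abundances; the default sdlog = 1.5 yields the realistic abundant/rare
#'   split a >0.1% group threshold presupposes.
#' @param mixture_weight weight of the selection component under
#'   `process = "mixed"` (0 = neutral, 1 = selection).
#' @param drift_sdlog sd (log scale) of the per-sample lognormal
#'   perturbation of every ASV's expected abundance, emulating ecological
#'   drift and core-to-core heterogeneity: with `drift_sdlog = 0` two
#'   samples sharing an environment have identical expectations; positive
#'   values create compositional turnover between replicate samples. Under
#'   selection this turnover replaces taxa with phylogenetically close ones
#'   (their optima must still fit the environment), which is what the
#'   nearest-taxon null model detects.
#' @return an `assembly_scenario` list.
#' @export
assembly_scenario <- function(process = c("selection", "neutral", "mixed"),
                              n_samples, env_values, read_depth = 1e4,
                              pool_meanlog = 0, pool_sdlog = 1.5,
                              mixture_weight = 0.5, drift_sdlog = 0) {
  process <- match.arg(process)
  env_values <- rep_len(as.numeric(env_values), n_samples)
  if (any(!is.finite(env_values))) stop("env_values must be finite",
                                        call. = FALSE)
  if (read_depth < 100) stop("read_depth must be >= 100", call. = FALSE)
  if (mixture_weight < 0 || mixture_weight > 1) {
    stop("mixture_weight must lie in [0, 1]", call. = FALSE)
  }
  if (drift_sdlog < 0) stop("drift_sdlog must be >= 0", call. = FALSE)
  structure(list(process = process, n_samples = n_samples,
                 env_values = env_values, read_depth = as.integer(read_depth),
                 pool_meanlog = pool_meanlog, pool_sdlog = pool_sdlog,
                 mixture_weight = mixture_weight, drift_sdlog = drift_sdlog),
            class = "assembly_scenario")
}

#' Simulate a metacommunity under environmental filtering or neutrality
#'
#' Under selection, the expected relative abundance of ASV j in sample i is
#' proportional to `pool_j * exp(-(env_i - opt_j)^2 / (2 * sigma_niche^2))`;
#' under neutrality it is proportional to `pool_j` regardless of the
#' environment; `mixed` takes the convex combination of the two normalized
#' expectations. Reads are drawn multinomially at the configured depth, so
#' every column sums exactly to `read_depth`.
#'
#' @param tree phylogeny whose tips are the regional species pool.
#' @param niche a `niche_model` from [evolve_optima()] (may be NULL for a
#'   purely neutral scenario).
#' @param scenario an [assembly_scenario()].
#' @param seed integer seed.
#' @param habitat habitat label stored in the metadata (default "ROV1").
#' @param sample_prefix prefix of generated sample identifiers.
#' @param depth_cmbs sediment depth recorded for each sample.
#' @param pool optional regional pool abundances (named per tip); drawn
#'   lognormal from the scenario parameters when NULL.
#' @return list with elements `table` ([community_table]), `metadata`
#'   ([sample_metadata] with an `env` column) and `pool`.
#' @export
simulate_metacommunity <- function(tree, niche, scenario, seed,
                                   habitat = "ROV1", sample_prefix = habitat,
                                   depth_cmbs = 5, pool = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  tips <- tree$tip.label
  if (scenario$process != "neutral") {
    if (is.null(niche)) stop("selection scenarios need a niche model",
                             call. = FALSE)
    if (!all(tips %in% names(niche$optima))) {
      stop("niche model lacks optima for some tips", call. = FALSE)
    }
  }
  set.seed(seed)
  if (is.null(pool)) {
    pool <- stats::rlnorm(length(tips), scenario$pool_meanlog,
                          scenario$pool_sdlog)
    names(pool) <- tips
  }
  pool <- pool[tips]
  n <- scenario$n_samples
  counts <- matrix(0L, nrow = length(tips), ncol = n,
                   dimnames = list(tips, sprintf("%s_s%02d", sample_prefix,
                                                 seq_len(n))))
  for (i in seq_len(n)) {
    pool_i <- pool
    if (scenario$drift_sdlog > 0) {
      pool_i <- pool * stats::rlnorm(length(pool), 0, scenario$drift_sdlog)
    }
    neutral_i <- pool_i / sum(pool_i)
    p <- switch(scenario$process,
      neutral = neutral_i,
      selection = {
        w <- pool_i * exp(-(scenario$env_values[i] - niche$optima[tips])^2 /
                            (2 * niche$sigma_niche^2))
        if (sum(w) <= 0 || !any(w > 1e-300)) {
          stop("all expected abundances are 0 in sample ", i,
               "; widen sigma_niche or move env inside the optima range",
               call. = FALSE)
        }
        w / sum(w)
      },
      mixed = {
        w <- pool_i * exp(-(scenario$env_values[i] - niche$optima[tips])^2 /
                            (2 * niche$sigma_niche^2))
        if (sum(w) <= 0) {
          stop("all expected abundances are 0 in sample ", i, call. = FALSE)
        }
        scenario$mixture_weight * w / sum(w) +
          (1 - scenario$mixture_weight) * neutral_i
      })
    counts[, i] <- stats::rmultinom(1, scenario$read_depth, p)[, 1]
  }
  md <- sample_metadata(data.frame(
    sample_id = colnames(counts), habitat = habitat,
    depth_cmbs = rep_len(depth_cmbs, n), env = scenario$env_values,
    process = scenario$process, stringsAsFactors = FALSE))
  list(table = community_table(counts), metadata = md, pool = pool)
}

#' Describe the planted activity structure of a synthetic RNA library
#'
#' @param inactive_fraction fraction of DNA ASVs whose RNA expectation is 0.
#' @param phantom_fraction fraction (of the DNA ASV count) of extra ASVs
#'   present only in the RNA library.
#' @param multiplier_meanlog,multiplier_sdlog lognormal parameters of the
#'   per-ASV activity multipliers of active ASVs.
#' @param phantom_lambda Poisson mean of the RNA reads injected per phantom
#'   ASV per sample (small, mimicking rare RNA-only detections).
#' @return an `activity_model` list.
#' @export
activity_model <- function(inactive_fraction = 0, phantom_fraction = 0,
                           multiplier_meanlog = 0, multiplier_sdlog = 1,
                           phantom_lambda = 5) {
  if (inactive_fraction < 0 || phantom_fraction < 0 ||
      inactive_fraction > 1 || phantom_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (inactive_fraction + phantom_fraction > 1) {
    stop("inactive_fraction + phantom_fraction must not exceed 1",
         call. = FALSE)
  }
  structure(list(inactive_fraction = inactive_fraction,
                 phantom_fraction = phantom_fraction,
                 multiplier_meanlog = multiplier_meanlog,
                 multiplier_sdlog = multiplier_sdlog,
                 phantom_lambda = phantom_lambda),
            class = "activity_model")
}

#' Simulate a paired RNA library with planted activity structure
#'
#' Active ASVs get an RNA expectation proportional to their DNA relative
#' abundance times a per-ASV activity multiplier; inactive ASVs get RNA
#' expectation exactly 0; phantom ASVs are injected into the RNA table only,
#' with Poisson read counts. The planted status of every ASV is returned as
#' ground truth so recovery can be scored.
#'
#' @param dna a [community_table].
#' @param activity an [activity_model()].
#' @param seed integer seed.
#' @param rna_depth RNA reads per sample before phantom injection; defaults
#'   to the DNA column sums.
#' @param phantom_ids identifiers of the phantom ASVs. Defaults to new
#'   `PHANTOM_###` ids; pass all-zero rows of `dna` (e.g. held-out tree
#'   tips) to keep the phylogeny covering the RNA table.
#' @param multipliers optional named per-ASV activity multipliers overriding
#'   the lognormal draw.
#' @param boost optional list(`asv_ids`, `samples`, `factor`): multiply the
#'   RNA expectation of the given ASVs by `factor` in the given samples
#'   (used to plant a seep-active group).
#' @return a [paired_community()] whose `truth` element is a data.frame with
#'   `asv_id`, `status` (active/inactive/phantom) and `multiplier`.
#' @export
simulate_paired_rna <- function(dna, activity, seed, rna_depth = NULL,
                                phantom_ids = NULL, multipliers = NULL,
                                boost = NULL) {
  stopifnot(inherits(dna, "community_table"),
            inherits(activity, "activity_model"))
  set.seed(seed)
  asvs <- rownames(dna)
  present <- asvs[rowSums(dna) > 0]
  n_phantom <- round(activity$phantom_fraction * length(present))
  if (is.null(phantom_ids)) {
    if (n_phantom > 0) phantom_ids <- sprintf("PHANTOM_%03d",
                                              seq_len(n_phantom))
  } else {
    n_phantom <- length(phantom_ids)
    in_dna <- intersect(phantom_ids, asvs)
    if (any(rowSums(dna[in_dna, , drop = FALSE]) > 0)) {
      stop("phantom_ids must be absent from the DNA counts", call. = FALSE)
    }
  }
  n_inactive <- round(activity$inactive_fraction * length(present))
  inactive <- sample(present, n_inactive)
  active <- setdiff(present, inactive)
  if (is.null(multipliers)) {
    multipliers <- stats::setNames(
      stats::rlnorm(length(active), activity$multiplier_meanlog,
                    activity$multiplier_sdlog), active)
  } else {
    if (!all(active %in% names(multipliers))) {
      stop("multipliers must cover all active ASVs", call. = FALSE)
    }
    multipliers <- multipliers[active]
  }
  mult <- stats::setNames(numeric(length(asvs)), asvs)
  mult[active] <- multipliers
  if (is.null(rna_depth)) rna_depth <- colSums(dna)
  rna_depth <- rep_len(as.integer(rna_depth), ncol(dna))

  rel <- relative_abundance(dna)
  expectation <- rel * mult  # recycles mult down columns (ASV-wise)
  if (!is.null(boost)) {
    ib <- intersect(boost$asv_ids, asvs)
    jb <- intersect(boost$samples, colnames(dna))
    expectation[ib, jb] <- expectation[ib, jb] * boost$factor
  }
  rna <- matrix(0L, nrow = length(asvs), ncol = ncol(dna),
                dimnames = dimnames(dna))
  for (j in seq_len(ncol(dna))) {
    q <- expectation[, j]
    if (sum(q) <= 0) stop("sample ", colnames(dna)[j],
                          " has no active ASVs; lower inactive_fraction",
                          call. = FALSE)
    rna[, j] <- stats::rmultinom(1, rna_depth[j], q / sum(q))[, 1]
  }
  if (n_phantom > 0) {
    new_ids <- setdiff(phantom_ids, rownames(rna))
    if (length(new_ids)) {
      rna <- rbind(rna, matrix(0L, length(new_ids), ncol(rna),
                               dimnames = list(new_ids, colnames(rna))))
    }
    rna[phantom_ids, ] <- matrix(
      stats::rpois(n_phantom * ncol(rna), activity$phantom_lambda),
      nrow = n_phantom)
  } else {
    phantom_ids <- character(0)
  }
  truth <- data.frame(
    asv_id = c(asvs, setdiff(phantom_ids, asvs)),
    stringsAsFactors = FALSE)
  truth$status <- ifelse(truth$asv_id %in% phantom_ids, "phantom",
                         ifelse(truth$asv_id %in% inactive, "inactive",
                                ifelse(truth$asv_id %in% active, "active",
                                       "absent")))
  truth$multiplier <- mult[truth$asv_id]
  truth$multiplier[is.na(truth$multiplier)] <- 0

  pairs <- data.frame(key = colnames(dna), dna_sample = colnames(dna),
                      rna_sample = colnames(dna), stringsAsFactors = FALSE)
  paired_community(dna, community_table(rna), pairs, truth = truth)
}

#' Generate a complete synthetic cold-seep study
#'
#' Convenience wrapper producing everything the pipeline consumes: a tree, a
#' niche model, DNA tables for five ROV habitats (ROV1-3 assembled under
#' selection or a selection/neutral mixture, ROV4-5 neutrally), paired RNA
#' tables with planted activity structure, a clade-based taxonomy and the
#' per-ASV ground truth.
#'
#' @param n_tips tips in the regional pool phylogeny.
#' @param n_per_habitat samples per ROV habitat.
#' @param seed integer seed driving every random draw.
#' @param read_depth reads per sample.
#' @param sigma_niche Gaussian niche tolerance of the selection habitats.
#' @param brownian_rate Brownian rate of the evolved optima.
#' @param drift_sdlog per-sample lognormal drift (see
#'   [assembly_scenario()]); the default 1 produces core-to-core
#'   compositional turnover between replicate sediment samples while
#'   keeping many taxa contributing to the nearest-taxon statistic.
#' @param seep_process assembly process of ROV1-3 ("selection" or "mixed").
#' @param activity an [activity_model()] for the paired RNA libraries.
#' @param n_groups number of clade-based taxonomy groups.
#' @param active_boost multiplier applied to the RNA expectation of one
#'   target group in seep samples (NULL for no planted seep-active group).
#' @return list: `tree`, `niche`, `paired` ([paired_community] with truth),
#'   `metadata`, `taxonomy`, `boost_group` (name of the boosted group or NA).
#' @export
simulate_study <- function(n_tips = 1500, n_per_habitat = 5, seed = 1,
                           read_depth = 1000, sigma_niche = 0.3,
                           brownian_rate = 1, drift_sdlog = 1,
                           seep_process = "selection",
                           activity = activity_model(0.3, 0.05),
                           n_groups = 8, active_boost = NULL) {
  tree <- simulate_tree(n_tips, seed = seed)
  niche <- evolve_optima(tree, brownian_rate, seed = seed + 1,
                         sigma_niche = sigma_niche)
  # Each seep habitat sits at one point of the environmental gradient
  # (samples within an ROV share their environment, as cores from one site
  # do): environmental filtering is then homogeneous within a habitat.
  env_seep <- stats::quantile(niche$optima, c(0.25, 0.5, 0.75), names = FALSE)
  habitats <- paste0("ROV", 1:5)
  set.seed(seed + 2)
  pool <- stats::setNames(stats::rlnorm(n_tips, 0, 1.5), tree$tip.label)
  parts <- vector("list", 5)
  for (h in seq_along(habitats)) {
    is_seep <- h <= 3
    env <- rep(if (is_seep) env_seep[h] else mean(range(niche$optima)),
               n_per_habitat)
    sc <- assembly_scenario(if (is_seep) seep_process else "neutral",
                            n_samples = n_per_habitat, env_values = env,
                            read_depth = read_depth,
                            drift_sdlog = drift_sdlog)
    parts[[h]] <- simulate_metacommunity(tree, niche, sc,
                                         seed = seed + 10 + h,
                                         habitat = habitats[h], pool = pool)
  }
  counts <- do.call(cbind, lapply(parts, function(p) unclass(p$table)))
  metadata <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$metadata)))
  metadata <- sample_metadata(metadata)
  dna <- community_table(counts)

  taxonomy <- clade_taxonomy(tree, n_groups)
  boost_group <- NA_character_
  boost <- NULL
  if (!is.null(active_boost)) {
    grp_sizes <- sort(table(taxonomy$group), decreasing = TRUE)
    boost_group <- names(grp_sizes)[1]
    seep_samples <- metadata$sample_id[metadata$region == "seep"]
    boost <- list(asv_ids = taxonomy$asv_id[taxonomy$group == boost_group],
                  samples = seep_samples, factor = active_boost)
  }
  paired <- simulate_paired_rna(dna, activity, seed = seed + 20, boost = boost)
  list(tree = tree, niche = niche, paired = paired, metadata = metadata,
       taxonomy = taxonomy, boost_group = boost_group)
}

#' Assign tree tips to taxonomy groups by clade
#'
#' Cuts the cophenetic-distance dendrogram into `n_groups` clusters and
#' writes synthetic QIIME-style lineages, so group membership is
#' phylogenetically coherent.
#'
#' @param tree a [ape::phylo] tree.
#' @param n_groups number of groups.
#' @return a [taxonomy_map()] data.frame covering every tip.
#' @export
clade_taxonomy <- function(tree, n_groups) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = n_groups)
  lineage <- sprintf("d__Synthetic;p__Phylum_%02d;c__Class_%02d", cl, cl)
  taxonomy_map(tree$tip.label, lineage, group_rank = "class")
}
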