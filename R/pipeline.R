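#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (TSV/newick, read by the core readers) or
#' in-memory objects of the matching classes.
#'
#' @param dna,rna count tables (paths or [community_table]).
#' @param tree phylogeny (path or [ape::phylo]).
#' @param taxonomy taxonomy (path or [taxonomy_map()] data.frame).
#' @param metadata sample metadata (path or [sample_metadata]).
#' @param seed integer seed (mandatory) driving every randomized stage.
#' @param rarefaction_depth common depth for DNA and RNA; NULL = 90% of the
#'   smallest paired sample total.
#' @param n_randomizations betaNTI null draws.
#' @param n_permutations permutations for ANOSIM / Mantel / accumulation.
#' @param alpha significance level.
#' @param max_depth_cmbs maximum sediment depth of retained pairs.
#' @param abundance_threshold abundant-group threshold (fraction).
#' @param group_rank taxonomy rank used for groups.
#' @param env_var metadata column used as the environmental axis for the
#'   phylogenetic-signal check.
#' @param depth_bin_cmbs bin width of the sediment-depth ANOSIM factor.
#' @param strict_signal abort the betaNTI stage (instead of warning) when
#'   the phylogenetic-signal prerequisite fails.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dna, rna, tree, taxonomy, metadata, seed,
                            rarefaction_depth = NULL,
                            n_randomizations = 999, n_permutations = 999,
                            alpha = 0.05, max_depth_cmbs = 10,
                            abundance_threshold = 0.001,
                            group_rank = "class", env_var = "env",
                            depth_bin_cmbs = 5, strict_signal = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  for (nm in c("n_randomizations", "n_permutations", "alpha",
               "max_depth_cmbs", "abundance_threshold", "depth_bin_cmbs")) {
    if (get(nm) <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  structure(list(dna = dna, rna = rna, tree = tree, taxonomy = taxonomy,
                 metadata = metadata, seed = as.integer(seed),
                 rarefaction_depth = rarefaction_depth,
                 n_randomizations = n_randomizations,
                 n_permutations = n_permutations, alpha = alpha,
                 max_depth_cmbs = max_depth_cmbs,
                 abundance_threshold = abundance_threshold,
                 group_rank = group_rank, env_var = env_var,
                 depth_bin_cmbs = depth_bin_cmbs,
                 strict_signal = strict_signal),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; input
#'   fields must be file paths (relative to the YAML's directory).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  for (nm in c("dna", "rna", "tree", "taxonomy", "metadata")) {
    if (is.null(y[[nm]])) stop("config lacks input: ", nm, call. = FALSE)
    if (!file.exists(y[[nm]])) y[[nm]] <- file.path(base, y[[nm]])
  }
  do.call(pipeline_config, y)
}

resolve_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1) return(reader(x))
  x
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full inference pipeline
#'
#' Stages, in order: load inputs; pair DNA/RNA samples (depth-filtered);
#' rarefy both libraries to a common depth; alpha diversity; Bray-Curtis
#' beta diversity; gamma diversity with accumulation curves; ANOSIM on
#' habitat, region and binned sediment depth; phylogenetic-signal check;
#' betaNTI within habitats with process classification; Levins' niche
#' breadth per habitat; relative activity; abundant groups; seep-active
#' groups; region-wise Wilcoxon contrasts of the alpha indices. One TSV is
#' written per stage plus a run manifest (seed, version, config hash);
#' outputs carry `#` parameter headers and no timestamps, so identical
#' config and seed reproduce byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @return (invisibly) a named list with every stage result.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  emit <- function(x, name, params = list()) {
    if (!is.null(out_dir)) {
      write_community_table(x, file.path(out_dir, paste0(name, ".tsv")),
                            params = c(list(seed = seed), params))
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()

  inputs <- stage_guard("load", {
    list(dna = resolve_input(config$dna, read_community_table),
         rna = resolve_input(config$rna, read_community_table),
         tree = resolve_input(config$tree, read_newick),
         taxonomy = resolve_input(config$taxonomy, function(p)
           read_taxonomy(p, group_rank = config$group_rank)),
         metadata = resolve_input(config$metadata, read_metadata))
  })
  md <- inputs$metadata

  paired <- stage_guard("pair", {
    pair_samples(inputs$dna, inputs$rna, metadata = md,
                 max_depth_cmbs = config$max_depth_cmbs)
  })
  res$paired <- paired
  md_paired <- md[match(paired$pairs$key, md$sample_id), ]

  depth <- config$rarefaction_depth
  if (is.null(depth)) {
    depth <- floor(0.9 * min(colSums(paired$dna), colSums(paired$rna)))
  }
  dna_r <- stage_guard("rarefy", rarefy(paired$dna, depth, seed = seed))
  res$rarefied_dna <- dna_r
  res$rarefaction_depth <- depth
  emit(dna_r, "rarefied_dna", list(depth = depth))
  md_r <- md_paired[match(colnames(dna_r), paired$pairs$dna_sample), ]
  md_r$sample_id <- colnames(dna_r)

  res$alpha <- stage_guard("alpha", alpha_diversity(dna_r, inputs$tree))
  emit(res$alpha, "alpha_diversity", list(depth = depth))

  res$beta <- stage_guard("beta", bray_curtis(dna_r))
  emit(as.matrix(res$beta), "bray_curtis", list(depth = depth))

  res$gamma <- stage_guard("gamma", gamma_diversity(dna_r, md_r))
  emit(res$gamma, "gamma_diversity")
  res$accumulation <- stage_guard("gamma", {
    accumulation_curve(dna_r, md_r,
                       n_permutations = max(100, config$n_permutations),
                       seed = seed + 1)
  })
  emit(as.data.frame(res$accumulation), "accumulation_curves")

  res$anosim <- stage_guard("anosim", {
    depth_bin <- cut(md_r$depth_cmbs,
                     breaks = seq(0, 70, by = config$depth_bin_cmbs),
                     include.lowest = TRUE)
    factors <- list(habitat = md_r$habitat, region = md_r$region,
                    depth = as.character(depth_bin))
    rows <- lapply(names(factors), function(f) {
      a <- tryCatch(anosim_test(res$beta, factors[[f]],
                                n_permutations = config$n_permutations,
                                seed = seed + 2),
                    error = function(e) list(R = NA_real_, p = NA_real_))
      data.frame(factor = f, R = a$R, p = a$p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  emit(res$anosim, "anosim", list(n_permutations = config$n_permutations))

  pat <- patristic_distances(inputs$tree)
  res$signal <- stage_guard("phylo_signal", {
    if (config$env_var %in% names(md_r)) {
      env <- stats::setNames(as.numeric(md_r[[config$env_var]]),
                             md_r$sample_id)
      nv <- niche_values(dna_r, env)
      phylo_signal(nv, pat, n_permutations = config$n_permutations,
                   seed = seed + 3)
    } else {
      warning("metadata lacks env_var '", config$env_var,
              "'; phylogenetic-signal check skipped", call. = FALSE)
      NULL
    }
  })
  if (!is.null(res$signal) && !is.null(res$signal$classes)) {
    emit(res$signal$classes, "phylo_signal",
         list(signal_present = res$signal$signal_present))
  }

  signal_ok <- is.null(res$signal) || res$signal$signal_present
  if (!signal_ok && config$strict_signal) {
    message("betaNTI stage skipped: phylogenetic-signal prerequisite failed")
    res$assembly <- NULL
  } else {
    if (!signal_ok) {
      warning("phylogenetic-signal prerequisite failed; betaNTI computed ",
              "anyway (advisory mode)", call. = FALSE)
    }
    res$assembly <- stage_guard("bnti", {
      pairs <- within_habitat_pairs(md_r)
      out <- bnti(dna_r, pat, n_randomizations = config$n_randomizations,
                  seed = seed + 4, pairs = pairs[c("sample_k", "sample_m")])
      out$habitat <- pairs$habitat
      out
    })
    res$process_summary <- process_fractions(res$assembly)
    emit(res$assembly, "assembly_bnti",
         list(n_randomizations = config$n_randomizations,
              null_model = "tip-shuffle across metacommunity pool"))
    emit(res$process_summary, "process_fractions")
  }

  res$niche_breadth <- stage_guard("niche_breadth", {
    out <- lapply(split(md_r$sample_id, md_r$habitat), function(s) {
      if (length(s) < 2) return(NULL)
      nb <- levins_breadth(dna_r, scope = s)
      cbind(habitat = md_r$habitat[match(s[1], md_r$sample_id)], nb$samples)
    })
    do.call(rbind, out)
  })
  emit(res$niche_breadth, "niche_breadth")

  res$activity <- stage_guard("relative_activity", {
    relative_activity(paired, rarefaction_depth = depth, seed = seed + 5)
  })
  emit(as.data.frame(res$activity), "activity", list(depth = depth))

  res$abundant <- stage_guard("abundant_groups", {
    abundant_groups(dna_r, inputs$taxonomy,
                    threshold = config$abundance_threshold)
  })
  emit(attr(res$abundant, "summary"), "abundant_groups",
       list(threshold = config$abundance_threshold))

  res$seep_active <- stage_guard("seep_active_groups", {
    seep_active_groups(res$activity, inputs$taxonomy, md,
                       abundant = res$abundant, alpha = config$alpha)
  })
  emit(res$seep_active, "seep_active_groups", list(alpha = config$alpha))

  res$region_contrasts <- stage_guard("region_contrasts", {
    rows <- lapply(c("richness", "chao1", "faith_pd", "pielou"), function(v) {
      x <- res$alpha[[v]][md_r$region == "seep"]
      y <- res$alpha[[v]][md_r$region == "non-seep"]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NULL)
      wt <- wilcoxon_rank_sum(x, y)
      data.frame(index = v, W = wt$statistic, p = wt$p,
                 median_seep = stats::median(x),
                 median_nonseep = stats::median(y), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  emit(res$region_contrasts, "region_contrasts")

  res$manifest <- data.frame(
    key = c("package", "version", "seed", "rarefaction_depth",
            "n_randomizations", "n_permutations", "config_hash"),
    value = c("seepecol", pkg_version(), seed, depth,
              config$n_randomizations, config$n_permutations,
              config_hash(config)),
    stringsAsFactors = FALSE)
  emit(res$manifest, "manifest")
  invisible(res)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}
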