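#' Read an ASV count table from TSV
#'
#' Expects the orientation ASVs-as-rows, samples-as-columns: the first column
#' holds ASV identifiers and the header row holds sample identifiers. Lines
#' beginning with `#` are treated as comments, except a QIIME-style header
#' line whose first cell is the sentinel `#ASV_ID` (or `#OTU ID`), which is
#' used as the header. Files in any other orientation are rejected rather
#' than silently transposed.
#'
#' @param path path to a tab-separated file.
#' @return a [community_table].
#' @seealso [write_community_table()]
#' @export
read_community_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_sentinel <- grepl("^#(ASV_ID|OTU ID|OTU_ID)\t", lines)
  lines[is_sentinel] <- sub("^#", "", lines[is_sentinel])
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  asv_ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric cells in count table ", path, call. = FALSE)
  rownames(m) <- asv_ids
  community_table(m)
}

pkg_version <- function() {
  as.character(utils::packageVersion("seepecol"))
}

#' Write a count table (or any data frame) as TSV with a parameter header
#'
#' Output files carry `#`-prefixed header lines recording the package
#' version and any parameters (including seeds) used to produce them, so a
#' result table is self-describing.
#'
#' @param x a `community_table`, matrix or data.frame.
#' @param path output path.
#' @param params named list echoed into the header.
#' @param id_column name of the first column when writing a matrix.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path, params = list(),
                                  id_column = "ASV_ID") {
  header <- c(sprintf("# seepecol %s", pkg_version()),
              vapply(names(params), function(nm) {
                sprintf("# %s = %s", nm,
                        paste(format(params[[nm]]), collapse = ","))
              }, character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (is.matrix(x) || inherits(x, "community_table")) {
    df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_column
  } else {
    df <- as.data.frame(x)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Tip labels must be unique (they are ASV identifiers). Missing branch
#' lengths are set to 0 with a warning; a tree in which more than 1% of
#' branches have zero length triggers an additional warning because
#' nearest-taxon distances degenerate on such trees.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("unparseable newick in ", path, call. = FALSE)
  validate_phylogeny(tree)
}

#' Write a phylogeny to newick at full precision
#'
#' Branch lengths are written with enough digits that patristic distances
#' survive a write/read round-trip to well below 1e-9.
#'
#' @param tree a [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  if (mean(tree$edge.length == 0) > 0.01) {
    warning("more than 1% of branches have zero length; ",
            "nearest-taxon distances may degenerate", call. = FALSE)
  }
  tree
}

#' Read a taxonomy map (QIIME2-style TSV)
#'
#' Two tab-separated columns: ASV identifier and a semicolon-delimited
#' lineage. The designated "group" rank (class for prokaryotes, phylum for
#' microeukaryotes) is extracted by position in the lineage.
#'
#' @param path TSV file; `#` comment lines allowed.
#' @param group_rank 1-based position of the group rank within the lineage
#'   (domain = 1, phylum = 2, class = 3, ...), or the rank name.
#' @return data.frame with columns `asv_id`, `lineage`, `group`.
#' @export
read_taxonomy <- function(path, group_rank = "class") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("asv_id", "lineage"),
                          colClasses = "character", quote = "")
  taxonomy_map(df$asv_id, df$lineage, group_rank = group_rank)
}

rank_index <- function(group_rank) {
  if (is.numeric(group_rank)) return(as.integer(group_rank))
  ranks <- c(domain = 1L, kingdom = 1L, phylum = 2L, class = 3L,
             order = 4L, family = 5L, genus = 6L)
  i <- ranks[tolower(group_rank)]
  if (is.na(i)) stop("unknown rank: ", group_rank, call. = FALSE)
  unname(i)
}

#' Build a taxonomy map from ASV identifiers and lineage strings
#'
#' @param asv_id character vector of ASV identifiers.
#' @param lineage semicolon-delimited lineages (domain;phylum;class;...).
#' @param group_rank rank (name or index) used as the grouping level.
#' @return data.frame with columns `asv_id`, `lineage`, `group`; ranks
#'   missing from a lineage yield group `"unclassified"`.
#' @export
taxonomy_map <- function(asv_id, lineage, group_rank = "class") {
  stopifnot(length(asv_id) == length(lineage))
  if (anyDuplicated(asv_id)) stop("duplicate ASV ids in taxonomy",
                                  call. = FALSE)
  i <- rank_index(group_rank)
  parts <- strsplit(lineage, ";", fixed = TRUE)
  group <- vapply(parts, function(p) {
    g <- if (length(p) >= i) trimws(p[i]) else ""
    g <- sub("^[a-z]__", "", g)
    if (!nzchar(g)) "unclassified" else g
  }, character(1))
  data.frame(asv_id = asv_id, lineage = lineage, group = group,
             stringsAsFactors = FALSE)
}

#' Read sample metadata
#'
#' Mandatory columns: `sample_id`, `habitat` (ROV1..ROV5), `depth_cmbs`.
#' Any further numeric columns are treated as environmental variables.
#' The `region` column is always (re)derived from the habitat: ROV1-3 are
#' seep, ROV4-5 non-seep.
#'
#' @param path TSV file.
#' @return data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Validate a sample-metadata data frame
#'
#' @param df data.frame with at least `sample_id`, `habitat`, `depth_cmbs`.
#' @return the validated data.frame with a derived `region` column
#'   (seep for ROV1-3, non-seep for ROV4-5).
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "habitat", "depth_cmbs")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata",
                                        call. = FALSE)
  df$habitat <- as.character(df$habitat)
  bad <- !df$habitat %in% paste0("ROV", 1:5)
  if (any(bad)) {
    stop("unknown habitat(s): ", paste(unique(df$habitat[bad]), collapse = ", "),
         call. = FALSE)
  }
  df$depth_cmbs <- as.numeric(df$depth_cmbs)
  if (any(is.na(df$depth_cmbs) | df$depth_cmbs < 0 | df$depth_cmbs > 70)) {
    stop("depth_cmbs must lie in [0, 70]", call. = FALSE)
  }
  df$region <- habitat_region(df$habitat)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Map ROV habitat labels to the seep / non-seep region contrast
#'
#' @param habitat character vector of ROV1..ROV5 labels.
#' @return character vector, "seep" (ROV1-3) or "non-seep" (ROV4-5).
#' @export
habitat_region <- function(habitat) {
  ifelse(habitat %in% c("ROV1", "ROV2", "ROV3"), "seep", "non-seep")
}

#' Pair DNA and RNA samples sharing a physical sample identity
#'
#' Sample identifiers are matched after stripping a library-type suffix
#' (default `_DNA` / `_RNA` / `_cDNA`). Pairs deeper than `max_depth_cmbs`
#' (looked up in the metadata by the stripped key, or by the DNA sample id)
#' are excluded, restricting the activity analysis to the surface layers
#' where RNA sampling is reliable.
#'
#' @param dna,rna `community_table` objects.
#' @param metadata optional `sample_metadata`; required for the depth filter.
#' @param max_depth_cmbs maximum sediment depth of retained pairs (default 10).
#' @param suffix_pattern regular expression stripped from sample ids to form
#'   the pairing key.
#' @return an object of class `paired_community`: a list with elements
#'   `dna`, `rna` (tables restricted to the paired samples, same pair order),
#'   `pairs` (data.frame: `key`, `dna_sample`, `rna_sample`) and `unpaired`
#'   (report of dropped samples).
#' @export
pair_samples <- function(dna, rna, metadata = NULL, max_depth_cmbs = 10,
                         suffix_pattern = "(_DNA|_RNA|_cDNA)$") {
  stopifnot(inherits(dna, "community_table"), inherits(rna, "community_table"))
  key_d <- sub(suffix_pattern, "", colnames(dna))
  key_r <- sub(suffix_pattern, "", colnames(rna))
  if (anyDuplicated(key_d) || anyDuplicated(key_r)) {
    stop("pairing keys are not unique within a library; ",
         "adjust 'suffix_pattern'", call. = FALSE)
  }
  keys <- sort(intersect(key_d, key_r))
  pairs <- data.frame(
    key = keys,
    dna_sample = colnames(dna)[match(keys, key_d)],
    rna_sample = colnames(rna)[match(keys, key_r)],
    stringsAsFactors = FALSE)
  dropped_depth <- character(0)
  if (!is.null(metadata) && nrow(pairs)) {
    idx <- match(pairs$key, metadata$sample_id)
    idx[is.na(idx)] <- match(pairs$dna_sample, metadata$sample_id)[is.na(idx)]
    if (anyNA(idx)) {
      stop("no metadata for pair key(s): ",
           paste(pairs$key[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    depth <- metadata$depth_cmbs[idx]
    keep <- depth <= max_depth_cmbs
    dropped_depth <- pairs$key[!keep]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    stop("no DNA/RNA sample pairs after matching and depth filtering",
         call. = FALSE)
  }
  unpaired <- list(
    dna = setdiff(colnames(dna), pairs$dna_sample),
    rna = setdiff(colnames(rna), pairs$rna_sample),
    excluded_by_depth = dropped_depth)
  paired_community(ct_samples(dna, pairs$dna_sample),
                   ct_samples(rna, pairs$rna_sample),
                   pairs, unpaired = unpaired)
}

#' Assemble a paired DNA/RNA community object
#'
#' @param dna,rna `community_table` objects whose columns follow `pairs`.
#' @param pairs data.frame with columns `key`, `dna_sample`, `rna_sample`.
#' @param unpaired optional report of samples dropped during pairing.
#' @param truth optional per-ASV ground-truth table (synthetic data only).
#' @return a `paired_community` list.
#' @export
paired_community <- function(dna, rna, pairs, unpaired = NULL, truth = NULL) {
  stopifnot(inherits(dna, "community_table"), inherits(rna, "community_table"))
  if (!all(pairs$dna_sample %in% colnames(dna)) ||
      !all(pairs$rna_sample %in% colnames(rna))) {
    stop("pairs reference unknown samples", call. = FALSE)
  }
  if (anyDuplicated(pairs$dna_sample) || anyDuplicated(pairs$rna_sample)) {
    stop("a sample participates in more than one pair", call. = FALSE)
  }
  structure(list(dna = dna, rna = rna, pairs = pairs,
                 unpaired = unpaired, truth = truth),
            class = "paired_community")
}

#' @export
print.paired_community <- function(x, ...) {
  cat(sprintf("paired_community: %d pairs; DNA %d ASVs, RNA %d ASVs\n",
              nrow(x$pairs), nrow(x$dna), nrow(x$rna)))
  invisible(x)
}
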