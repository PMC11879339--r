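#' Construct a validated ASV-by-sample count table
#'
#' The basic data container of the package: a non-negative integer matrix
#' with ASVs as rows and samples as columns. All downstream functions
#' (diversity, assembly null models, relative activity) accept this class.
#'
#' @param counts numeric matrix, rows = ASVs, columns = samples. Values must
#'   be non-negative integers (within `tol` of an integer).
#' @param asv_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @param tol numeric tolerance used when checking integrality.
#'
#' @return An object of class `community_table`: the integer count matrix
#'   with validated, unique dimnames.
#'
#' @details Samples with a total count of zero are rejected: an all-zero
#'   column carries no community information and silently breaks relative
#'   abundances downstream. All-zero ASV rows are allowed (e.g. taxa present
#'   in the regional pool but undetected in the loaded samples).
#'
#' @examples
#' m <- matrix(c(5, 0, 2, 1, 0, 4), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("ASV_", 1:3), c("s1", "s2")))
#' ct <- community_table(m)
#' colSums(ct)
#' @export
community_table <- function(counts, asv_ids = rownames(counts),
                            sample_ids = colnames(counts), tol = 1e-8) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(asv_ids) || is.null(sample_ids)) {
    stop("community_table requires ASV and sample identifiers (dimnames)",
         call. = FALSE)
  }
  asv_ids <- as.character(asv_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(asv_ids)) {
    stop("duplicate ASV identifiers: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) stop("counts contain negative values", call. = FALSE)
  if (any(abs(counts - round(counts)) > tol)) {
    stop("counts contain non-integer values", call. = FALSE)
  }
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(asv_ids, sample_ids)
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(sample_ids[zero], collapse = ", "),
         call. = FALSE)
  }
  structure(counts, class = c("community_table", "matrix", "array"))
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d ASVs x %d samples (total reads %s)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Subset the samples of a community table
#'
#' @param x a `community_table`.
#' @param samples character vector of sample identifiers to keep, in order.
#' @param drop_empty_asvs drop ASV rows that are all-zero after subsetting.
#' @return a `community_table` restricted to `samples`.
#' @export
ct_samples <- function(x, samples, drop_empty_asvs = FALSE) {
  stopifnot(inherits(x, "community_table"))
  missing <- setdiff(samples, colnames(x))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- unclass(x)[, samples, drop = FALSE]
  if (drop_empty_asvs) m <- m[rowSums(m) > 0, , drop = FALSE]
  community_table(m)
}

#' Convert counts to within-sample relative abundances
#'
#' @param x a `community_table` (or count matrix, ASVs x samples).
#' @return numeric matrix of the same shape; each column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- unclass(x)
  storage.mode(m) <- "double"
  sweep(m, 2, colSums(m), "/")
}
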