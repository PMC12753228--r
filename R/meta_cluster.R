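## Cross-dataset feature matrix of terminus-specific truncation sites,
## missingness filtering, Ward clustering, and cluster motif summaries.

site_keys <- function(terminus) {
  as.vector(outer(AA_STANDARD, AA_STANDARD,
                  function(a, b) paste0(terminus, ":", a, "|", b)))
}

parse_site_keys <- function(keys) {
  m <- regmatches(keys, regexec("^([NC]):([A-Z])\\|([A-Z])$", keys))
  data.frame(terminus = vapply(m, `[`, "", 2L),
             x = vapply(m, `[`, "", 3L),
             x_prime = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Assemble the cross-dataset truncation-site feature matrix
#'
#' Stacks the N- and C-terminus normalized frequency matrices of every
#' dataset into one matrix with one row per (terminus, X, X') site key that is
#' non-missing in at least one dataset, and one column per dataset.
#'
#' @param per_dataset named list (one element per dataset) of lists with
#'   elements `N` and `C`, each a [normalized_frequency()] matrix.
#' @return numeric matrix (rows = site keys like `"N:D|P"`, columns =
#'   dataset ids) with `NA` for missing cells.
#' @export
assemble_feature_matrix <- function(per_dataset) {
  if (length(per_dataset) < 2L) {
    stop("assemble_feature_matrix requires at least 2 datasets")
  }
  ids <- names(per_dataset)
  keys <- c(site_keys("N"), site_keys("C"))
  m <- matrix(NA_real_, nrow = length(keys), ncol = length(ids),
              dimnames = list(keys, ids))
  for (d in ids) {
    m[site_keys("N"), d] <- as.vector(per_dataset[[d]]$N)
    m[site_keys("C"), d] <- as.vector(per_dataset[[d]]$C)
  }
  m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
}

#' Filter a feature matrix by missingness
#'
#' Drops rows (site keys) with at least `threshold` missing values, then
#' columns (datasets) with at least `threshold` missing among the surviving
#' rows, then re-checks rows once. The pass order is recorded in the
#' `filter_order` attribute.
#'
#' @param m feature matrix from [assemble_feature_matrix()].
#' @param threshold missingness fraction; cells strictly below it survive.
#' @return the filtered matrix.
#' @export
filter_by_missingness <- function(m, threshold = 0.40) {
  row_ok <- rowMeans(is.na(m)) < threshold
  m <- m[row_ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("missingness filter removed every row")
  col_ok <- colMeans(is.na(m)) < threshold
  m <- m[, col_ok, drop = FALSE]
  if (ncol(m) == 0L) stop("missingness filter removed every column")
  row_ok2 <- rowMeans(is.na(m)) < threshold
  m <- m[row_ok2, , drop = FALSE]
  if (nrow(m) == 0L) stop("missingness filter removed every row")
  attr(m, "filter_order") <- "rows, columns, rows"
  attr(m, "threshold") <- threshold
  m
}

#' Ward clustering of truncation-site profiles
#'
#' Residual missing cells are imputed with 0 -- the neutral "truncated as
#' expected" value of the log2 enrichment scale -- before Euclidean distances
#' are computed; agglomeration follows Ward's criterion in its "ward.D2"
#' convention (squared-distance update, square-root merge heights).
#'
#' @param m filtered feature matrix ([filter_by_missingness()]).
#' @return object of class `papt_clustering`: list with `hclust` (the merge
#'   tree), `matrix` (the imputed matrix) and `imputation_mask` (logical
#'   matrix marking filled-in cells).
#' @export
cluster_truncation_sites <- function(m) {
  if (nrow(m) < 2L) stop("clustering requires at least 2 rows")
  mask <- is.na(m)
  mi <- m
  mi[mask] <- 0
  hc <- hclust(dist(mi, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc, matrix = mi, imputation_mask = mask),
            class = "papt_clustering")
}

#' @export
print.papt_clustering <- function(x, ...) {
  cat("Ward (ward.D2) clustering of", length(x$hclust$order),
      "truncation-site profiles over", ncol(x$matrix), "datasets;",
      sum(x$imputation_mask), "cells imputed with 0\n")
  invisible(x)
}

#' Cut the dendrogram into k clusters
#'
#' Clusters are labelled 1..k in order of first row appearance in the matrix.
#'
#' @param clustering a `papt_clustering` object.
#' @param k number of clusters.
#' @return named integer vector: cluster id per site key.
#' @export
cut_clusters <- function(clustering, k = 15L) {
  hc <- clustering$hclust
  n <- length(hc$order)
  if (k > n) stop("k (", k, ") exceeds the number of clustered rows (", n, ")")
  raw <- cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  setNames(relabel, names(raw))
}

shannon_ic <- function(freq) {
  p <- freq[freq > 0]
  log2(20) - sum(-p * log2(p))
}

#' Per-cluster motif frequencies, information content and summaries
#'
#' For each cluster the residue frequencies of the member site keys are
#' computed separately for the X and the X' slot, together with the per-slot
#' information content in bits (log2 20 minus the Shannon entropy, no
#' small-sample correction), the median of all non-missing member values
#' across datasets, and the counts of N- versus C-terminal member keys.
#'
#' @param m the filtered (pre-imputation) feature matrix.
#' @param assignments named cluster vector from [cut_clusters()].
#' @return data.frame (one row per cluster) with columns `cluster`,
#'   `n_members`, `n_terminal_count`, `c_terminal_count`, `median_value`,
#'   `x_information`, `xp_information`; attribute `motifs` holds the per-slot
#'   frequency tables.
#' @export
cluster_motif_summary <- function(m, assignments) {
  stopifnot(all(names(assignments) %in% rownames(m)))
  info <- parse_site_keys(names(assignments))
  ks <- sort(unique(assignments))
  motifs <- list()
  rows <- lapply(ks, function(cl) {
    idx <- assignments == cl
    fx <- table(factor(info$x[idx], levels = AA_STANDARD))
    fxp <- table(factor(info$x_prime[idx], levels = AA_STANDARD))
    fx <- as.numeric(fx) / sum(fx)
    fxp <- as.numeric(fxp) / sum(fxp)
    names(fx) <- names(fxp) <- AA_STANDARD
    motifs[[as.character(cl)]] <<- list(x_freq = fx, xp_freq = fxp)
    vals <- m[names(assignments)[idx], , drop = FALSE]
    data.frame(cluster = cl, n_members = sum(idx),
               n_terminal_count = sum(info$terminus[idx] == "N"),
               c_terminal_count = sum(info$terminus[idx] == "C"),
               median_value = median(vals, na.rm = TRUE),
               x_information = shannon_ic(fx),
               xp_information = shannon_ic(fxp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "motifs") <- motifs
  out
}
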