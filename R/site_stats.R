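## Truncation-site extraction, peptide-bond background, normalized frequency
## matrices, and per-dataset descriptive statistics and diagnostics.

#' Extract X|X' truncation sites from annotated proteoforms
#'
#' For every noncanonical N terminus the residues flanking the broken bond
#' are `canonical[start-1] | canonical[start]`; for every noncanonical C
#' terminus `canonical[end] | canonical[end+1]`. Full-length proteoforms and
#' start-methionine-excision starts emit no site.
#'
#' @param annotated data.frame from [annotate_proteoforms()].
#' @param db a `papt_db` object.
#' @return data.frame with columns `dataset_id`, `accession`, `terminus`
#'   (`"N"`/`"C"`), `x`, `x_prime`, `position` (start for N sites, end for C
#'   sites).
#' @export
extract_truncation_sites <- function(annotated, db) {
  canon <- db$sequences[annotated$accession]
  n_side <- annotated$state %in% c("N_TRUNC", "NC_TRUNC")
  c_side <- annotated$state %in% c("C_TRUNC", "NC_TRUNC")
  mk <- function(idx, terminus) {
    if (!any(idx)) {
      return(data.frame(dataset_id = character(0), accession = character(0),
                        terminus = character(0), x = character(0),
                        x_prime = character(0), position = integer(0),
                        stringsAsFactors = FALSE))
    }
    s <- canon[idx]
    if (terminus == "N") {
      p <- annotated$start[idx]
      x <- substr(s, p - 1L, p - 1L)
      xp <- substr(s, p, p)
    } else {
      p <- annotated$end[idx]
      x <- substr(s, p, p)
      xp <- substr(s, p + 1L, p + 1L)
    }
    data.frame(dataset_id = annotated$dataset_id[idx],
               accession = annotated$accession[idx],
               terminus = terminus, x = x, x_prime = xp,
               position = as.integer(p), stringsAsFactors = FALSE)
  }
  out <- rbind(mk(n_side, "N"), mk(c_side, "C"))
  rownames(out) <- NULL
  out
}

new_site_matrix <- function(counts, scope, excluded = 0L) {
  structure(counts, scope = scope, total = sum(counts),
            excluded = as.integer(excluded), class = c("papt_sites", "matrix"))
}

#' @export
print.papt_sites <- function(x, ...) {
  cat("20x20 site-count matrix, scope ", attr(x, "scope"), ": ",
      attr(x, "total"), " events (", attr(x, "excluded"),
      " with non-standard residues excluded)\n", sep = "")
  invisible(x)
}

pair_matrix <- function(x, x_prime) {
  std <- x %in% AA_STANDARD & x_prime %in% AA_STANDARD
  counts <- table(factor(x[std], levels = AA_STANDARD),
                  factor(x_prime[std], levels = AA_STANDARD))
  m <- matrix(as.integer(counts), 20L, 20L,
              dimnames = list(x = AA_STANDARD, x_prime = AA_STANDARD))
  list(counts = m, excluded = sum(!std))
}

#' Count truncation events per residue pair
#'
#' Aggregates the sites of [extract_truncation_sites()] into a 20x20 count
#' matrix indexed (X, X'), restricted to the requested terminus scope. Sites
#' with a non-standard residue are excluded from the matrix and tallied in the
#' `excluded` attribute.
#'
#' @param sites site data.frame from [extract_truncation_sites()].
#' @param scope `"combined"`, `"N_only"` or `"C_only"`.
#' @return 20x20 integer matrix with attributes `scope`, `total`, `excluded`.
#' @export
count_truncation_events <- function(sites,
                                    scope = c("combined", "N_only", "C_only")) {
  scope <- match.arg(scope)
  keep <- switch(scope, combined = rep(TRUE, nrow(sites)),
                 N_only = sites$terminus == "N",
                 C_only = sites$terminus == "C")
  pm <- pair_matrix(sites$x[keep], sites$x_prime[keep])
  new_site_matrix(pm$counts, scope, pm$excluded)
}

#' Count the peptide-bond background of a dataset
#'
#' Every adjacent residue pair inside every reported proteoform sequence
#' contributes one count (a proteoform of length n contributes n - 1 bonds).
#' Counting is per record, unweighted by PrSMs; bonds involving non-standard
#' letters are tallied separately.
#'
#' @param records data.frame with a `sequence` column (annotated or raw).
#' @return 20x20 integer matrix with attributes `scope = "bonds"`, `total`,
#'   `excluded`.
#' @export
count_peptide_bonds <- function(records) {
  ch <- strsplit(records$sequence, "", fixed = TRUE)
  a <- unlist(lapply(ch, function(v) v[-length(v)]), use.names = FALSE)
  b <- unlist(lapply(ch, function(v) v[-1L]), use.names = FALSE)
  pm <- pair_matrix(a, b)
  new_site_matrix(pm$counts, "bonds", pm$excluded)
}

#' Normalized truncation-site frequency matrix
#'
#' The share of truncation events at a residue pair is divided by the share of
#' that pair among the peptide bonds identified in the dataset, and the log2
#' of the ratio is reported. Zero means the bond is truncated exactly as often
#' as expected from its occurrence; positive values are overrepresented and
#' negative values underrepresented truncation sites. Cells where either the
#' truncation count or the bond count is zero are missing (`NA`), not
#' pseudocounted.
#'
#' @param trunc 20x20 truncation-event count matrix
#'   ([count_truncation_events()]).
#' @param bonds 20x20 peptide-bond count matrix ([count_peptide_bonds()]).
#' @return 20x20 numeric matrix (log2 enrichment) with `NA` for missing cells
#'   and attributes `scope` and `log_base = 2`.
#' @export
normalized_frequency <- function(trunc, bonds) {
  if (attr(trunc, "total") == 0L || attr(bonds, "total") == 0L) {
    stop("normalized_frequency requires non-zero truncation and bond totals")
  }
  t_share <- unclass(trunc) / attr(trunc, "total")
  b_share <- unclass(bonds) / attr(bonds, "total")
  v <- log2(t_share / b_share)
  v[unclass(trunc) == 0L | unclass(bonds) == 0L] <- NA_real_
  structure(matrix(as.numeric(v), 20L, 20L,
                   dimnames = list(x = AA_STANDARD, x_prime = AA_STANDARD)),
            scope = attr(trunc, "scope"), log_base = 2)
}

#' Truncation-state and protein-level summary of one dataset
#'
#' @param annotated data.frame from [annotate_proteoforms()] (one dataset).
#' @return list with `state_proportions` (named fractions over the four
#'   states, summing to 1) and `protein_level` (fractions of proteins seen
#'   `only_full_length`, `only_truncated`, or `both`).
#' @export
dataset_state_summary <- function(annotated) {
  if (nrow(annotated) == 0L) stop("dataset_state_summary: empty dataset")
  state_tab <- table(annotated$state)
  state_proportions <- as.numeric(state_tab) / nrow(annotated)
  names(state_proportions) <- names(state_tab)
  fl <- annotated$state == "FULL_LENGTH"
  any_fl <- tapply(fl, annotated$accession, any)
  any_tr <- tapply(!fl, annotated$accession, any)
  protein_level <- c(
    only_full_length = mean(any_fl & !any_tr),
    only_truncated   = mean(!any_fl & any_tr),
    both             = mean(any_fl & any_tr)
  )
  list(state_proportions = state_proportions, protein_level = protein_level)
}

#' Mean PrSM counts of full-length versus truncated proteoforms
#'
#' Per group, the total number of PrSMs is divided by the number of
#' proteoforms in the group. Records without a PrSM count are excluded and
#' counted.
#'
#' @param annotated annotated dataset.
#' @return named numeric `c(full_length=, truncated=)`; `NA` for a group with
#'   no PrSM-carrying members. Attributes: `n_without_prsm`, and
#'   `defined = FALSE` when no record carries PrSM information at all.
#' @export
prsm_state_summary <- function(annotated) {
  has <- !is.na(annotated$prsm_count)
  grp <- ifelse(annotated$state == "FULL_LENGTH", "full_length", "truncated")
  out <- c(full_length = NA_real_, truncated = NA_real_)
  for (g in names(out)) {
    idx <- has & grp == g
    if (any(idx)) out[g] <- sum(annotated$prsm_count[idx]) / sum(idx)
  }
  attr(out, "n_without_prsm") <- sum(!has)
  attr(out, "defined") <- any(has)
  out
}

#' Fraction of truncated proteoforms whose termini are described in the database
#'
#' A truncated terminus is "known" under the annotation-matching rules of
#' [match_uniprot_annotation()]; an N/C-truncated proteoform requires both
#' termini to match.
#'
#' @param annotated annotated dataset.
#' @param db a `papt_db` object carrying features.
#' @return named numeric fractions for `N_TRUNC`, `C_TRUNC`, `NC_TRUNC`
#'   (`NaN` where the state is absent from the dataset).
#' @export
known_in_uniprot_fraction <- function(annotated, db) {
  len <- nchar(db$sequences)
  known_term <- function(acc, terminus, pos) {
    ## deduplicate (accession, terminus, position) before feature matching
    key <- paste(acc, terminus, pos)
    uk <- !duplicated(key)
    res <- mapply(function(a, p) {
      match_uniprot_annotation(terminus, p,
                               db$features[db$features$accession == a, ,
                                           drop = FALSE], len[[a]])$known
    }, acc[uk], pos[uk], USE.NAMES = FALSE)
    unname(res[match(key, key[uk])])
  }
  n_ok <- rep(NA, nrow(annotated))
  c_ok <- rep(NA, nrow(annotated))
  ni <- annotated$state %in% c("N_TRUNC", "NC_TRUNC")
  ci <- annotated$state %in% c("C_TRUNC", "NC_TRUNC")
  if (any(ni)) n_ok[ni] <- known_term(annotated$accession[ni], "N", annotated$start[ni])
  if (any(ci)) c_ok[ci] <- known_term(annotated$accession[ci], "C", annotated$end[ci])
  known <- ifelse(annotated$state == "N_TRUNC", n_ok,
           ifelse(annotated$state == "C_TRUNC", c_ok,
           ifelse(annotated$state == "NC_TRUNC", n_ok & c_ok, NA)))
  vapply(c("N_TRUNC", "C_TRUNC", "NC_TRUNC"), function(s) {
    idx <- annotated$state == s
    mean(known[idx])
  }, numeric(1))
}

#' Ratio of proline at the X' position of N- versus C-terminal truncation sites
#'
#' In-source ion activation artificially truncates proteoforms through a
#' CID-like mechanism producing y-ions (N-terminal truncations), with peptide
#' bonds N-terminal to proline particularly susceptible. An elevated
#' N-to-C ratio of proline at X' therefore flags in-source fragmentation.
#'
#' @param sites site data.frame from [extract_truncation_sites()].
#' @return the ratio, or `NA` when no C-terminal proline site exists
#'   (attribute `numerator` then carries the N-side count).
#' @export
proline_insource_ratio <- function(sites) {
  num <- sum(sites$terminus == "N" & sites$x_prime == "P")
  den <- sum(sites$terminus == "C" & sites$x_prime == "P")
  if (den == 0L) {
    return(structure(NA_real_, numerator = num))
  }
  num / den
}

#' Histograms of terminus positions relative to the canonical sequence
#'
#' @param annotated annotated dataset.
#' @return list with `n_position` and `c_offset`: named integer vectors of
#'   exact-integer counts (no smoothing).
#' @export
terminus_position_histograms <- function(annotated) {
  list(n_position = table(annotated$n_position),
       c_offset = table(annotated$c_offset))
}

#' Truncation-state proportions by proteoform length bin
#'
#' Proteoforms are binned by observed sequence length into
#' `[k*w, (k+1)*w)` bins labelled like `"125-150"`; per-bin fractions over the
#' four states sum to 1. Empty bins are omitted.
#'
#' @param annotated annotated dataset.
#' @param bin_width bin width in residues.
#' @return matrix: one row per non-empty bin, four state-fraction columns.
#' @export
length_bin_state_proportions <- function(annotated, bin_width = 25L) {
  len <- nchar(annotated$sequence)
  k <- len %/% bin_width
  lab <- paste0(k * bin_width, "-", (k + 1L) * bin_width)
  labs <- unique(lab[order(k)])
  tab <- table(factor(lab, levels = labs), annotated$state)
  props <- tab / rowSums(tab)
  m <- matrix(as.numeric(props), nrow = nrow(tab),
              dimnames = list(bin = rownames(tab), state = colnames(tab)))
  m
}

#' Correlation between protein abundance and truncated-proteoform counts
#'
#' Ordinary least squares of the number of truncated proteoforms per protein
#' on (by default log10-scaled) abundance, computed on the accessions present
#' in both maps.
#'
#' @param truncated_counts named integer vector: truncated proteoforms per
#'   accession.
#' @param abundance named numeric vector of abundances (PaxDb-style units).
#' @param log10_abundance regress on log10 abundance (default) or linear.
#' @return R-squared with attribute `n` (intersection size); `NA` when fewer
#'   than 3 accessions overlap.
#' @export
abundance_truncation_correlation <- function(truncated_counts, abundance,
                                             log10_abundance = TRUE) {
  common <- intersect(names(truncated_counts), names(abundance))
  common <- common[!is.na(abundance[common]) & abundance[common] > 0]
  if (length(common) < 3L) {
    return(structure(NA_real_, n = length(common)))
  }
  x <- abundance[common]
  if (log10_abundance) x <- log10(x)
  fit <- lm(y ~ x, data = data.frame(y = as.numeric(truncated_counts[common]),
                                     x = as.numeric(x)))
  structure(summary(fit)$r.squared, n = length(common))
}
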