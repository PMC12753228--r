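## Per-protein termini profiles across datasets, consistency counts,
## annotation matching, and terminus categories.

#' Build per-protein noncanonical-termini profiles across datasets
#'
#' Collects, per accession and dataset, the deduplicated set of noncanonical
#' terminus positions (N positions are proteoform starts, C positions are
#' proteoform ends). Canonical termini and start-methionine-excision starts
#' contribute nothing.
#'
#' @param annotated annotated proteoform data.frame (any number of datasets,
#'   distinguished by `dataset_id`), or a list of such data.frames.
#' @return data.frame with columns `accession`, `dataset_id`, `terminus`,
#'   `position`, one row per distinct (accession, dataset, terminus,
#'   position).
#' @export
build_termini_profiles <- function(annotated) {
  if (is.list(annotated) && !is.data.frame(annotated)) {
    annotated <- do.call(rbind, annotated)
  }
  ni <- annotated$state %in% c("N_TRUNC", "NC_TRUNC")
  ci <- annotated$state %in% c("C_TRUNC", "NC_TRUNC")
  prof <- rbind(
    data.frame(accession = annotated$accession[ni],
               dataset_id = annotated$dataset_id[ni],
               terminus = rep("N", sum(ni)), position = annotated$start[ni],
               stringsAsFactors = FALSE),
    data.frame(accession = annotated$accession[ci],
               dataset_id = annotated$dataset_id[ci],
               terminus = rep("C", sum(ci)), position = annotated$end[ci],
               stringsAsFactors = FALSE)
  )
  prof <- unique(prof)
  prof <- prof[order(prof$accession, prof$terminus, prof$position,
                     prof$dataset_id), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' Match a noncanonical terminus against sequence annotation features
#'
#' An N terminus at position p is known when p is the begin of a chain or
#' peptide feature starting after position 1, or p is one past the end of a
#' signal peptide, transit peptide or propeptide (the processed mature start).
#' A C terminus at position e is known when e is the end of a chain or peptide
#' feature ending before the last residue, or e is one before the begin of a
#' propeptide. Chain features spanning the whole sequence describe the
#' unprocessed molecule and never generate known termini.
#'
#' @param terminus `"N"` or `"C"`.
#' @param position 1-based terminus position on the canonical sequence.
#' @param features feature data.frame (columns `category`, `begin`, `end`)
#'   for this protein.
#' @param length canonical sequence length.
#' @return list with `known` (logical), `nearest_category` and
#'   `nearest_distance` (`NA` when no feature implies a cleavage for this
#'   terminus).
#' @export
match_uniprot_annotation <- function(terminus, position, features, length) {
  if (is.null(features) || nrow(features) == 0L) {
    return(list(known = FALSE, nearest_category = NA_character_,
                nearest_distance = NA_integer_))
  }
  full_span <- features$category == "chain" &
    features$begin == 1L & features$end == length
  f <- features[!full_span, , drop = FALSE]
  cand_pos <- integer(0)
  cand_cat <- character(0)
  if (terminus == "N") {
    cp <- f$category %in% c("chain", "peptide") & f$begin > 1L
    cand_pos <- c(cand_pos, f$begin[cp])
    cand_cat <- c(cand_cat, f$category[cp])
    sp <- f$category %in% c("signal_peptide", "transit_peptide", "propeptide") &
      f$end < length
    cand_pos <- c(cand_pos, f$end[sp] + 1L)
    cand_cat <- c(cand_cat, f$category[sp])
  } else {
    cp <- f$category %in% c("chain", "peptide") & f$end < length
    cand_pos <- c(cand_pos, f$end[cp])
    cand_cat <- c(cand_cat, f$category[cp])
    pp <- f$category == "propeptide" & f$begin > 1L
    cand_pos <- c(cand_pos, f$begin[pp] - 1L)
    cand_cat <- c(cand_cat, f$category[pp])
  }
  if (length(cand_pos) == 0L) {
    return(list(known = FALSE, nearest_category = NA_character_,
                nearest_distance = NA_integer_))
  }
  d <- abs(cand_pos - position)
  i <- which.min(d)
  list(known = any(d == 0L), nearest_category = cand_cat[i],
       nearest_distance = as.integer(d[i]))
}

#' Categorize a consistent noncanonical terminus
#'
#' Four categories: `annotated_match` (the terminus coincides with a cleavage
#' implied by an annotation feature), `near_annotated` (within `near_window`
#' residues of one), `inter_domain` (the cut falls strictly between two
#' annotated domains that lie fully on opposite sides), `unrelated`.
#'
#' @inheritParams match_uniprot_annotation
#' @param near_window maximal distance (residues) to an implied cleavage for
#'   the `near_annotated` category.
#' @param match optional precomputed result of [match_uniprot_annotation()].
#' @return one of the four category strings.
#' @export
categorize_terminus <- function(terminus, position, features, length,
                                near_window = 15L, match = NULL) {
  if (is.null(match)) {
    match <- match_uniprot_annotation(terminus, position, features, length)
  }
  if (isTRUE(match$known)) return("annotated_match")
  if (!is.na(match$nearest_distance) && match$nearest_distance <= near_window) {
    return("near_annotated")
  }
  ## the broken bond lies between residues cut and cut + 1
  cut <- if (terminus == "N") position - 1L else position
  dom <- features[features$category == "domain", , drop = FALSE]
  if (nrow(dom) >= 2L &&
      !any(dom$begin <= cut & dom$end >= cut + 1L) &&
      any(dom$end <= cut) && any(dom$begin >= cut + 1L)) {
    return("inter_domain")
  }
  "unrelated"
}

#' Count consistently identified noncanonical termini across datasets
#'
#' For each (accession, terminus, position) the number of datasets whose
#' termini set contains the position is counted; a terminus counts once per
#' dataset regardless of how many proteoforms share it. When a database is
#' supplied, each call is matched against annotation features and categorized.
#'
#' @param profiles termini profiles from [build_termini_profiles()].
#' @param min_datasets report only termini seen in at least this many
#'   datasets.
#' @param db optional `papt_db`; adds `known`, `category`,
#'   `nearest_category`, `nearest_distance` columns.
#' @param near_window passed to [categorize_terminus()].
#' @return data.frame sorted by `n_datasets` descending, then accession, then
#'   position, with columns `accession`, `terminus`, `position`,
#'   `n_datasets` (+ annotation columns when `db` is given).
#' @export
consistency_counts <- function(profiles, min_datasets = 1L, db = NULL,
                               near_window = 15L) {
  key <- paste(profiles$accession, profiles$terminus, profiles$position,
               sep = "\r")
  n_ds <- tapply(profiles$dataset_id, key, function(x) length(unique(x)))
  uk <- !duplicated(key)
  calls <- data.frame(accession = profiles$accession[uk],
                      terminus = profiles$terminus[uk],
                      position = profiles$position[uk],
                      n_datasets = as.integer(n_ds[key[uk]]),
                      stringsAsFactors = FALSE)
  calls <- calls[calls$n_datasets >= min_datasets, , drop = FALSE]
  calls <- calls[order(-calls$n_datasets, calls$accession, calls$position), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  if (!is.null(db) && nrow(calls) > 0L) {
    len <- nchar(db$sequences)
    res <- mapply(function(a, tm, p) {
      feats <- db$features[db$features$accession == a, , drop = FALSE]
      mt <- match_uniprot_annotation(tm, p, feats, len[[a]])
      list(known = mt$known,
           category = categorize_terminus(tm, p, feats, len[[a]],
                                          near_window = near_window,
                                          match = mt),
           nearest_category = mt$nearest_category,
           nearest_distance = mt$nearest_distance)
    }, calls$accession, calls$terminus, calls$position, SIMPLIFY = FALSE)
    calls$known <- vapply(res, function(r) r$known, logical(1))
    calls$category <- vapply(res, function(r) r$category, character(1))
    calls$nearest_category <- vapply(res, function(r) r$nearest_category,
                                     character(1))
    calls$nearest_distance <- vapply(res, function(r) r$nearest_distance,
                                     integer(1))
  }
  calls
}
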