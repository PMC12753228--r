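## Mapping proteoforms onto canonical sequences and truncation-state calls.

#' Locate a proteoform sequence on its canonical sequence
#'
#' If reported coordinates are supplied and agree with the sequence content
#' they are used; otherwise the leftmost occurrence is taken and a
#' coordinate-conflict flag is raised. Placement is ambiguous when the
#' sequence occurs at more than one offset of the canonical sequence.
#'
#' @param sequence bare proteoform amino-acid sequence.
#' @param canonical canonical protein sequence (must contain `sequence`).
#' @param reported_start,reported_end optional reported 1-based coordinates.
#' @return list with `start`, `end` (1-based inclusive), `ambiguous` (logical)
#'   and `coord_conflict` (TRUE when reported coordinates were rejected).
#' @export
locate_proteoform <- function(sequence, canonical,
                              reported_start = NA_integer_,
                              reported_end = NA_integer_) {
  first <- stringi::stri_locate_first_fixed(canonical, sequence)[, 1L]
  if (is.na(first)) stop("proteoform sequence does not occur in canonical sequence")
  ambiguous <- stringi::stri_count_fixed(canonical, sequence, overlap = TRUE) > 1L
  conflict <- FALSE
  if (!is.na(reported_start) && !is.na(reported_end)) {
    if (reported_end - reported_start + 1L == nchar(sequence) &&
        reported_start >= 1L && reported_end <= nchar(canonical) &&
        substr(canonical, reported_start, reported_end) == sequence) {
      return(list(start = as.integer(reported_start),
                  end = as.integer(reported_end),
                  ambiguous = ambiguous, coord_conflict = FALSE))
    }
    conflict <- TRUE
  }
  s <- as.integer(first)
  list(start = s, end = s + nchar(sequence) - 1L,
       ambiguous = ambiguous, coord_conflict = conflict)
}

#' Classify the truncation state of a placed proteoform
#'
#' The N terminus is canonical when the proteoform starts at position 1, or at
#' position 2 of a methionine-initiated protein (start-methionine excision is
#' not a truncation). The C terminus is canonical when the proteoform ends at
#' the last canonical residue. All arguments are vectorized.
#'
#' @param start,end 1-based coordinates on the canonical sequence.
#' @param length canonical sequence length(s).
#' @param first_residue first residue(s) of the canonical sequence.
#' @return factor with levels `FULL_LENGTH`, `N_TRUNC`, `C_TRUNC`, `NC_TRUNC`.
#' @export
classify_truncation <- function(start, end, length, first_residue) {
  n_canon <- start == 1L | (start == 2L & first_residue == "M")
  c_canon <- end == length
  state <- ifelse(n_canon & c_canon, "FULL_LENGTH",
           ifelse(!n_canon & c_canon, "N_TRUNC",
           ifelse(n_canon & !c_canon, "C_TRUNC", "NC_TRUNC")))
  factor(state, levels = STATE_LEVELS)
}

#' Terminus positions relative to the canonical sequence
#'
#' The N-terminal coordinate is the start position itself; the C-terminal
#' coordinate is the offset from the canonical C terminus (0 = canonical,
#' -1 = loss of one residue, ...). Vectorized.
#'
#' @inheritParams classify_truncation
#' @return list with `n_position` and `c_offset` integer vectors.
#' @export
terminus_offsets <- function(start, end, length) {
  list(n_position = as.integer(start), c_offset = as.integer(end - length))
}

#' Annotate proteoform records against their canonical sequences
#'
#' Places every record on its canonical sequence (verified reported
#' coordinates first, leftmost occurrence otherwise), assigns the truncation
#' state and the terminus coordinates, and flags ambiguous placements.
#' Records must already have passed [link_and_filter()].
#'
#' @param records proteoform record data.frame.
#' @param db a `papt_db` object.
#' @return the records with added columns `start`, `end`, `state`,
#'   `ambiguous`, `n_position`, `c_offset`. Attribute `n_coord_conflicts`
#'   counts records whose reported coordinates were rejected.
#' @export
annotate_proteoforms <- function(records, db) {
  stopifnot(inherits(db, "papt_db"))
  canon <- db$sequences[records$accession]
  if (anyNA(canon)) stop("records contain accessions absent from the database; ",
                         "run link_and_filter() first")
  n <- nrow(records)
  len <- nchar(canon)
  slen <- nchar(records$sequence)

  ## fast path: reported coordinates that verify against the canonical sequence
  rs <- if ("start" %in% names(records)) records$start else rep(NA_integer_, n)
  re <- if ("end" %in% names(records)) records$end else rep(NA_integer_, n)
  has_coord <- !is.na(rs) & !is.na(re)
  verified <- has_coord & (re - rs + 1L == slen) & rs >= 1L & re <= len &
    substr(canon, pmax(rs, 1L), pmax(re, 1L)) == records$sequence
  verified[is.na(verified)] <- FALSE
  conflict <- has_coord & !verified

  start <- ifelse(verified, rs, NA_integer_)
  need <- !verified
  if (any(need)) {
    hit <- stringi::stri_locate_first_fixed(canon[need],
                                            records$sequence[need])[, 1L]
    if (anyNA(hit)) stop("record sequence not found in canonical sequence")
    start[need] <- as.integer(hit)
  }
  end <- as.integer(start + slen - 1L)
  start <- as.integer(start)

  ## ambiguous iff the sequence occurs at more than one (possibly
  ## overlapping) offset of the canonical sequence
  n_occ <- stringi::stri_count_fixed(canon, records$sequence,
                                     overlap = TRUE)
  ambiguous <- n_occ > 1L

  if (any(conflict)) {
    .papt_msg(sum(conflict),
              " record(s) with reported coordinates inconsistent with the ",
              "sequence content; leftmost placement used")
  }
  out <- records
  out$start <- start
  out$end <- end
  out$state <- classify_truncation(start, end, len, substr(canon, 1L, 1L))
  out$ambiguous <- ambiguous
  off <- terminus_offsets(start, end, len)
  out$n_position <- off$n_position
  out$c_offset <- off$c_offset
  attr(out, "n_coord_conflicts") <- sum(conflict)
  out
}
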