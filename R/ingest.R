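## Ingestion of proteoform identification lists and canonical sequence databases.

#' Strip ProForma-style modification notation from a proteoform string
#'
#' Removes square-bracketed modification tags, parenthesized mass shifts and
#' terminal markers from ProForma-like proteoform strings, returning only the
#' uppercased residue letters. Bracket nesting is respected; the function is
#' idempotent on bare sequences.
#'
#' @param x character vector of ProForma-like strings (e.g.
#'   `"[+42.0106]-MAGTK[Oxidation]"`).
#' @return character vector of bare amino-acid sequences.
#' @examples
#' strip_proforma("M[Acetyl]AGTK")
#' strip_proforma("[+42.0106]-MAGTK[Oxidation]")
#' @export
strip_proforma <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    sq <- 0L
    par <- 0L
    keep <- logical(length(chars))
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "[") {
        sq <- sq + 1L
      } else if (ch == "]") {
        sq <- sq - 1L
        if (sq < 0L) stop("unbalanced brackets in ProForma string: ", s)
      } else if (ch == "(") {
        par <- par + 1L
      } else if (ch == ")") {
        par <- par - 1L
        if (par < 0L) stop("unbalanced brackets in ProForma string: ", s)
      } else if (sq == 0L && par == 0L) {
        keep[i] <- grepl("[A-Za-z]", ch)
      }
    }
    if (sq != 0L || par != 0L) {
      stop("unbalanced brackets in ProForma string: ", s)
    }
    toupper(paste(chars[keep], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## "db|ACC|name" style identifiers are reduced to the token between the pipes;
## anything else is used verbatim.
normalize_accession <- function(x) {
  has_pipe <- grepl("|", x, fixed = TRUE)
  if (any(has_pipe)) {
    parts <- strsplit(x[has_pipe], "|", fixed = TRUE)
    x[has_pipe] <- vapply(parts, function(p) {
      if (length(p) >= 2L && nzchar(p[2L])) p[2L] else p[1L]
    }, character(1))
  }
  x
}

#' Default column mapping for proteoform identification tables
#'
#' The canonical interchange dialect used by [write_proteoform_table()]:
#' tab-separated with columns `dataset_id`, `accession`, `sequence`,
#' `proforma`, `prsm_count`, `start`, `end` (absent optionals as empty cells).
#'
#' @return named list mapping canonical field names to source column names.
#' @export
canonical_dialect <- function() {
  list(accession = "accession", sequence = "sequence", proforma = "proforma",
       prsm_count = "prsm_count", start = "start", end = "end")
}

#' Read a proteoform identification table
#'
#' Reads one delimited proteoform identification list (one row per reported
#' proteoform) and maps its columns onto the canonical record fields. Rows
#' missing both a sequence and a ProForma string are dropped with a logged
#' count; where only a ProForma string is present the bare sequence is
#' recovered with [strip_proforma()].
#'
#' @param path path to a delimited text file with a header row.
#' @param dataset_id identifier attached to every record from this table.
#' @param dialect named list mapping canonical fields (`accession`,
#'   `sequence`, and optionally `proforma`, `prsm_count`, `start`, `end`) to
#'   source column names; see [canonical_dialect()]. `accession` is mandatory;
#'   at least one of `sequence`/`proforma` must be mapped.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @return data.frame with columns `dataset_id`, `accession`, `sequence`,
#'   `proforma`, `prsm_count`, `start`, `end`; attribute `n_dropped` counts
#'   rows removed for lacking any sequence information.
#' @export
read_proteoform_table <- function(path, dataset_id, dialect = canonical_dialect(),
                                  sep = NULL) {
  if (!file.exists(path)) stop("cannot read proteoform table: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (is.null(dialect$accession)) {
    stop("dialect does not map the mandatory column: accession")
  }
  if (is.null(dialect$sequence) && is.null(dialect$proforma)) {
    stop("dialect does not map the mandatory column: sequence")
  }
  pick <- function(field, mandatory = FALSE) {
    col <- dialect[[field]]
    if (is.null(col)) return(NULL)
    if (!col %in% names(raw)) {
      if (mandatory) stop("mapped column not found in ", path, ": ", col)
      return(NULL)
    }
    raw[[col]]
  }
  acc <- pick("accession", mandatory = TRUE)
  if (is.null(acc)) stop("dialect does not map the mandatory column: accession")
  n <- nrow(raw)
  take_chr <- function(v) if (is.null(v)) rep(NA_character_, n) else as.character(v)
  take_int <- function(v) if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  seq_mapped <- !is.null(dialect$sequence) && dialect$sequence %in% names(raw)
  if (!seq_mapped && (is.null(dialect$proforma) || !dialect$proforma %in% names(raw))) {
    stop("mapped column not found in ", path, ": ",
         if (!is.null(dialect$sequence)) dialect$sequence else "sequence")
  }
  rec <- data.frame(
    dataset_id = rep(as.character(dataset_id), n),
    accession  = normalize_accession(take_chr(acc)),
    sequence   = toupper(take_chr(pick("sequence"))),
    proforma   = take_chr(pick("proforma")),
    prsm_count = take_int(pick("prsm_count")),
    start      = take_int(pick("start")),
    end        = take_int(pick("end")),
    stringsAsFactors = FALSE
  )
  need_strip <- is.na(rec$sequence) & !is.na(rec$proforma)
  if (any(need_strip)) {
    rec$sequence[need_strip] <- strip_proforma(rec$proforma[need_strip])
  }
  drop <- is.na(rec$sequence) | !nzchar(rec$sequence)
  if (any(drop)) {
    .papt_msg(dataset_id, ": dropped ", sum(drop),
              " record(s) without sequence or ProForma")
    rec <- rec[!drop, , drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "n_dropped") <- sum(drop)
  rec
}

#' Write proteoform records in the canonical tab-separated dialect
#'
#' @param records data.frame as returned by [read_proteoform_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteoform_table <- function(records, path) {
  cols <- c("dataset_id", "accession", "sequence", "proforma",
            "prsm_count", "start", "end")
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

## --- canonical sequence databases -------------------------------------------

uniprot_feature_map <- c(
  "signal peptide"       = "signal_peptide",
  "transit peptide"      = "transit_peptide",
  "propeptide"           = "propeptide",
  "chain"                = "chain",
  "peptide"              = "peptide",
  "domain"               = "domain",
  "initiator methionine" = "initiator_methionine"
)

empty_features <- function() {
  data.frame(accession = character(0), category = character(0),
             begin = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

new_protein_db <- function(sequences, features = empty_features(),
                           abundance = NULL) {
  structure(list(sequences = sequences, features = features,
                 abundance = abundance),
            class = "papt_db")
}

#' Construct a canonical protein database from in-memory objects
#'
#' Programmatic alternative to [read_canonical_db()] for sequences and
#' features built in code.
#'
#' @param sequences named character vector of canonical sequences (names are
#'   accessions; 20 standard letters plus the B/J/O/U/X/Z ambiguity set).
#' @param features optional data.frame with columns `accession`, `category`
#'   (one of the supported annotation categories), `begin`, `end` (1-based,
#'   inclusive, within the sequence).
#' @param abundance optional named non-negative numeric vector.
#' @return a `papt_db` object.
#' @export
protein_db <- function(sequences, features = NULL, abundance = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  sequences <- toupper(sequences)
  ok <- grepl(paste0("^[", paste(c(AA_STANDARD, AA_AMBIGUOUS), collapse = ""),
                     "]+$"), sequences)
  if (!all(ok)) stop("sequences contain letters outside the amino-acid alphabet: ",
                     paste(names(sequences)[!ok], collapse = ", "))
  if (is.null(features)) features <- empty_features()
  stopifnot(all(c("accession", "category", "begin", "end") %in% names(features)))
  if (!all(features$category %in% FEATURE_CATEGORIES)) {
    stop("unsupported feature category")
  }
  if (!all(features$accession %in% names(sequences))) {
    stop("features reference unknown accessions")
  }
  len <- nchar(sequences)[features$accession]
  if (!all(features$begin >= 1L & features$begin <= features$end &
             features$end <= len)) {
    stop("features must lie within [1, sequence length]")
  }
  db <- new_protein_db(sequences, features)
  if (!is.null(abundance)) db <- set_abundance(db, abundance)
  db
}

#' @export
print.papt_db <- function(x, ...) {
  cat("Canonical protein database:", length(x$sequences), "entries,",
      nrow(x$features), "annotation features",
      if (!is.null(x$abundance)) paste0("(", sum(!is.na(x$abundance)),
                                        " with abundance)") else "", "\n")
  invisible(x)
}

parse_uniprot_xml <- function(xml_path) {
  doc <- tryCatch(xml2::read_xml(xml_path),
                  error = function(e) stop("malformed XML in ", xml_path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  entries <- xml2::xml_find_all(doc, ".//entry")
  seqs <- character(0)
  feats <- list()
  unknown_types <- 0L
  discarded <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    acc_node <- xml2::xml_find_first(e, "./accession")
    seq_node <- xml2::xml_find_first(e, "./sequence")
    if (is.na(acc_node) || is.na(seq_node)) {
      stop("malformed XML entry at index ", i, " in ", xml_path,
           ": missing accession or sequence")
    }
    acc <- xml2::xml_text(acc_node)
    sq <- toupper(gsub("[^A-Za-z]", "", xml2::xml_text(seq_node)))
    seqs[acc] <- sq
    for (f in xml2::xml_find_all(e, "./feature")) {
      type <- xml2::xml_attr(f, "type")
      cat_ <- uniprot_feature_map[type]
      if (is.na(cat_)) {
        unknown_types <- unknown_types + 1L
        next
      }
      b <- xml2::xml_attr(xml2::xml_find_first(f, "./location/begin"), "position")
      en <- xml2::xml_attr(xml2::xml_find_first(f, "./location/end"), "position")
      if (is.na(b) && is.na(en)) {
        p <- xml2::xml_attr(xml2::xml_find_first(f, "./location/position"), "position")
        b <- p
        en <- p
      }
      b <- suppressWarnings(as.integer(b))
      en <- suppressWarnings(as.integer(en))
      if (is.na(b) || is.na(en)) {
        discarded <- discarded + 1L
        next
      }
      if (b < 1L || en < b || en > nchar(sq)) {
        discarded <- discarded + 1L
        warning("feature outside sequence bounds discarded for ", acc,
                " (", cat_, " ", b, "-", en, ")", call. = FALSE)
        next
      }
      feats[[length(feats) + 1L]] <- data.frame(
        accession = acc, category = unname(cat_), begin = b, end = en,
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  list(sequences = seqs, features = features,
       unknown_feature_types = unknown_types, discarded_features = discarded)
}

#' Read a canonical sequence database from FASTA and/or UniProt-style XML
#'
#' Loads canonical protein sequences and, when XML is supplied, their
#' positional annotation features (signal peptide, transit peptide, propeptide,
#' chain, peptide, domain, initiator methionine). When both inputs are given
#' the XML features attach to the union of entries; on a sequence conflict for
#' the same accession the XML sequence wins and the conflict is logged.
#' Features with unknown types are ignored and counted; features extending
#' beyond the sequence are discarded with a warning.
#'
#' @param fasta_path optional path to a protein FASTA file.
#' @param xml_path optional path to a UniProt-entry-style XML file.
#' @return a `papt_db` object: list with `sequences` (named character vector),
#'   `features` (data.frame with columns `accession`, `category`, `begin`,
#'   `end`) and `abundance` (`NULL` until set with [set_abundance()]).
#' @export
read_canonical_db <- function(fasta_path = NULL, xml_path = NULL) {
  if (is.null(fasta_path) && is.null(xml_path)) {
    stop("at least one of fasta_path / xml_path must be given")
  }
  seqs <- character(0)
  features <- empty_features()
  if (!is.null(fasta_path)) {
    aas <- Biostrings::readAAStringSet(fasta_path)
    if (length(aas) == 0L) stop("no parsable entries in ", fasta_path)
    acc <- normalize_accession(vapply(strsplit(names(aas), "\\s+"), `[`, "", 1L))
    seqs <- setNames(toupper(as.character(aas)), acc)
  }
  if (!is.null(xml_path)) {
    xp <- parse_uniprot_xml(xml_path)
    if (length(xp$sequences) == 0L && length(seqs) == 0L) {
      stop("no parsable entries in ", xml_path)
    }
    shared <- intersect(names(seqs), names(xp$sequences))
    conflicts <- shared[seqs[shared] != xp$sequences[shared]]
    if (length(conflicts)) {
      .papt_msg("sequence conflict between FASTA and XML for ",
                length(conflicts), " accession(s); XML sequence used")
    }
    seqs[names(xp$sequences)] <- xp$sequences
    features <- xp$features
    if (xp$unknown_feature_types > 0L) {
      .papt_msg("ignored ", xp$unknown_feature_types,
                " feature(s) with out-of-scope types")
    }
  }
  if (length(seqs) == 0L) stop("no parsable entries in canonical database")
  bad <- !grepl(paste0("^[", paste(c(AA_STANDARD, AA_AMBIGUOUS), collapse = ""),
                       "]+$"), seqs)
  if (any(bad)) {
    warning(sum(bad), " entries with letters outside the amino-acid alphabet ",
            "were removed", call. = FALSE)
    seqs <- seqs[!bad]
    features <- features[features$accession %in% names(seqs), , drop = FALSE]
  }
  new_protein_db(seqs, features)
}

#' Attach a PaxDb-style abundance table to a canonical database
#'
#' @param db a `papt_db` object.
#' @param abundance either a named numeric vector (names are accessions) or a
#'   data.frame with columns `accession` and `abundance`.
#' @return the database with abundances attached (unmatched accessions are
#'   silently ignored).
#' @export
set_abundance <- function(db, abundance) {
  stopifnot(inherits(db, "papt_db"))
  if (is.data.frame(abundance)) {
    abundance <- setNames(abundance$abundance, abundance$accession)
  }
  ab <- abundance[names(abundance) %in% names(db$sequences)]
  if (any(ab < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  db$abundance <- ab
  db
}

#' Remove records without an active accession or a canonical sequence match
#'
#' Applies the record-filtering rules of the pooled analysis: records whose
#' accession is absent from the canonical database are removed, as are records
#' whose (stripped) sequence does not occur as a substring of the canonical
#' sequence of their protein. Filtering is reported, never silent.
#'
#' @param records proteoform record data.frame.
#' @param db a `papt_db` object.
#' @return list with `records` (the retained subset) and `report` (named list
#'   of per-reason counts: `unknown_accession`, `no_match`, plus `n_input` and
#'   `n_retained`).
#' @export
link_and_filter <- function(records, db) {
  stopifnot(inherits(db, "papt_db"))
  unknown <- !(records$accession %in% names(db$sequences))
  canon <- db$sequences[records$accession]
  nomatch <- !unknown & (is.na(records$sequence) | !nzchar(records$sequence))
  chk <- !unknown & !nomatch
  nomatch[chk] <- !stringi::stri_detect_fixed(canon[chk], records$sequence[chk])
  keep <- !unknown & !nomatch
  report <- list(unknown_accession = sum(unknown), no_match = sum(nomatch),
                 n_input = nrow(records), n_retained = sum(keep))
  if (report$unknown_accession + report$no_match > 0L) {
    .papt_msg("filtered ", report$unknown_accession,
              " record(s) with unknown accession and ", report$no_match,
              " with no canonical sequence match")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}
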