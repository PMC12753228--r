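# shared fixture builders (everything is generated in code)

toy_db <- function() {
  protein_db(
    c(P1 = "MADPKGVR",
      P2 = "MAGAGAK",
      P3 = "AADPK"),
    features = data.frame(
      accession = "P1", category = "chain", begin = 3L, end = 8L,
      stringsAsFactors = FALSE)
  )
}

random_protein <- function(len, first_m = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  body <- paste(sample(aa, len - first_m, replace = TRUE), collapse = "")
  if (first_m) paste0("M", body) else body
}

# annotated data.frame built directly from coordinates against a db
annotated_from_coords <- function(db, accession, start, end,
                                  dataset_id = "DS1", prsm = NA_integer_) {
  rec <- data.frame(dataset_id = dataset_id, accession = accession,
                    sequence = substr(db$sequences[accession], start, end),
                    proforma = NA_character_,
                    prsm_count = as.integer(prsm),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  annotate_proteoforms(rec, db)
}

quiet <- function(expr) suppressMessages(expr)
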