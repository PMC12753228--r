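# reading identification lists, ProForma stripping, canonical databases,
# and the record-filtering rules

test_that("strip_proforma removes tags, keeps residues, and is idempotent", {
  expect_identical(strip_proforma("M[Acetyl]AGTK"), "MAGTK")
  expect_identical(strip_proforma("AGTK"), "AGTK")
  expect_identical(strip_proforma("[+42.0106]-MAGTK[Oxidation]"), "MAGTK")
  expect_identical(strip_proforma("M[a[nested]tag]AGTK(+15.99)"), "MAGTK")

  # independent character-level reference parser: delete bracketed stretches,
  # then keep letters only
  ref_strip <- function(s) {
    out <- character(0)
    depth <- 0L
    for (ch in strsplit(s, "")[[1]]) {
      if (ch %in% c("[", "(")) depth <- depth + 1L
      else if (ch %in% c("]", ")")) depth <- depth - 1L
      else if (depth == 0L && grepl("[A-Za-z]", ch)) out <- c(out, ch)
    }
    toupper(paste(out, collapse = ""))
  }
  set.seed(4)
  for (i in 1:25) {
    bare <- random_protein(sample(5:20, 1))
    pos <- sort(sample(nchar(bare), 2))
    dec <- paste0(substr(bare, 1, pos[1]), "[Mod", i, "]",
                  substr(bare, pos[1] + 1, pos[2]), "(+", i, ".01)",
                  substr(bare, pos[2] + 1, nchar(bare)))
    got <- strip_proforma(dec)
    expect_identical(got, ref_strip(dec))
    expect_identical(got, bare)
    expect_identical(strip_proforma(got), got)        # idempotent
    expect_lte(nchar(got), nchar(dec))                # length non-increasing
  }
  expect_error(strip_proforma("M[AcetylAGTK"), "unbalanced")
  expect_error(strip_proforma("MAG]TK"), "unbalanced")
})

test_that("proteoform tables are read, filtered, and round-trip the canonical dialect", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Accession\tSequence",
               "P1\tMADPK",
               "P2\tAGTK",
               "P3\tMMK"), p)
  rec <- read_proteoform_table(p, "DS1",
                               dialect = list(accession = "Accession",
                                              sequence = "Sequence"))
  expect_identical(nrow(rec), 3L)
  expect_true(all(is.na(rec$prsm_count)))
  expect_identical(attr(rec, "n_dropped"), 0L)

  # a row with an empty sequence cell is dropped and counted
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Accession\tSequence", "P1\tMADPK", "P2\t"), p2)
  rec2 <- quiet(read_proteoform_table(p2, "DS1",
                                      dialect = list(accession = "Accession",
                                                     sequence = "Sequence")))
  expect_identical(nrow(rec2), 1L)
  expect_identical(attr(rec2, "n_dropped"), 1L)

  # all optional fields carried through and round-tripped field-for-field
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tproforma\t#PrSMs\tstart\tend",
               "P1\tM[Acetyl]ADPK\t12\t1\t5",
               "sp|P2|NAME\tAGTK\t3\t4\t7"), p3)
  rec3 <- read_proteoform_table(p3, "DS2",
                                dialect = list(accession = "accession",
                                               proforma = "proforma",
                                               prsm_count = "#PrSMs",
                                               start = "start", end = "end"))
  expect_identical(rec3$sequence, c("MADPK", "AGTK"))
  expect_identical(rec3$accession, c("P1", "P2"))   # pipe style normalized
  expect_identical(rec3$prsm_count, c(12L, 3L))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_proteoform_table(rec3, out)
  back <- read_proteoform_table(out, "DS2")
  back$dataset_id <- rec3$dataset_id
  attr(rec3, "n_dropped") <- attr(back, "n_dropped")
  expect_equal(back, rec3, ignore_attr = TRUE)

  expect_error(read_proteoform_table(p, "DS1",
                                     dialect = list(sequence = "Sequence")),
               "accession")
  expect_error(read_proteoform_table(p, "DS1",
                                     dialect = list(accession = "Accession",
                                                    sequence = "Missing")),
               "Missing")
  expect_error(read_proteoform_table(file.path(tempdir(), "nope.tsv"), "x"),
               "cannot read")
})

uniprot_xml <- function(entries) {
  paste0('<uniprot xmlns="http://uniprot.org/uniprot">',
         paste(entries, collapse = ""), "</uniprot>")
}

xml_entry <- function(acc, seq, features = "") {
  paste0("<entry><accession>", acc, "</accession>", features,
         '<sequence length="', nchar(seq), '">', seq, "</sequence></entry>")
}

xml_feature <- function(type, begin, end) {
  paste0('<feature type="', type, '"><location><begin position="', begin,
         '"/><end position="', end, '"/></location></feature>')
}

test_that("canonical databases load from FASTA and UniProt-style XML", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|Q00001|ONE test protein", "MADPKGVR",
               ">Q00002", "MAGAGAK"), fa)
  db <- read_canonical_db(fasta_path = fa)
  expect_identical(sort(names(db$sequences)), c("Q00001", "Q00002"))
  expect_identical(nrow(db$features), 0L)

  xp <- withr::local_tempfile(fileext = ".xml")
  writeLines(uniprot_xml(c(
    xml_entry("Q00003", paste0("MAEQ", strrep("LV", 10)),
              paste0(xml_feature("signal peptide", 1, 17),
                     xml_feature("helix", 2, 5),            # out-of-scope type
                     xml_feature("chain", 18, 24))),
    xml_entry("Q00002", "MAGAGAR",                           # conflicts with FASTA
              xml_feature("domain", 2, 90))                  # beyond length
  )), xp)
  expect_warning(quiet(read_canonical_db(fasta_path = fa, xml_path = xp)),
                 "outside sequence bounds")
  db2 <- quiet(suppressWarnings(read_canonical_db(fasta_path = fa,
                                                  xml_path = xp)))
  expect_identical(db2$sequences[["Q00002"]], "MAGAGAR")      # XML wins
  sig <- db2$features[db2$features$category == "signal_peptide", ]
  expect_identical(c(sig$begin, sig$end), c(1L, 17L))
  expect_false("helix" %in% db2$features$category)
  expect_false(any(db2$features$end > nchar(db2$sequences[db2$features$accession])))

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<uniprot><entry>", bad)
  expect_error(read_canonical_db(xml_path = bad), "malformed XML")
  expect_error(read_canonical_db(), "at least one")
})

test_that("link_and_filter removes unknown accessions and sequence mismatches", {
  db <- toy_db()
  rec <- data.frame(dataset_id = "DS1",
                    accession = c("P1", "P1", "P2", "PX", "P3"),
                    sequence = c("ADPK", "MADPKGVR", "GAGA", "MMM", "QQQ"),
                    proforma = NA, prsm_count = NA_integer_,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  lf <- quiet(link_and_filter(rec, db))
  expect_identical(lf$report$unknown_accession, 1L)
  expect_identical(lf$report$no_match, 1L)
  expect_identical(nrow(lf$records), 3L)
  # subset + count conservation
  expect_true(all(paste(lf$records$accession, lf$records$sequence) %in%
                    paste(rec$accession, rec$sequence)))
  expect_identical(lf$report$n_input,
                   lf$report$n_retained + lf$report$unknown_accession +
                     lf$report$no_match)
  # identity on fully valid input
  lf2 <- link_and_filter(lf$records, db)
  expect_identical(lf2$records, lf$records)
  expect_identical(lf2$report$unknown_accession + lf2$report$no_match, 0L)
})

test_that("protein_db validates sequences and feature bounds", {
  expect_error(protein_db(c(A = "MAZ1")), "alphabet")
  expect_error(protein_db(c(A = "MADP"),
                          features = data.frame(accession = "A",
                                                category = "chain",
                                                begin = 1L, end = 9L)),
               "within")
  db <- protein_db(c(A = "MADP"), abundance = c(A = 2))
  expect_s3_class(db, "papt_db")
  expect_identical(db$abundance[["A"]], 2)
})
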