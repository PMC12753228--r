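# truncation sites, bond background, normalized frequencies, summaries

test_that("truncation sites flank the broken bonds; Met excision emits none", {
  db <- toy_db()
  a <- annotated_from_coords(db, c("P1", "P1", "P1"),
                             start = c(4L, 2L, 1L), end = c(6L, 8L, 5L))
  s <- extract_truncation_sites(a, db)
  # "PKG" (4-6): N site D|P and C site G|V
  expect_equal(s[s$terminus == "N", c("x", "x_prime")],
               data.frame(x = "D", x_prime = "P"), ignore_attr = TRUE)
  cs <- s[s$terminus == "C", c("x", "x_prime")]
  expect_setequal(paste(cs$x, cs$x_prime), c("G V", "K G"))
  # "ADPKGVR" (2-8) is Met excision + canonical C: nothing
  expect_identical(nrow(s), 3L)
})

test_that("peptide-bond counting matches the n-1 closed form", {
  one <- count_peptide_bonds(data.frame(sequence = "MAD"))
  expect_identical(attr(one, "total"), 2L)
  expect_identical(one["M", "A"], 1L)
  expect_identical(one["A", "D"], 1L)
  two <- count_peptide_bonds(data.frame(sequence = c("MAD", "AD")))
  expect_identical(two["A", "D"], 2L)
  expect_identical(attr(two, "total"), 3L)
  set.seed(31)
  seqs <- vapply(sample(5:60, 100, replace = TRUE), random_protein, "")
  m <- count_peptide_bonds(data.frame(sequence = seqs))
  expect_identical(attr(m, "total"), sum(nchar(seqs)) - 100L)
})

test_that("event counting respects scope and conserves totals", {
  db <- toy_db()
  a <- annotated_from_coords(db, c("P1", "P1", "P1"),
                             start = c(4L, 2L, 1L), end = c(6L, 8L, 5L))
  s <- extract_truncation_sites(a, db)
  comb <- count_truncation_events(s, "combined")
  expect_identical(comb["D", "P"], 1L)
  expect_identical(comb["G", "V"], 1L)
  expect_identical(comb["K", "G"], 1L)
  n_only <- count_truncation_events(s, "N_only")
  c_only <- count_truncation_events(s, "C_only")
  expect_identical(n_only["D", "P"], 1L)
  expect_identical(attr(n_only, "total"), 1L)
  expect_identical(attr(comb, "total"),
                   attr(n_only, "total") + attr(c_only, "total"))
  # conservation against the state calls
  expect_identical(attr(n_only, "total"),
                   sum(a$state %in% c("N_TRUNC", "NC_TRUNC")))
  expect_identical(attr(c_only, "total"),
                   sum(a$state %in% c("C_TRUNC", "NC_TRUNC")))
})

# helper: a site table with `n` events of pair (x, xp) and filler events
sites_of <- function(pairs) {
  data.frame(dataset_id = "D", accession = "A", terminus = "N",
             x = pairs[, 1], x_prime = pairs[, 2], position = 2L,
             stringsAsFactors = FALSE)
}

test_that("normalized frequency reproduces the worked ratio and its invariances", {
  # truncations: D|P twice out of 10; bonds: D|P 5 of 100
  tr <- count_truncation_events(sites_of(cbind(
    c(rep("D", 2), rep("A", 8)), c(rep("P", 2), rep("C", 8)))))
  bn <- count_peptide_bonds(data.frame(sequence = c(
    strrep("DP", 5),                      # 5 D|P bonds + 4 P|D bonds
    paste0("M", strrep("AC", 45), "A")))) # 91 bonds, none D|P
  expect_identical(unclass(tr)["D", "P"], 2L)
  expect_identical(attr(tr, "total"), 10L)
  expect_identical(unclass(bn)["D", "P"], 5L)
  expect_identical(attr(bn, "total"), 100L)
  nf <- normalized_frequency(tr, bn)
  expect_identical(nf["D", "P"], 2)                       # log2(0.2 / 0.05)
  expect_true(is.na(nf["W", "W"]))                        # zero count: missing
  expect_identical(attr(nf, "log_base"), 2)

  # truncations exactly proportional to bonds -> all non-missing cells 0
  tr2 <- count_truncation_events(sites_of(cbind(c("M", "A"), c("A", "D"))))
  bn2 <- count_peptide_bonds(data.frame(sequence = "MAD"))
  nf2 <- normalized_frequency(tr2, bn2)
  expect_true(all(nf2[!is.na(nf2)] == 0))

  # scale invariance: multiplying both matrices by 7 changes nothing
  tr7 <- count_truncation_events(sites_of(cbind(
    rep(c(rep("D", 2), rep("A", 8)), 7), rep(c(rep("P", 2), rep("C", 8)), 7))))
  bn7 <- count_peptide_bonds(data.frame(sequence = rep(c(
    strrep("DP", 5), paste0("M", strrep("AC", 45), "A")), 7)))
  expect_equal(normalized_frequency(tr7, bn7), nf)
  expect_error(normalized_frequency(tr, count_peptide_bonds(
    data.frame(sequence = "A"))), "non-zero")
})

test_that("state and protein-level summaries match an independent groupby", {
  db <- toy_db()
  a <- annotated_from_coords(db, rep("P1", 4),
                             start = c(1L, 2L, 3L, 3L), end = c(8L, 8L, 8L, 8L))
  s <- dataset_state_summary(a)
  expect_equal(unname(s$state_proportions[c("FULL_LENGTH", "N_TRUNC")]),
               c(0.5, 0.5))
  expect_equal(unname(s$protein_level["both"]), 1)
  expect_equal(sum(s$state_proportions), 1)
  expect_equal(sum(s$protein_level), 1)

  a2 <- annotated_from_coords(db, c("P1", "P2"), start = c(1L, 1L),
                              end = c(8L, 7L))
  s2 <- dataset_state_summary(a2)
  expect_equal(unname(s2$protein_level["only_full_length"]), 1)

  # random annotated table vs an aggregate() oracle
  set.seed(41)
  cfg <- sim_config(seed = 42, n_proteins = 40, n_proteoforms = 400)
  dbs <- generate_proteome(cfg)
  aa <- annotate_proteoforms(generate_dataset(dbs, cfg, "d")$records, dbs)
  got <- dataset_state_summary(aa)
  ref_states <- vapply(levels(aa$state),
                       function(st) mean(aa$state == st), 0)
  expect_equal(got$state_proportions[names(ref_states)], ref_states)
  agg <- aggregate(state ~ accession, aa,
                   function(x) c(fl = any(x == "FULL_LENGTH"),
                                 tr = any(x != "FULL_LENGTH")))
  ref_both <- mean(agg$state[, "fl"] & agg$state[, "tr"])
  expect_equal(unname(got$protein_level["both"]), ref_both)
  expect_error(dataset_state_summary(aa[0, ]), "empty")
})

test_that("PrSM means divide totals by group sizes", {
  db <- toy_db()
  a <- annotated_from_coords(db, rep("P1", 7),
                             start = c(1L, 2L, 3L, 3L, 4L, 4L, 5L),
                             end = rep(8L, 7),
                             prsm = c(30L, 60L, 1L, 2L, 3L, 2L, 2L))
  m <- prsm_state_summary(a)
  expect_equal(unname(m["full_length"]), 45)
  expect_equal(unname(m["truncated"]), 2)
  # single group present: the other is undefined
  a2 <- a[a$state == "FULL_LENGTH", ]
  m2 <- prsm_state_summary(a2)
  expect_true(is.na(m2["truncated"]))
  # no PrSM information at all
  a$prsm_count <- NA_integer_
  m3 <- prsm_state_summary(a)
  expect_false(attr(m3, "defined"))
})

test_that("known-in-database fractions follow the annotation-matching rules", {
  db <- protein_db(
    c(S1 = paste0("M", random_protein(99, first_m = FALSE))),
    features = data.frame(accession = "S1", category = "signal_peptide",
                          begin = 1L, end = 17L, stringsAsFactors = FALSE))
  a <- annotated_from_coords(db, rep("S1", 3),
                             start = c(18L, 40L, 18L), end = c(100L, 100L, 90L))
  kf <- known_in_uniprot_fraction(a, db)
  expect_equal(unname(kf["N_TRUNC"]), 0.5)   # start 18 known, start 40 not
  expect_equal(unname(kf["NC_TRUNC"]), 0)    # N matches but C at 90 does not
})

test_that("proline ratio and terminus histograms are plain counts", {
  s <- data.frame(terminus = c(rep("N", 40), rep("C", 15)),
                  x = "A",
                  x_prime = c(rep("P", 30), rep("G", 10),
                              rep("P", 10), rep("G", 5)),
                  stringsAsFactors = FALSE)
  expect_equal(proline_insource_ratio(s), 3)
  s0 <- s[s$terminus == "N", ]
  r0 <- proline_insource_ratio(s0)
  expect_true(is.na(r0))
  expect_identical(attr(r0, "numerator"), 30L)

  db <- toy_db()
  a <- annotated_from_coords(db, c("P1", "P1", "P1"),
                             start = c(1L, 2L, 3L), end = c(8L, 8L, 8L))
  h <- terminus_position_histograms(a)
  expect_equal(as.vector(h$n_position[c("1", "2", "3")]), c(1, 1, 1))
  expect_equal(as.vector(h$c_offset["0"]), 3)
})

test_that("length bins label [kw, (k+1)w) ranges and fractions sum to 1", {
  db <- protein_db(c(L1 = paste0("M", random_protein(129, first_m = FALSE))))
  a <- annotated_from_coords(db, "L1", 1L, 130L)
  lb <- length_bin_state_proportions(a)
  expect_identical(rownames(lb), "125-150")
  expect_equal(unname(lb["125-150", "FULL_LENGTH"]), 1)
  cfg <- sim_config(seed = 5, n_proteins = 50, n_proteoforms = 500)
  dbs <- generate_proteome(cfg)
  aa <- annotate_proteoforms(generate_dataset(dbs, cfg, "d")$records, dbs)
  lb2 <- length_bin_state_proportions(aa)
  expect_equal(unname(rowSums(lb2)), rep(1, nrow(lb2)))
})

test_that("abundance correlation is the OLS R-squared on the intersection", {
  ab <- setNames(10^seq(1, 4, length.out = 20), paste0("P", 1:20))
  counts <- setNames(2 * log10(ab) + 1, names(ab))
  r2 <- suppressWarnings(abundance_truncation_correlation(counts, ab))
  expect_equal(as.numeric(r2), 1)
  expect_identical(attr(r2, "n"), 20L)
  set.seed(51)
  ab2 <- setNames(rlnorm(1000, 3, 1), paste0("Q", 1:1000))
  counts2 <- setNames(rpois(1000, 5), names(ab2))
  expect_lt(as.numeric(abundance_truncation_correlation(counts2, ab2)), 0.02)
  expect_true(is.na(abundance_truncation_correlation(counts2[1:2], ab2)))
})
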