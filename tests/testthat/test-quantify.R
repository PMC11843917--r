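test_that("contaminant/decoy filtering reports counts by reason", {
  n <- 30
  flags_con <- c(rep(TRUE, 9), rep(FALSE, n - 9))
  flags_rev <- c(rep(FALSE, 9), rep(TRUE, 14), rep(FALSE, n - 23))
  pg <- make_pg(sprintf("P%02d", 1:n), sprintf("Protein %02d", 1:n),
                samples = "s1", intensity = rep(1, n),
                is_contaminant = flags_con, is_reverse = flags_rev)
  out <- filter_decoys_contaminants(pg)
  expect_equal(out$report$n_removed[out$report$reason == "contaminants"], 9)
  expect_equal(out$report$n_removed[out$report$reason == "false_positives"], 14)
  expect_equal(nrow(out$kept), n - 23)

  # unflagged table passes through unchanged
  clean <- make_pg("P1", "A", "s1", 1)
  expect_equal(nrow(filter_decoys_contaminants(clean)$kept), 1)

  # double-flagged rows are removed once, counted as contaminant
  both <- make_pg("P1", "A", "s1", 1,
                  is_contaminant = TRUE, is_reverse = TRUE)
  rep2 <- filter_decoys_contaminants(both)$report
  expect_equal(rep2$n_removed, c(1, 0))
})

test_that("fragment classes follow the name structure of the dataset", {
  pg <- make_pg(c("P1", "P2", "P3"),
                c("Catalase (Fragment)", "Catalase", "Aldolase (Fragment)"),
                samples = "s1", intensity = c(1, 1, 1))
  marked <- mark_fragment_groups(pg)
  expect_identical(marked$fragment_class,
                   c("fragment_with_same_name_full", "full",
                     "fragment_orphan"))
  expect_identical(marked$working_name,
                   c("Catalase*", "Catalase", "Aldolase*"))
})

test_that("fragment iBAQ recalculation divides intensity by TP_max", {
  expect_equal(recalc_fragment_ibaq(1000, 10), 100)
  expect_true(is.na(recalc_fragment_ibaq(NA_real_, 10)))
  expect_error(recalc_fragment_ibaq(10, 0), "invalid resolution")
  # linearity: scaling intensities scales iBAQ_rec
  x <- c(10, 20, NA)
  expect_equal(recalc_fragment_ibaq(3 * x, 7), 3 * recalc_fragment_ibaq(x, 7))
})

test_that("TP_max resolution follows in_group, in_dataset, surrogate order", {
  fasta <- tibble::tibble(
    accession = c("F1", "FULL1", "F2", "FULL2", "F3"),
    desc = c("Catalase (Fragment)", "Catalase", "Aldolase (Fragment)",
             "Aldolase", "Enolase (Fragment)"),
    sequence = c(random_protein(100, seed = 1), random_protein(400, seed = 2),
                 random_protein(80, seed = 3), random_protein(350, seed = 4),
                 random_protein(90, seed = 5))
  )
  pg <- make_pg(c("F1", "F2", "FULL2", "F3"),
                c("Catalase (Fragment)", "Aldolase (Fragment)", "Aldolase",
                  "Enolase (Fragment)"),
                samples = "s1", intensity = c(1, 1, 1, 1),
                members = c("F1;FULL1", "F2", "FULL2", "F3"))
  pg <- mark_fragment_groups(pg)

  r1 <- resolve_tp_max("F1", pg, fasta)
  expect_identical(r1$source, "in_group")
  expect_identical(r1$tp_max, count_theoretical_peptides(fasta$sequence[2]))

  r2 <- resolve_tp_max("F2", pg, fasta)
  expect_identical(r2$source, "in_dataset")
  expect_identical(r2$tp_max, count_theoretical_peptides(fasta$sequence[4]))

  surr_seq <- random_protein(500, seed = 6)
  surr <- tibble::tibble(accession = "F3", surrogate_accession = "BLAST1",
                         sequence = surr_seq)
  r3 <- resolve_tp_max("F3", pg, fasta, surr)
  expect_identical(r3$source, "surrogate")
  expect_identical(r3$tp_max, count_theoretical_peptides(surr_seq))
  expect_equal(r3$mw_used_kda, sequence_mw_kda(surr_seq))

  expect_error(resolve_tp_max("F3", pg, fasta), "unresolved fragment")
})

test_that("recalculated iBAQ on generated fragments matches ground truth", {
  pr <- generate_proteome(60, fragment_rate = 0.2, isoform_rate = 0,
                          seed = 21)
  pg <- generate_protein_groups(pr$truth, crude_design(), cv = 0.1,
                                seed = 22)
  marked <- mark_fragment_groups(pg)
  fasta <- tibble::tibble(accession = pr$truth$proteins$accession,
                          desc = pr$truth$proteins$name,
                          sequence = pr$truth$proteins$sequence)
  rec <- apply_fragment_recalc(marked, fasta)
  expect_gt(nrow(rec$resolutions), 0)
  for (k in seq_len(nrow(rec$resolutions))) {
    acc <- rec$resolutions$accession[k]
    row <- which(rec$pg$lead_accession == acc)
    intens <- as.numeric(rec$pg[row, paste0("intensity.", pg_samples(pg))])
    got <- as.numeric(rec$pg[row, paste0("ibaq.", pg_samples(pg))])
    expect_equal(got, intens / rec$resolutions$tp_max[k])
  }
})

test_that("riBAQ normalizes each sample to molar fractions", {
  m <- matrix(c(3, 1, 5, NA), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  rb <- compute_ribaq(m)
  expect_equal(rb[, "s1"], c(a = 0.75, b = 0.25))
  expect_equal(rb["a", "s2"], 1)
  expect_true(is.na(rb["b", "s2"]))
  bad <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "empty"))
  expect_error(compute_ribaq(bad), "empty")
})

test_that("TriBAQ is mean riBAQ over fractions and sums to one", {
  rb <- matrix(0.1, 1, 15, dimnames = list("p", paste0("F", 1:15)))
  expect_equal(unname(compute_tribaq(rb)), 0.1)
  one <- matrix(c(0.15, rep(NA, 14)), 1, 15,
                dimnames = list("p", paste0("F", 1:15)))
  expect_equal(unname(compute_tribaq(one)), 0.01)
})

test_that("isoform merging sums shares and conserves sample totals", {
  rb <- matrix(c(0.02, 0.03, 0.95, 0.5, NA, 0.5), 3, 2,
               dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  merged <- combine_isoforms(rb, c("Superoxide dismutase",
                                   "Superoxide dismutase", "Other"))
  expect_equal(merged["Superoxide dismutase (2)", "s1"], 0.05)
  expect_equal(merged["Other (1)", "s1"], 0.95)
  expect_equal(colSums(merged, na.rm = TRUE), colSums(rb, na.rm = TRUE))
  # fragment-marked names never merge with unmarked
  m2 <- combine_isoforms(rb, c("Catalase", "Catalase*", "Catalase"))
  expect_setequal(rownames(m2), c("Catalase (2)", "Catalase* (1)"))
})

test_that("abundance filter modes match a brute-force threshold scan", {
  set.seed(31)
  rb <- matrix(runif(200, 0, 0.05), 20, 10,
               dimnames = list(sprintf("p%02d", 1:20), paste0("F", 1:10)))
  rb <- sweep(rb, 2, colSums(rb), "/")
  tb <- compute_tribaq(rb)
  mx <- apply(rb, 1, max)
  expect_setequal(abundance_filter(rb, "global"), names(tb)[tb > 0.005])
  expect_setequal(abundance_filter(rb, "fractional"), names(mx)[mx > 0.02])
  expect_setequal(abundance_filter(rb, "shortlist"),
                  names(tb)[tb > 0.005 | mx > 0.01])
  # boundary cases from the definitions
  rb2 <- matrix(c(0.006, 0.004), 1, 2, dimnames = list("x", c("F1", "F2")))
  tb2 <- c(x = 0.006)
  expect_identical(abundance_filter(rb2, "global", tb2), "x")
  expect_identical(abundance_filter(rb2, "fractional", tb2), character(0))
  expect_identical(abundance_filter(rb2, "shortlist", tb2), "x")
})

test_that("riBAQ rank order tracks true abundance in the noise-free limit", {
  pr <- generate_proteome(40, isoform_rate = 0, fragment_rate = 0, seed = 41)
  pg <- generate_protein_groups(pr$truth, crude_design(), cv = 0, seed = 42)
  rb <- compute_ribaq(pg_matrix(pg, "ibaq"))
  for (s in pg_samples(pg)) {
    expect_identical(order(rb[, s]), order(pr$truth$proteins$true_abundance))
  }
})
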