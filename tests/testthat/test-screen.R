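test_that("GO/keyword prediction matches ids and substrings", {
  proteins <- tibble::tibble(protein = c("A", "B", "C", "D"),
                             accessions = c("P1", "P2", "P3", "P4"))
  ann <- tibble::tibble(
    accession = c("P1", "P2", "P3"),
    go_ids = c("GO:0006979", "", ""),
    keywords = c("", "Oxidoreductase activity, acting on peroxide",
                 "DNA binding")
  )
  hit <- go_keyword_filter(proteins, ann)
  # GO id match, case-insensitive keyword substring; no-annotation fails
  expect_setequal(hit$protein, c("A", "B"))
})

test_that("cross-reference retains only crude-identified accessions", {
  proteins <- tibble::tibble(protein = c("A", "B"),
                             accessions = c("P1;P9", "P2"))
  kept <- cross_reference_filter(proteins, c("P9", "P7"))
  expect_identical(kept$protein, "A")
  expect_warning(out <- cross_reference_filter(proteins, character()),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("confidence filter applies score and 2-of-3 replicate rules", {
  juice <- paste0("juice_", 1:3)
  pg <- make_pg(c("P1", "P2", "P3"), c("A", "B", "C"), juice,
                intensity = matrix(1, 3, 3),
                msms = matrix(c(2, 2, 0,  0, 0, 1,  2, 2, 2), 3, 3,
                              byrow = TRUE),
                coverage = matrix(c(10, 8, 1,  2, 1, 1,  9, 9, 9), 3, 3,
                                  byrow = TRUE),
                unique_peptides = matrix(c(3, 2, 0,  1, 1, 1,  4, 4, 4),
                                         3, 3, byrow = TRUE),
                score = c(50, 39, 39))
  res <- confidence_filter(pg, juice)
  # P1: 4/4; P2: 0/4; P3: 3/4 (score fails) -> "at least three" boundary
  expect_identical(res$n_met, c(4, 0, 3))
  expect_identical(res$pass, c(TRUE, FALSE, TRUE))
  expect_error(confidence_filter(pg, juice[1:2]), "3 juice replicates")
})

test_that("screen stages are monotone, idempotent and order-insensitive", {
  set.seed(91)
  n <- 40
  proteins <- tibble::tibble(protein = sprintf("N%02d", 1:n),
                             accessions = sprintf("P%02d", 1:n))
  ann <- tibble::tibble(
    accession = sample(proteins$accessions, 25),
    go_ids = sample(c("GO:0006979", "GO:0000001"), 25, replace = TRUE),
    keywords = ""
  )
  crude <- sample(proteins$accessions, 30)
  g1 <- go_keyword_filter(proteins, ann)
  expect_true(all(g1$protein %in% proteins$protein))
  expect_identical(go_keyword_filter(g1, ann), g1)
  x1 <- cross_reference_filter(g1, crude)
  expect_true(all(x1$protein %in% g1$protein))
  expect_identical(cross_reference_filter(x1, crude), x1)
  # order of the two per-protein predicates does not matter
  other_order <- go_keyword_filter(cross_reference_filter(proteins, crude),
                                   ann)
  expect_setequal(x1$protein, other_order$protein)
})

test_that("run_screen bookkeeping matches a planted fixture", {
  n_go <- 20; n_other <- 10
  acc <- sprintf("P%03d", 1:(n_go + n_other))
  proteins <- tibble::tibble(protein = paste("Protein", acc),
                             accessions = acc)
  ann <- tibble::tibble(accession = acc[1:n_go], go_ids = "GO:0006979",
                        keywords = "")
  crude <- acc[1:15]                     # 5 GO-positives not in crude
  conf_fail <- acc[1:4]                  # 4 low-confidence
  juice <- paste0("juice_", 1:3)
  low <- matrix(rep(ifelse(acc %in% conf_fail, 0, 5), 3), length(acc), 3)
  pg <- make_pg(acc, proteins$protein, juice,
                intensity = matrix(10, length(acc), 3),
                msms = low, unique_peptides = low,
                coverage = low * 10,
                score = ifelse(acc %in% conf_fail, 5, 100))
  abundant <- acc[7:12]
  rb <- matrix(1e-4, length(acc), 5,
               dimnames = list(proteins$protein, paste0("F", 1:5)))
  rb[proteins$protein[acc %in% abundant], 1] <- 0.05
  out <- run_screen(proteins, rb, ann, crude, pg, juice)
  expect_identical(out$funnel$n_remaining,
                   c(30L, 20L, 15L, 11L, length(7:12)))
  expect_setequal(out$result$protein[out$result$shortlisted],
                  paste("Protein", abundant))
  # degenerate threshold: requiring 0 criteria makes the stage an identity
  out0 <- run_screen(proteins, rb, ann, crude, pg, juice,
                     criteria = screen_criteria(criteria_required = 0L))
  expect_identical(out0$funnel$n_remaining[4], out0$funnel$n_remaining[3])
})

test_that("loosening any single threshold never shrinks the shortlist", {
  set.seed(92)
  n <- 30
  acc <- sprintf("P%03d", 1:n)
  proteins <- tibble::tibble(protein = paste("Prot", acc), accessions = acc)
  ann <- tibble::tibble(accession = sample(acc, 20), go_ids = "GO:0006979",
                        keywords = "")
  crude <- sample(acc, 22)
  juice <- paste0("juice_", 1:3)
  pg <- make_pg(acc, proteins$protein, juice,
                intensity = matrix(10, n, 3),
                msms = matrix(sample(0:3, n * 3, TRUE), n, 3),
                coverage = matrix(sample(0:20, n * 3, TRUE), n, 3),
                unique_peptides = matrix(sample(0:4, n * 3, TRUE), n, 3),
                score = sample(20:120, n, TRUE))
  rb <- matrix(runif(n * 5, 0, 0.02), n, 5,
               dimnames = list(proteins$protein, paste0("F", 1:5)))
  base <- screen_criteria()
  shortlist <- function(crit)
    sum(run_screen(proteins, rb, ann, crude, pg, juice, crit)$result$shortlisted)
  n0 <- shortlist(base)
  looser <- list(screen_criteria(score_min = 10),
                 screen_criteria(coverage_min_pct = 1),
                 screen_criteria(unique_peptides_min = 1L),
                 screen_criteria(criteria_required = 2L),
                 screen_criteria(tribaq_min = 0.001),
                 screen_criteria(ribaq_any_min = 0.001))
  for (crit in looser) expect_gte(shortlist(crit), n0)
})
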