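mk_list <- function(ids, dirs, cohort, level = "pathway")
  marker_list(ids, dirs, cohort = cohort, level = level)

test_that("complete and incomplete matches classify by id and direction", {
  a <- mk_list(c("Ras Pathway (CDC42 Signaling)",
                 "ATM Pathway (Checkpoint Control)",
                 "EGF Pathway (Cell Survival)"),
               c("up", "up", "down"), "pediatric")
  b <- mk_list(c("Ras Pathway (CDC42 Signaling)",
                 "ATM Pathway (Checkpoint Control)",
                 "EGF Pathway (IP3 Signaling)"),
               c("up", "down", "down"), "adult")
  rep <- match_markers(a, b)
  p <- rep$pairs
  expect_equal(p$category[p$feature_a == "Ras Pathway (CDC42 Signaling)"],
               "complete_concordant")
  expect_equal(p$category[p$feature_a == "ATM Pathway (Checkpoint Control)"],
               "complete_discordant")
  inc <- p[p$category == "incomplete_concordant", ]
  expect_equal(inc$root, "EGF Pathway")
  expect_equal(inc$feature_a, "EGF Pathway (Cell Survival)")
  expect_equal(inc$feature_b, "EGF Pathway (IP3 Signaling)")
  expect_length(rep$unmatched_a, 0)
  expect_length(rep$unmatched_b, 0)
})

test_that("complete matches exclude their features from incomplete matching", {
  a <- mk_list(c("P (x)", "P (y)"), c("up", "up"), "A")
  b <- mk_list(c("P (x)", "P (z)"), c("up", "down"), "B")
  rep <- match_markers(a, b)
  p <- rep$pairs
  # "P (x)" matches completely, so only (y, z) pairs under root P remain
  expect_equal(sum(p$category == "complete_concordant"), 1)
  inc <- p[startsWith(p$category, "incomplete"), ]
  expect_equal(nrow(inc), 1)
  expect_equal(inc$feature_a, "P (y)")
  expect_equal(inc$feature_b, "P (z)")
  expect_equal(inc$category, "incomplete_discordant")
})

test_that("gene-level matching has no incomplete category", {
  a <- mk_list(c("CAMK2B", "BID", "LIPE"), c("up", "up", "up"), "A", "gene")
  b <- mk_list(c("CAMK2B", "BID", "SAR1B"), c("up", "down", "up"), "B", "gene")
  rep <- match_markers(a, b)
  expect_equal(sort(unique(rep$pairs$category)),
               c("complete_concordant", "complete_discordant"))
  expect_equal(rep$unmatched_a, "LIPE")
  expect_equal(rep$unmatched_b, "SAR1B")
  expect_error(match_markers(a, mk_list("X", "up", "B", "pathway")),
               "different levels")
})

test_that("match summaries count a constructed fixture correctly", {
  # 2 complete-concordant, 1 complete-discordant, 1 incomplete pair
  a <- mk_list(c("Alpha Pathway (X)", "Beta Pathway", "Gamma Pathway (A)",
                 "Delta Pathway (M)"),
               c("up", "up", "up", "down"), "A")
  b <- mk_list(c("Alpha Pathway (X)", "Beta Pathway", "Gamma Pathway (B)",
                 "Delta Pathway (M)", "Omega Pathway"),
               c("up", "up", "up", "up", "down"), "B")
  s <- summarize_matches(match_markers(a, b))
  got <- setNames(s$n_pairs, s$category)
  expect_equal(unname(got[c("complete_concordant", "complete_discordant",
                            "incomplete_concordant", "incomplete_discordant")]),
               c(2, 1, 1, 0))
  expect_equal(unname(got["unmatched_b"]), 1)
  expect_equal(unname(got["unmatched_a"]), 0)
  # empty lists on one side leave every category at zero pairs
  empty_rep <- match_markers(mk_list("Zed Pathway", "up", "A"),
                             mk_list("Q Pathway", "down", "B"))
  s0 <- summarize_matches(empty_rep)
  expect_true(all(s0$n_pairs[1:4] == 0))
  # identical lists with identical directions are all complete-concordant
  same <- mk_list(c("P1", "P2"), c("up", "down"), "A")
  same_b <- mk_list(c("P1", "P2"), c("up", "down"), "B")
  s1 <- summarize_matches(match_markers(same, same_b))
  expect_equal(s1$n_pairs[s1$category == "complete_concordant"], 2)
})

test_that("matching is symmetric in the two cohorts", {
  set.seed(77)
  roots <- sprintf("R%02d Pathway", 1:8)
  branches <- c("(a)", "(b)", "(c)", "")
  mk_rand <- function(co) {
    ids <- unique(trimws(paste(sample(roots, 12, TRUE), sample(branches, 12, TRUE))))
    mk_list(ids, sample(c("up", "down"), length(ids), TRUE), co)
  }
  for (i in 1:10) {
    a <- mk_rand("A"); b <- mk_rand("B")
    sab <- summarize_matches(match_markers(a, b))
    sba <- summarize_matches(match_markers(b, a))
    expect_equal(sab$n_pairs[1:4], sba$n_pairs[1:4])
    expect_equal(sab$n_pairs[5], sba$n_pairs[6])  # unmatched swap sides
    expect_equal(sab$n_pairs[6], sba$n_pairs[5])
  }
})

test_that("every feature lands in exactly one accounting bucket per list", {
  set.seed(78)
  roots <- sprintf("R%02d Pathway", 1:6)
  branches <- c("(a)", "(b)", "")
  for (i in 1:10) {
    ids_a <- unique(trimws(paste(sample(roots, 10, TRUE), sample(branches, 10, TRUE))))
    ids_b <- unique(trimws(paste(sample(roots, 10, TRUE), sample(branches, 10, TRUE))))
    a <- mk_list(ids_a, sample(c("up", "down"), length(ids_a), TRUE), "A")
    b <- mk_list(ids_b, sample(c("up", "down"), length(ids_b), TRUE), "B")
    rep <- match_markers(a, b)
    p <- rep$pairs
    complete_a <- p$feature_a[startsWith(p$category, "complete")]
    contrib_a <- unique(p$feature_a[startsWith(p$category, "incomplete")])
    buckets <- list(complete_a, contrib_a, rep$unmatched_a)
    expect_setequal(unlist(buckets), ids_a)
    expect_equal(sum(lengths(buckets)), length(ids_a))  # disjoint
  }
})

test_that("adding a novel-root feature only changes unmatched counts", {
  a <- mk_list(c("P1 (x)", "P2"), c("up", "down"), "A")
  b <- mk_list(c("P1 (y)", "P2"), c("up", "up"), "B")
  base <- summarize_matches(match_markers(a, b))
  a2 <- mk_list(c("P1 (x)", "P2", "Brand New Pathway"),
                c("up", "down", "up"), "A")
  grown <- summarize_matches(match_markers(a2, b))
  expect_equal(grown$n_pairs[1:4], base$n_pairs[1:4])
  expect_equal(grown$n_pairs[grown$category == "unmatched_a"],
               base$n_pairs[base$category == "unmatched_a"] + 1)
})

test_that("match reports serialize to TSV", {
  a <- mk_list(c("P1", "P2 (a)"), c("up", "down"), "A")
  b <- mk_list(c("P1", "P2 (b)", "Q"), c("up", "up", "down"), "B")
  f <- tempfile(fileext = ".tsv")
  write_match_report(match_markers(a, b), f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_true(all(c("category", "root", "feature_a", "feature_b") %in% names(tab)))
  expect_equal(sum(tab$category == "complete_concordant"), 1)
  expect_equal(sum(tab$category == "unmatched_b"), 1)
})
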