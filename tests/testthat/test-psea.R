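# Weighted running-sum enrichment, permutation null, NES/FDR, leading edge.

ranked_1to5 <- function() {
  rank_proteins(data.frame(accession = paste0("P", 1:5), score = c(5, 4, 3, 2, 1)))
}

test_that("ranking is deterministic: score descending, ties by accession", {
  rl <- rank_proteins(data.frame(accession = c("B", "A", "C"),
                                 score = c(1, 1, 2)))
  expect_equal(rl$accession, c("C", "A", "B"))
  # duplicates collapse to the largest-magnitude score and are reported
  rl2 <- rank_proteins(data.frame(accession = c("A", "A", "B"),
                                  score = c(3, -5, 0)))
  expect_equal(rl2$score[rl2$accession == "A"], -5)
  expect_equal(attr(rl2, "duplicates"), "A")
  expect_error(rank_proteins(data.frame(accession = c("A", "B"),
                                        score = c(NaN, 1))), "A")
})

test_that("the running sum reproduces the worked example", {
  prof <- enrichment_score(ranked_1to5(), c("P1", "P3"), weight_p = 1)
  expect_equal(prof$values,
               c(5 / 8, 5 / 8 - 1 / 3, 5 / 8 - 1 / 3 + 3 / 8,
                 2 / 3 - 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(prof$es, 2 / 3, tolerance = 1e-12)
  expect_equal(prof$peak_index, 3L)
})

test_that("unweighted single-member sets reach the extremes", {
  prof <- enrichment_score(ranked_1to5(), "P1", weight_p = 0)
  expect_equal(prof$es, 1.0)
  expect_equal(prof$peak_index, 1L)
  prof <- enrichment_score(ranked_1to5(), "P5", weight_p = 0)
  expect_equal(prof$es, -1.0)
  expect_equal(prof$peak_index, 4L)
})

test_that("degenerate member sets are rejected", {
  rl <- ranked_1to5()
  expect_error(enrichment_score(rl, "NOPE"), "absent")
  expect_error(enrichment_score(rl, paste0("P", 1:5)), "equals list")
  rl0 <- rank_proteins(data.frame(accession = c("A", "B", "C"),
                                  score = c(0, 1, 2)))
  expect_error(enrichment_score(rl0, "A", weight_p = 1), "zero")
})

test_that("ES matches exact integer-arithmetic recomputation, ends at zero", {
  set.seed(41)
  for (rep in 1:200) {
    N <- sample(4:12, 1)
    scores <- sort(sample(-20:20, N), decreasing = TRUE)
    rl <- rank_proteins(data.frame(accession = sprintf("P%02d", 1:N),
                                   score = scores))
    nh <- sample(seq_len(N - 1), 1)
    members <- sample(rl$accession, nh)
    p <- sample(c(0, 1), 1)
    if (p == 1 && all(rl$score[rl$accession %in% members] == 0)) next
    prof <- enrichment_score(rl, members, weight_p = p)
    oracle <- es_oracle_exact(rl$score, rl$accession %in% members, p)
    expect_equal(prof$es, oracle$es, tolerance = 1e-12)
    expect_equal(prof$peak_index, oracle$peak_index)
    expect_lt(abs(prof$values[N]), 1e-9)
    expect_true(abs(prof$es) <= 1)
  }
})

test_that("at weight 0 the ES is the classical signed KS statistic", {
  set.seed(17)
  for (rep in 1:100) {
    N <- sample(5:20, 1)
    rl <- rank_proteins(data.frame(accession = sprintf("P%02d", 1:N),
                                   score = rnorm(N)))
    nh <- sample(seq_len(N - 1), 1)
    members <- sample(rl$accession, nh)
    prof <- enrichment_score(rl, members, weight_p = 0)
    expect_equal(prof$es, signed_ks_oracle(rl$accession %in% members),
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea reference implementation at weight 1", {
  set.seed(23)
  for (rep in 1:50) {
    N <- sample(10:40, 1)
    rl <- rank_proteins(data.frame(accession = sprintf("P%03d", 1:N),
                                   score = rnorm(N)))
    members <- sample(rl$accession, sample(2:(N - 2), 1))
    es_ref <- fgsea::calcGseaStat(rl$score,
                                  which(rl$accession %in% members),
                                  gseaParam = 1)
    expect_equal(enrichment_score(rl, members, 1)$es, es_ref,
                 tolerance = 1e-9)
  }
})

test_that("the permutation null is seeded and reproducible", {
  rl <- ranked_1to5()
  a <- permutation_null(rl, c("P1", "P3"), 1, n_perm = 50, seed = 99)
  b <- permutation_null(rl, c("P1", "P3"), 1, n_perm = 50, seed = 99)
  expect_identical(a, b)
  expect_length(a, 50)
  expect_error(permutation_null(rl, c("P1", "P3"), 1, n_perm = 0), ">= 1")
})

test_that("NES and nominal p follow the same-sign pseudo-count formulas", {
  r <- nes_and_pvalues(0.5, c(0.25, 0.25, -0.1))
  expect_equal(r$nes, 2.0)
  expect_equal(r$nominal_p, 1 / 3)
  r <- nes_and_pvalues(0.5, c(0.5, 0.5))
  expect_equal(r$nominal_p, 1.0)
  expect_warning(r <- nes_and_pvalues(-0.4, c(0.9, 0.9)), "same-sign")
  expect_true(is.na(r$nes))
  expect_equal(r$nominal_p, 1.0)
  expect_warning(r <- nes_and_pvalues(0, c(0.5)), "degenerate|0")
  expect_equal(r$nes, 0)
})

test_that("FDR q is the pooled-null ratio with monotone cleanup", {
  # single term: pooled null fraction 0.04, observed fraction 1
  pool <- c(rep(2, 4), rep(0.5, 96))
  expect_equal(compute_fdr(1.0, pool), 0.04)
  # |nes| above every pooled null -> q = 0
  expect_equal(compute_fdr(3.0, pool), 0)
  # monotone cleanup: the stronger term's q never exceeds the weaker's
  nes <- c(2.0, 1.2)
  pool2 <- c(rep(1.9, 50), rep(1.0, 50))   # raw q: strong 50/50=1? -> clip
  q <- compute_fdr(nes, pool2)
  expect_lte(q[1], q[2])
  expect_true(all(q >= 0 & q <= 1))
})

test_that("leading edge collects members up to (or from) the peak", {
  rl <- ranked_1to5()
  prof <- enrichment_score(rl, c("P1", "P3"), 1)
  expect_equal(leading_edge(rl, c("P1", "P3"), prof), c("P1", "P3"))
  prof <- enrichment_score(rl, "P5", 0)
  expect_equal(leading_edge(rl, "P5", prof), "P5")
  # positive ES with members after the peak: all members up to the peak
  prof <- enrichment_score(rl, c("P1", "P2"), 1)
  expect_equal(leading_edge(rl, c("P1", "P2"), prof), c("P1", "P2"))
})

test_that("run_psea is deterministic and ranks the planted term first", {
  cfg <- simulation_config(n_proteins = 100, n_terms = 5, prevalence = 0.25,
                           delta = 3, noise = 1, seed = 8)
  sim <- simulate_database(cfg)
  scored <- simulate_scored_list(sim$db, cfg)
  r1 <- run_psea(sim$db, scored, n_perm = 100, seed = 4)
  r2 <- run_psea(sim$db, scored, n_perm = 100, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$term[1], attr(scored, "truth")$enriched_term)
  expect_lt(r1$nominal_p[1], 0.05)
  # scrambling the input row order changes nothing
  r3 <- run_psea(sim$db, scored[sample(nrow(scored)), ], n_perm = 100, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r3))
  # leading edge is a subset of the term's listed members
  le <- strsplit(r1$leading_edge[1], ",")[[1]]
  expect_true(all(le %in% sim$db$term_index[[r1$term[1]]]))
  expect_true(length(le) >= 1)
})

test_that("a term covering the whole list is excluded with a warning", {
  sets <- lapply(1:10, function(i) "ALL")
  names(sets) <- sprintf("P%02d", 1:10)
  sets$P01 <- c("ALL", "SOME"); sets$P02 <- c("ALL", "SOME")
  sets$P03 <- c("ALL", "SOME"); sets$P04 <- c("ALL", "SOME")
  sets$P05 <- c("ALL", "SOME")
  db <- make_db(sets)
  scored <- data.frame(accession = sprintf("P%02d", 1:10), score = 10:1)
  expect_warning(res <- run_psea(db, scored, n_perm = 50, seed = 1,
                                 min_population_count = 2), "whole list")
  expect_false("ALL" %in% res$term)
  expect_true("SOME" %in% res$term)
})

test_that("consistent relabeling of accessions changes no statistic", {
  cfg <- simulation_config(n_proteins = 50, n_terms = 3, prevalence = 0.3,
                           delta = 2, noise = 1, seed = 12)
  sim <- simulate_database(cfg)
  scored <- simulate_scored_list(sim$db, cfg)
  r1 <- run_psea(sim$db, scored, n_perm = 50, seed = 2,
                 min_population_count = 3)
  # relabel P000xx -> Q000xx everywhere (preserves tie-break order)
  relabel <- function(x) sub("^P", "Q", x)
  db2 <- sim$db
  db2$accessions <- relabel(db2$accessions)
  names(db2$organisms) <- relabel(names(db2$organisms))
  names(db2$keywords) <- relabel(names(db2$keywords))
  names(db2$ptm_terms) <- relabel(names(db2$ptm_terms))
  db2$term_index <- lapply(db2$term_index, relabel)
  db2$organism_index <- lapply(db2$organism_index, relabel)
  scored2 <- scored
  scored2$accession <- relabel(scored2$accession)
  r2 <- run_psea(db2, scored2, n_perm = 50, seed = 2,
                 min_population_count = 3)
  expect_equal(r2$es, r1$es)
  expect_equal(r2$nes, r1$nes)
  expect_equal(r2$nominal_p, r1$nominal_p)
})
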