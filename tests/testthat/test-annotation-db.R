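# Flat-file parsing and the annotation database build rules.

test_that("flat-file records expose AC, OS, KW, and FT fields", {
  recs <- parse_flatfile_records(c(
    "AC   P99901; Q00001;",
    "OS   Homo sapiens (Human).",
    "KW   Phosphoprotein; Acetylation.",
    "FT   MOD_RES         15",
    'FT                   /note="Phosphothreonine; by AURKB"',
    "//"))
  r <- recs[[1]]
  expect_equal(r$accessions, c("P99901", "Q00001"))
  expect_equal(r$organism, "Homo sapiens (Human)")
  expect_setequal(r$keywords, c("Phosphoprotein", "Acetylation"))
  expect_equal(r$features$key, "MOD_RES")
  expect_equal(r$features$note, "Phosphothreonine; by AURKB")
})

test_that("multi-line FT notes are concatenated before extraction", {
  recs <- parse_flatfile_records(c(
    "AC   P1;", "OS   X.",
    "FT   CROSSLNK        48",
    'FT                   /note="Glycyl lysine isopeptide (Lys-Gly) (interchain',
    'FT                   with G-Cter in ubiquitin)"',
    "//"))
  expect_equal(recs[[1]]$features$note,
               "Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)")
})

test_that("structural errors are reported", {
  expect_error(parse_flatfile_records(c("OS   X.", "//")), "no AC")
  expect_error(parse_flatfile_records(c("AC   P1;", "OS   X.")), "unterminated")
  legacy <- c("AC   P1;", "OS   X.",
              "FT   MOD_RES      15     15       Phosphothreonine.", "//")
  expect_error(parse_flatfile_records(legacy), "columnar")
})

test_that("build rules combine KW-universe terms and FT note matches", {
  vocab <- parse_ptm_vocabulary(c(
    "ID   Phosphothreonine", "FT   MOD_RES", "TG   Threonine.",
    "MM   79.966331", "KW   Phosphothreonine.", "//",
    "ID   Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)",
    "FT   CROSSLNK", "TG   Lysine-Glycine.", "KW   Ubl conjugation.", "//"))
  recs <- parse_flatfile_records(c(
    "AC   P1;", "OS   Homo sapiens (Human).",
    "KW   Phosphoprotein; Reference proteome.",
    "FT   MOD_RES         15",
    'FT                   /note="Phosphothreonine; by AURKB"',
    "//",
    "AC   P2;", "OS   Homo sapiens (Human).",
    "KW   Reference proteome.",
    "//",
    "AC   P3;", "OS   Homo sapiens (Human).",
    "FT   CROSSLNK        48",
    'FT                   /note="Glycyl lysine isopeptide (Lys-Gly) (interchain with G-Cter in ubiquitin)"',
    "//"))
  db <- build_database(recs, vocab, ptm_keywords = "Phosphoprotein")
  expect_setequal(db$ptm_terms[["P1"]], c("Phosphoprotein", "Phosphothreonine"))
  # no PTM terms, but still part of the population
  expect_equal(db$ptm_terms[["P2"]], character())
  expect_true("P2" %in% db$accessions)
  # CROSSLNK note maps through the vocabulary to its parent keyword
  expect_equal(db$ptm_terms[["P3"]], "Ubl conjugation")
  # "Reference proteome" is not in the keyword universe
  expect_false("Reference proteome" %in% names(db$term_index))
})

test_that("FT note matching truncates at the first semicolon only", {
  vocab <- parse_ptm_vocabulary(make_vocab_lines("K1", ids = "Some mod"))
  recs <- parse_flatfile_records(c(
    "AC   P1;", "OS   X.",
    "FT   MOD_RES         1",
    'FT                   /note="Some mod; with evidence"', "//",
    "AC   P2;", "OS   X.",
    "FT   MOD_RES         1",
    'FT                   /note="some mod"', "//"))   # case mismatch: no hit
  db <- build_database(recs, vocab)
  expect_equal(db$ptm_terms[["P1"]], "K1")
  expect_equal(db$ptm_terms[["P2"]], character())
})

test_that("transpose consistency holds after build, filter, and load", {
  check_transpose <- function(db) {
    for (t in names(db$term_index))
      for (a in db$term_index[[t]])
        expect_true(t %in% db$ptm_terms[[a]])
    for (a in db$accessions)
      for (t in db$ptm_terms[[a]])
        expect_true(a %in% db$term_index[[t]])
    expect_true(all(unlist(db$term_index) %in% db$accessions))
  }
  for (seed in 1:3) {
    cfg <- simulation_config(n_proteins = 30, n_terms = 4, prevalence = 0.4,
                             seed = seed)
    db <- simulate_database(cfg)$db
    check_transpose(db)
    path <- tempfile(fileext = ".json.gz")
    save_database(db, path)
    check_transpose(load_database(path))
  }
  db <- load_fixture_db()
  check_transpose(filter_by_organism(db, "Homo sapiens"))
})

test_that("building twice from the same stream yields equal databases", {
  lines <- readLines(fixture_path("swissprot_records.dat"))
  vocab <- load_fixture_vocab()
  d1 <- build_database(parse_flatfile_records(lines), vocab)
  d2 <- build_database(parse_flatfile_records(lines), vocab)
  expect_equal(d1$ptm_terms, d2$ptm_terms)
  expect_equal(d1$term_index, d2$term_index)
  expect_equal(d1$organism_index, d2$organism_index)
})

test_that("organism filtering is case-insensitive substring matching", {
  lines <- c(make_record_lines(list(P1 = "K1"), "Homo sapiens (Human)"),
             make_record_lines(list(P2 = "K1"), "Mus musculus (Mouse)"))
  vocab <- parse_ptm_vocabulary(make_vocab_lines("K1"))
  db <- build_database(parse_flatfile_records(lines), vocab)
  expect_equal(filter_by_organism(db, "Homo sapiens")$accessions, "P1")
  expect_equal(filter_by_organism(db, "homo SAPIENS")$accessions, "P1")
  expect_error(filter_by_organism(db, "Danio"), "absent")
})

test_that("term frequencies count index cardinalities with tie-break by name", {
  db <- make_db(list(P1 = c("T1"), P2 = c("T1", "T2")))
  expect_equal(term_frequencies(db),
               data.frame(term = c("T1", "T2"), count = c(2L, 1L),
                          stringsAsFactors = FALSE))
  db2 <- make_db(list(P1 = c("B", "A"), P2 = c("A", "B")))
  expect_equal(term_frequencies(db2)$term, c("A", "B"))
  # row-count/sum identity: total count equals sum of per-protein term sets
  db3 <- simulate_database(simulation_config(n_proteins = 25, n_terms = 5,
                                             prevalence = 0.5, seed = 9))$db
  expect_equal(sum(term_frequencies(db3)$count),
               sum(lengths(db3$ptm_terms)))
})

test_that("save/load round trip is the identity", {
  db <- load_fixture_db()
  path <- tempfile(fileext = ".json.gz")
  save_database(db, path)
  db2 <- load_database(path)
  expect_equal(db2$accessions, db$accessions)
  expect_equal(db2$organisms, db$organisms)
  expect_equal(db2$ptm_terms, db$ptm_terms)
  expect_equal(db2$term_index, db$term_index)
  expect_equal(db2$organism_index, db$organism_index)
  expect_equal(db2$aliases, db$aliases)
  expect_equal(db2$meta, db$meta)
})

test_that("corrupted and future-version payloads are rejected", {
  db <- make_db(list(P1 = "K1"))
  path <- tempfile()
  save_database(db, path)
  raw <- suppressWarnings(readLines(gzfile(path)))  # payload has no final \n
  trunc <- tempfile()
  writeLines(substr(raw, 1, nchar(raw) %/% 2), trunc)
  expect_error(load_database(trunc), "corrupt")
  future <- tempfile()
  writeLines(sub('"version":1', '"version":99', raw, fixed = TRUE), future)
  expect_error(load_database(future), "99.*expected 1|expected 1.*99")
})

test_that("secondary accessions and isoform suffixes resolve to primaries", {
  db <- load_fixture_db()
  res <- map_accessions(db, c("P00001", "Q90001", "P00002-3", "XXXXXX",
                              "P00001-2"))
  expect_equal(res$mapped, c("P00001", "P00002"))
  expect_equal(res$unmapped, "XXXXXX")
})
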