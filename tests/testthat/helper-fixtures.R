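# Shared fixtures and independent oracles, all built in code.

fixture_path <- function(f) system.file("extdata", f, package = "ptmenrich")

load_fixture_vocab <- function() {
  parse_ptm_vocabulary(fixture_path("ptmlist_subset.txt"))
}

load_fixture_db <- function() {
  build_database_from_files(fixture_path("swissprot_records.dat"),
                            fixture_path("ptmlist_subset.txt"),
                            fixture_path("ptm_keywords.txt"))
}

# Minimal ptmlist text: one modification entry per keyword.
make_vocab_lines <- function(keywords, ids = paste0("mod-for-", keywords)) {
  unlist(mapply(function(id, kw) {
    c(paste0("ID   ", id),
      "FT   MOD_RES",
      "TG   Serine.",
      "MM   80.0",
      paste0("KW   ", kw, "."),
      "//")
  }, ids, keywords, SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

# Flat-file text for a named list accession -> character vector of keywords.
make_record_lines <- function(term_sets, organism = "Homo sapiens (Human)") {
  unlist(lapply(names(term_sets), function(acc) {
    kw <- term_sets[[acc]]
    lines <- c(paste0("AC   ", acc, ";"),
               paste0("OS   ", organism, "."))
    if (length(kw))
      lines <- c(lines, paste0("KW   ", paste(kw, collapse = "; "), "."))
    c(lines, "//")
  }))
}

# Annotation database with exactly the given term memberships.
make_db <- function(term_sets, organism = "Homo sapiens (Human)") {
  all_terms <- unique(unlist(term_sets))
  if (!length(all_terms)) all_terms <- "UnusedTerm"
  vocab <- parse_ptm_vocabulary(make_vocab_lines(all_terms))
  build_database(parse_flatfile_records(make_record_lines(term_sets, organism)),
                 vocab)
}

# --- independent oracles -------------------------------------------------

# Exact hypergeometric upper tail by integer-binomial enumeration.
# choose() is integer-exact for N <= 25 and the products stay far below
# 2^53, so this is exact rational arithmetic carried in doubles.
hyper_oracle <- function(N, K, n, m) {
  xs <- m:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Exact running-sum ES via integer arithmetic for integer scores and
# p in {0, 1}: every step is a multiple of 1 / (NR * (N - NH)), so the
# running sum is tracked as an exact integer numerator.
es_oracle_exact <- function(scores_sorted, hit, p) {
  stopifnot(all(scores_sorted == round(scores_sorted)), p %in% c(0, 1))
  N <- length(hit); NH <- sum(hit); NM <- N - NH
  w <- if (p == 0) rep(1, N) else abs(scores_sorted)
  NR <- sum(w[hit])
  num <- 0          # running sum numerator over denominator NR * NM
  best_num <- 0; best_i <- 0L
  for (i in seq_len(N)) {
    num <- num + if (hit[i]) w[i] * NM else -NR
    if (abs(num) > abs(best_num)) { best_num <- num; best_i <- i }
  }
  list(es = best_num / (NR * NM), peak_index = best_i,
       final = num / (NR * NM))
}

# Classical signed two-sample KS statistic over list positions: the
# maximum (first-attained) deviation between the hit and miss ECDFs.
signed_ks_oracle <- function(hit) {
  N <- length(hit); NH <- sum(hit); NM <- N - NH
  # integer numerators over the common denominator NH * NM: exact, so the
  # first-attained maximum is unambiguous
  d_num <- cumsum(hit) * NM - cumsum(!hit) * NH
  i <- which.max(abs(d_num))
  d_num[i] / (NH * NM)
}
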