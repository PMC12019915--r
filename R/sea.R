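# Singular enrichment analysis: hypergeometric over-representation of PTM
# terms in an unranked protein list against a background population.

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `m` or more annotated proteins in a sample of
#' `n` proteins drawn without replacement from a population of `N` proteins
#' of which `K` carry the term:
#' \deqn{p = \sum_{x=m}^{\min(K,n)} \binom{K}{x}\binom{N-K}{n-x} / \binom{N}{n}}
#' Computed through the hypergeometric survival function, numerically
#' stable for large populations.
#'
#' @param N Population size.
#' @param K Number of population proteins carrying the term (`0 <= K <= N`).
#' @param n Sample (list) size (`0 <= n <= N`).
#' @param m Observed overlap (`max(0, n+K-N) <= m <= min(K, n)`).
#' @return The upper-tail probability in `[0, 1]`.
#' @examples
#' hypergeom_upper_pvalue(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_upper_pvalue <- function(N, K, n, m) {
  check_int <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v))
      stop("'", nm, "' must be a single integer")
  }
  check_int(N, "N"); check_int(K, "K"); check_int(n, "n"); check_int(m, "m")
  if (K < 0 || K > N) stop("bound violated: 0 <= K <= N (K=", K, ", N=", N, ")")
  if (n < 0 || n > N) stop("bound violated: 0 <= n <= N (n=", n, ", N=", N, ")")
  lo <- max(0, n + K - N)
  if (m < lo || m > min(K, n))
    stop("bound violated: max(0, n+K-N) <= m <= min(K, n) (m=", m, ")")
  stats::phyper(m - 1, K, N - K, n, lower.tail = FALSE)
}

ADJUST_METHODS <- c("BH", "bonferroni", "holm", "none")

#' Adjust p-values for multiple testing
#'
#' Standard Benjamini-Hochberg, Bonferroni, Holm, or no adjustment; output
#' order matches input order and values are clipped to at most 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @return Adjusted p-values, same length and order as `pvals`.
#' @export
adjust_pvalues <- function(pvals, method = "BH") {
  if (!is.character(method) || length(method) != 1L ||
      !(method %in% ADJUST_METHODS))
    stop("unknown adjustment method '", paste(method, collapse = ","),
         "'; valid methods: ", paste(ADJUST_METHODS, collapse = ", "))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("all p-values must lie in [0, 1]")
  pmin(stats::p.adjust(pvals, method = method), 1)
}

#' Singular enrichment analysis of a protein list
#'
#' Tests each PTM term for over-representation in an unranked protein list
#' with the upper-tail hypergeometric test. The population is the
#' organism-restricted database by default; alternatively the full database
#' or a user-supplied background list (e.g., the detected proteome).
#'
#' @param db A `ptm_annotation_db`.
#' @param protein_list Character vector of accessions (isoform suffixes and
#'   secondary accessions are resolved; duplicates dropped).
#' @param organism Optional taxonomy-name fragment restricting the
#'   population (case-insensitive substring match).
#' @param min_population_count Minimum population count `K` for a term to be
#'   tested (default 5; suppresses degenerate single-protein terms).
#' @param adjust_method Multiplicity adjustment across the reported terms.
#' @param background Optional character vector of accessions defining the
#'   population instead of the whole (organism-filtered) database.
#' @return data.frame of class `sea_result` with columns `term`, `m`, `n`,
#'   `K`, `N`, `fold_enrichment`, `pvalue`, `adj_pvalue`, sorted by p-value
#'   then term; attribute `unmapped` lists accessions not found.
#' @examples
#' db <- build_database_from_files(
#'   system.file("extdata", "swissprot_records.dat", package = "ptmenrich"),
#'   system.file("extdata", "ptmlist_subset.txt", package = "ptmenrich"),
#'   system.file("extdata", "ptm_keywords.txt", package = "ptmenrich"))
#' run_sea(db, c("P00001", "P00002"), min_population_count = 1)
#' @export
run_sea <- function(db, protein_list, organism = NULL,
                    min_population_count = 5, adjust_method = "BH",
                    background = NULL) {
  stopifnot(inherits(db, "ptm_annotation_db"))
  if (!length(protein_list)) stop("'protein_list' is empty")
  if (!is.numeric(min_population_count) || min_population_count < 1)
    stop("'min_population_count' must be >= 1")

  pop <- if (!is.null(organism)) filter_by_organism(db, organism) else db
  if (!is.null(background)) {
    bg <- map_accessions(pop, background)
    if (!length(bg$mapped)) stop("no background accession maps into the database")
    keep <- pop$accessions %in% bg$mapped
    pop <- new_annotation_db(pop$accessions[keep],
                             unname(pop$organisms[keep]),
                             pop$keywords[keep], pop$ptm_terms[keep],
                             pop$aliases[pop$aliases %in% pop$accessions[keep]],
                             pop$meta)
  }

  res <- map_accessions(pop, protein_list)
  if (!length(res$mapped))
    stop("none of the ", length(unique(protein_list)),
         " listed accessions map into the database population")
  listed <- res$mapped
  n <- length(listed)
  N <- db_size(pop)

  K_all <- lengths(pop$term_index)
  terms <- names(pop$term_index)[K_all >= min_population_count]
  if (!length(terms)) {
    out <- data.frame(term = character(), m = integer(), n = integer(),
                      K = integer(), N = integer(),
                      fold_enrichment = numeric(), pvalue = numeric(),
                      adj_pvalue = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("sea_result", class(out))
    attr(out, "unmapped") <- res$unmapped
    return(out)
  }
  m <- vapply(pop$term_index[terms],
              function(a) length(intersect(a, listed)), 0L)
  keep <- m >= 1L
  terms <- terms[keep]; m <- m[keep]
  K <- unname(K_all[terms])
  p <- vapply(seq_along(terms),
              function(i) hypergeom_upper_pvalue(N, K[i], n, m[i]), 0)
  out <- data.frame(term = terms, m = unname(m), n = n, K = K, N = N,
                    fold_enrichment = (unname(m) / n) / (K / N),
                    pvalue = p, stringsAsFactors = FALSE)
  out$adj_pvalue <- adjust_pvalues(out$pvalue, adjust_method)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sea_result", class(out))
  attr(out, "unmapped") <- res$unmapped
  out
}

#' Write SEA results as TSV
#'
#' Writes the result table, and optionally a lollipop-plot-ready long table
#' (`term`, `neg_log10_adj_pvalue`, `m`).
#'
#' @param results A `sea_result`.
#' @param path Output TSV path.
#' @param plot_path Optional path for the plot-ready table.
#' @return Invisibly, `path`.
#' @export
write_sea_tsv <- function(results, path, plot_path = NULL) {
  write_tsv(as.data.frame(results), path)
  if (!is.null(plot_path)) {
    plot_df <- data.frame(term = results$term,
                          neg_log10_adj_pvalue = -log10(results$adj_pvalue),
                          m = results$m, stringsAsFactors = FALSE)
    write_tsv(plot_df, plot_path)
  }
  invisible(path)
}
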