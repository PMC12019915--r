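# Protein set enrichment analysis: weighted Kolmogorov-Smirnov running-sum
# enrichment score per PTM term, score-permutation null, normalized
# enrichment scores, permutation FDR, and leading-edge extraction.

#' Rank a scored protein list
#'
#' Sorts descending by score, breaking ties by accession (ascending) so
#' that the ranking — and everything downstream of it — is deterministic.
#' Duplicate accessions are collapsed to the score of largest magnitude and
#' reported via the `duplicates` attribute.
#'
#' @param scored data.frame with columns `accession` and `score`, or a list
#'   of (accession, score) pairs.
#' @return data.frame of class `ranked_list` with columns `accession`,
#'   `score`, sorted; attribute `duplicates` names collapsed accessions.
#' @export
rank_proteins <- function(scored) {
  scored <- as.data.frame(scored, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "score") %in% names(scored)))
  acc <- canonical_accession(as.character(scored$accession))
  sc <- as.numeric(scored$score)
  bad <- !is.finite(sc)
  if (any(bad))
    stop("non-finite score for accession ", acc[which(bad)[1L]])
  dups <- unique(acc[duplicated(acc)])
  if (length(dups)) {
    keep <- order(acc, -abs(sc))          # per accession, largest |score| first
    acc <- acc[keep]; sc <- sc[keep]
    first <- !duplicated(acc)
    acc <- acc[first]; sc <- sc[first]
  }
  if (length(acc) < 2L) stop("a ranked list needs at least 2 distinct proteins")
  ord <- order(-sc, acc)
  out <- data.frame(accession = acc[ord], score = sc[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  attr(out, "duplicates") <- dups
  out
}

# Core running-sum computation on a prepared hit indicator. `weights` are
# |score|^p for every position. Returns list(values, peak_index, es).
running_sum <- function(hit, weights, n_miss_inv) {
  nr <- sum(weights[hit])
  steps <- numeric(length(hit))
  steps[hit] <- weights[hit] / nr
  steps[!hit] <- -n_miss_inv
  values <- cumsum(steps)
  # first index attaining the maximal |value|; the tolerance absorbs 1-ulp
  # cumsum noise so exact ties (e.g. +x at i, -x at j > i) resolve to the
  # earlier position, as they would in exact arithmetic
  a <- abs(values)
  mx <- max(a)
  peak <- which(a >= mx - mx * 1e-12)[1L]
  list(values = values, peak_index = peak, es = values[peak])
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom; encountering a member of the
#' set increments the running statistic by `|score|^p / N_R` (with
#' `N_R = sum of |score|^p over members`), a non-member decrements it by
#' `1/(N - N_H)`. The enrichment score is the value at the first position
#' of maximal absolute deviation from zero; the profile ends at zero.
#'
#' @param ranked A `ranked_list`.
#' @param members Character vector: the term's protein set.
#' @param weight_p Non-negative weighting exponent `p` (0 gives the
#'   classical unweighted Kolmogorov-Smirnov form; default 1).
#' @return Object of class `running_profile`: list with `values` (running
#'   sum after each position), `peak_index`, `es`, and `hits` (logical per
#'   position).
#' @examples
#' rl <- rank_proteins(data.frame(accession = paste0("P", 1:5), score = 5:1))
#' enrichment_score(rl, c("P1", "P3"), weight_p = 1)$es  # 2/3
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(weight_p) || length(weight_p) != 1L || weight_p < 0)
    stop("'weight_p' must be a non-negative real")
  N <- nrow(ranked)
  hit <- ranked$accession %in% members
  nh <- sum(hit)
  if (nh == 0L) stop("term absent from list")
  if (nh == N) stop("set equals list")
  w <- if (weight_p == 0) rep(1, N) else abs(ranked$score)^weight_p
  if (sum(w[hit]) == 0)
    stop("all member scores are zero with weight_p > 0; ",
         "the weighted running sum is undefined")
  prof <- running_sum(hit, w, 1 / (N - nh))
  prof$hits <- hit
  class(prof) <- "running_profile"
  prof
}

#' @export
print.running_profile <- function(x, ...) {
  cat("Running enrichment profile: ES =", format(x$es),
      "at position", x$peak_index, "of", length(x$values), "\n")
  invisible(x)
}

#' Permutation null distribution of the enrichment score
#'
#' Uniformly shuffles the score vector over the fixed accession order
#' (equivalently: draws the member positions uniformly at random) and
#' recomputes the enrichment score, `n_perm` times. Fully reproducible
#' from `seed`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param detail If `TRUE`, also return the drawn member positions.
#' @return Numeric vector of `n_perm` null enrichment scores, or (with
#'   `detail = TRUE`) a list with `es` and the `n_perm x N_H` integer
#'   matrix `member_positions`.
#' @export
permutation_null <- function(ranked, members, weight_p = 1, n_perm = 1000,
                             seed = 1L, detail = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(n_perm) || n_perm < 1) stop("'n_perm' must be >= 1")
  N <- nrow(ranked)
  nh <- sum(ranked$accession %in% members)
  if (nh == 0L) stop("term absent from list")
  if (nh == N) stop("set equals list")
  w <- if (weight_p == 0) rep(1, N) else abs(ranked$score)^weight_p
  miss_inv <- 1 / (N - nh)
  es <- numeric(n_perm)
  pos <- if (detail) matrix(0L, nrow = n_perm, ncol = nh)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N, nh)
      hit <- logical(N); hit[idx] <- TRUE
      if (sum(w[hit]) == 0) { es[b] <- 0; next }
      es[b] <- running_sum(hit, w, miss_inv)$es
      if (detail) pos[b, ] <- sort(idx)
    }
  })
  if (detail) list(es = es, member_positions = pos) else es
}

#' Normalized enrichment score and nominal p-value
#'
#' Same-sign convention: with `S` the non-zero null scores sharing the sign
#' of the observed `es`, `nes = es / mean(|S|)` and
#' `nominal_p = (1 + #\{|e| >= |es|, e in S\}) / (1 + |S|)` (the +1
#' pseudo-count keeps finite-permutation p-values strictly positive).
#'
#' @param es Observed enrichment score.
#' @param null_es Non-empty numeric vector of null enrichment scores.
#' @return List with `nes` (NA-flagged when no same-sign null exists) and
#'   `nominal_p`.
#' @export
nes_and_pvalues <- function(es, null_es) {
  if (!length(null_es)) stop("'null_es' must be non-empty")
  if (es == 0) {
    warning("observed enrichment score is exactly 0; degenerate result")
    return(list(nes = 0, nominal_p = 1))
  }
  s <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (!length(s)) {
    warning("no same-sign null enrichment score; NES undefined, p set to 1")
    return(list(nes = NA_real_, nominal_p = 1))
  }
  list(nes = es / mean(abs(s)),
       nominal_p = (1 + sum(abs(s) >= abs(es))) / (1 + length(s)))
}

# Normalize a term's null ES values into null NES, each by the mean |ES| of
# its own sign within that term's null collection (standard GSEA scheme).
normalize_null <- function(null_es) {
  pos <- null_es[null_es > 0]; neg <- null_es[null_es < 0]
  mp <- if (length(pos)) mean(pos) else NA_real_
  mn <- if (length(neg)) mean(abs(neg)) else NA_real_
  out <- numeric(length(null_es))
  out[null_es > 0] <- null_es[null_es > 0] / mp
  out[null_es < 0] <- null_es[null_es < 0] / mn
  out[null_es == 0] <- 0
  out[is.finite(out)]
}

#' Permutation FDR q-values over a set of terms
#'
#' For each term's observed NES, q is the ratio of (a) the fraction of the
#' pooled same-sign null NES at least as extreme, over (b) the fraction of
#' observed same-sign NES at least as extreme, clipped to `[0, 1]`, with a
#' monotone cleanup so q never decreases as |NES| decreases within a sign.
#'
#' @param nes Numeric vector of observed normalized enrichment scores
#'   (NA allowed; such terms get q = 1 with a warning).
#' @param null_nes_pool Numeric vector pooling all terms' null NES values.
#' @return Numeric vector of q-values aligned with `nes`.
#' @export
compute_fdr <- function(nes, null_nes_pool) {
  if (!length(nes)) stop("at least one term is required")
  q <- rep(NA_real_, length(nes))
  for (i in seq_along(nes)) {
    v <- nes[i]
    if (is.na(v) || v == 0) { q[i] <- 1; next }
    pool <- null_nes_pool[sign(null_nes_pool) == sign(v)]
    obs <- nes[!is.na(nes) & sign(nes) == sign(v)]
    if (!length(pool)) {
      warning("degenerate null pool for sign of NES = ", format(v),
              "; q set to 1")
      q[i] <- 1
      next
    }
    num <- mean(abs(pool) >= abs(v))
    den <- mean(abs(obs) >= abs(v))
    q[i] <- min(1, max(0, num / den))
  }
  # monotone cleanup within each sign: stronger |NES| never has larger q.
  # Walking from the weakest |NES| upward, each term takes the running
  # minimum, so q is non-increasing in |NES|.
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & sign(nes) == sgn)
    if (length(idx) > 1L) {
      ord <- idx[order(abs(nes[idx]))]
      q[ord] <- cummin(q[ord])
    }
  }
  q
}

#' Leading-edge proteins
#'
#' For a positive enrichment score: the member proteins at or before the
#' running-sum peak. For a negative score: the members at or after the
#' peak (the core of the depletion signal at the bottom of the list).
#' List order is preserved.
#'
#' @inheritParams enrichment_score
#' @param profile The `running_profile` from [enrichment_score()] on the
#'   same inputs.
#' @return Character vector of accessions (possibly empty when `es == 0`).
#' @export
leading_edge <- function(ranked, members, profile) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(profile, "running_profile"))
  hit <- ranked$accession %in% members
  pos <- seq_len(nrow(ranked))
  sel <- if (profile$es > 0) hit & pos <= profile$peak_index
         else if (profile$es < 0) hit & pos >= profile$peak_index
         else rep(FALSE, nrow(ranked))
  ranked$accession[sel]
}

#' Protein set enrichment analysis
#'
#' Runs the full PSEA pipeline against an annotation database: rank the
#' scored list, compute per-term weighted running-sum enrichment scores,
#' a per-term score-permutation null (independent, deterministically
#' derived sub-seeds per term), normalized enrichment scores, nominal
#' permutation p-values, multiplicity-adjusted p-values, pooled-null FDR
#' q-values, and leading-edge subsets.
#'
#' @param db A `ptm_annotation_db`.
#' @param scored data.frame with columns `accession`, `score`.
#' @param organism Optional taxonomy-name fragment restricting the
#'   population database.
#' @param weight_p Weighting exponent (default 1).
#' @param n_perm Number of score permutations per term (default 1000).
#' @param seed Integer seed governing all permutations.
#' @param min_population_count Minimum population count `K` for a term to
#'   be analyzed (default 5).
#' @param adjust_method Adjustment applied across the terms' nominal
#'   p-values (default `"BH"`).
#' @return data.frame of class `psea_result` with columns `term`,
#'   `set_size`, `K`, `es`, `nes`, `nominal_p`, `adj_pvalue`, `fdr_q`,
#'   `leading_edge` (comma-joined accessions), sorted by decreasing |NES|;
#'   attributes `unmapped` and `ranked` (the ranked list used).
#' @export
run_psea <- function(db, scored, organism = NULL, weight_p = 1,
                     n_perm = 1000, seed = 1L, min_population_count = 5,
                     adjust_method = "BH") {
  stopifnot(inherits(db, "ptm_annotation_db"))
  pop <- if (!is.null(organism)) filter_by_organism(db, organism) else db

  scored <- as.data.frame(scored, stringsAsFactors = FALSE)
  acc_canon <- canonical_accession(as.character(scored$accession))
  resolved <- ifelse(acc_canon %in% pop$accessions, acc_canon,
                     unname(pop$aliases[acc_canon]))
  unmapped <- unique(scored$accession[is.na(resolved)])
  mapped_scored <- data.frame(accession = resolved[!is.na(resolved)],
                              score = as.numeric(scored$score)[!is.na(resolved)],
                              stringsAsFactors = FALSE)
  if (nrow(mapped_scored) < 2L)
    stop("fewer than 2 scored proteins map into the database population (",
         nrow(mapped_scored), " mapped, ", length(unmapped), " unmapped)")
  ranked <- rank_proteins(mapped_scored)
  N <- nrow(ranked)

  K_all <- lengths(pop$term_index)
  cand <- names(pop$term_index)[K_all >= min_population_count]
  set_sizes <- vapply(pop$term_index[cand],
                      function(a) sum(ranked$accession %in% a), 0L)
  full <- cand[set_sizes == N]
  if (length(full))
    warning("term(s) whose members equal the whole list excluded: ",
            paste(full, collapse = ", "))
  terms <- cand[set_sizes >= 1L & set_sizes < N]
  if (!length(terms))
    stop("no analyzable term: of ", length(cand), " terms with K >= ",
         min_population_count, ", none has 1 <= set size < ", N)

  n_t <- length(terms)
  es <- nes <- nominal_p <- numeric(n_t)
  set_size <- integer(n_t)
  ledge <- character(n_t)
  null_pool <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    mem <- pop$term_index[[terms[i]]]
    prof <- enrichment_score(ranked, mem, weight_p)
    null_es <- permutation_null(ranked, mem, weight_p, n_perm,
                                seed = term_seed(seed, terms[i]))
    np <- nes_and_pvalues(prof$es, null_es)
    es[i] <- prof$es
    nes[i] <- np$nes
    nominal_p[i] <- np$nominal_p
    set_size[i] <- sum(prof$hits)
    ledge[i] <- paste(leading_edge(ranked, mem, prof), collapse = ",")
    null_pool[[i]] <- normalize_null(null_es)
  }
  adj <- adjust_pvalues(nominal_p, adjust_method)
  fdr <- compute_fdr(nes, unlist(null_pool))

  out <- data.frame(term = terms, set_size = set_size,
                    K = unname(K_all[terms]), es = es, nes = nes,
                    nominal_p = nominal_p, adj_pvalue = adj, fdr_q = fdr,
                    leading_edge = ledge, stringsAsFactors = FALSE)
  ord <- order(-abs(ifelse(is.na(out$nes), -Inf, out$nes)), out$term)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("psea_result", class(out))
  attr(out, "unmapped") <- unmapped
  attr(out, "ranked") <- ranked
  out
}

#' Write PSEA results as TSV
#'
#' @param results A `psea_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_psea_tsv <- function(results, path) {
  write_tsv(as.data.frame(results), path)
}

#' Export per-term running-score profiles
#'
#' The data behind a running-score plot: one long TSV with, per term and
#' list position, the accession, its score, the in-set flag, and the
#' running-sum value.
#'
#' @param db A `ptm_annotation_db` (the same population used for the run).
#' @param results A `psea_result` (carries the ranked list).
#' @param path Output TSV path.
#' @param weight_p The weighting exponent used in the run.
#' @return Invisibly, `path`.
#' @export
write_running_profiles <- function(db, results, path, weight_p = 1) {
  ranked <- attr(results, "ranked")
  stopifnot(!is.null(ranked))
  blocks <- lapply(results$term, function(t) {
    prof <- enrichment_score(ranked, db$term_index[[t]], weight_p)
    data.frame(term = t, position = seq_len(nrow(ranked)),
               accession = ranked$accession, score = ranked$score,
               in_set = as.integer(prof$hits), running = prof$values,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, blocks), path)
}
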