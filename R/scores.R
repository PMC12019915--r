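# Protein-level scores for PSEA from replicate intensity tables, and
# modified-peptide occupancy normalization for PTM monitoring.

#' Log2 fold change between two replicate groups
#'
#' `log2(mean(treat) / mean(ctrl))`, on raw (non-negative) intensities.
#'
#' @param treat_values,ctrl_values Numeric replicate intensities (`NA`s are
#'   treated as absent and excluded from the means).
#' @return The log2 fold change.
#' @export
log2_fold_change <- function(treat_values, ctrl_values) {
  treat_values <- treat_values[!is.na(treat_values)]
  ctrl_values <- ctrl_values[!is.na(ctrl_values)]
  if (!length(treat_values) || !length(ctrl_values))
    stop("both groups must be non-empty")
  if (any(treat_values < 0) || any(ctrl_values < 0))
    stop("negative intensity encountered")
  mc <- mean(ctrl_values)
  if (mc == 0) stop("control mean is zero; fold change undefined")
  log2(mean(treat_values) / mc)
}

#' Two-sample t-test with equal-variance assumption
#'
#' Pooled-variance Student t with `|x| + |y| - 2` degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y Numeric replicate values, each of length >= 2 (`NA`s
#'   excluded).
#' @return List with `t` and `pvalue`.
#' @export
equal_variance_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observed replicates")
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      warning("zero pooled variance with equal means; degenerate t = 0, p = 1")
      return(list(t = 0, pvalue = 1))
    }
    stop("zero pooled variance with different group means; t undefined")
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, pvalue = 2 * stats::pt(-abs(t), df = nx + ny - 2))
}

#' Ranking score for one protein
#'
#' Default: `sign(log2FC) * (-log10 p)` — preserves the direction of change
#' and the strength of evidence, the most common GSEA-style input.
#' Alternatives: the log2 fold change alone.
#'
#' @param lfc Log2 fold change.
#' @param pvalue p-value in `(0, 1]` (raw or adjusted; floor zero p-values
#'   upstream).
#' @param method `"signed_log_p"` (default) or `"log2fc"`.
#' @return The score.
#' @export
protein_score <- function(lfc, pvalue, method = c("signed_log_p", "log2fc")) {
  method <- match.arg(method)
  if (method == "log2fc") return(lfc)
  if (any(pvalue <= 0) || any(pvalue > 1))
    stop("'pvalue' must lie in (0, 1]; floor zero p-values upstream")
  sign(lfc) * (-log10(pvalue))
}

#' Score all proteins of an expression table
#'
#' Computes, per protein, the log2 fold change (treatment vs. control),
#' the equal-variance two-sample t-test, BH-adjusted p-values, and the
#' PSEA ranking score. Proteins with fewer than 2 observed replicates in
#' either group are skipped and reported.
#'
#' @param tbl data.frame: column `accession` plus one numeric column per
#'   sample.
#' @param groups Named character vector mapping sample column names to
#'   condition labels.
#' @param treatment,control Condition labels to compare.
#' @param score_method Passed to [protein_score()].
#' @return data.frame with columns `accession`, `log2fc`, `t`, `pvalue`,
#'   `adj_pvalue`, `score`; attribute `skipped` lists skipped accessions.
#' @export
score_proteins <- function(tbl, groups, treatment, control,
                           score_method = "signed_log_p") {
  stopifnot("accession" %in% names(tbl))
  t_cols <- names(groups)[groups == treatment]
  c_cols <- names(groups)[groups == control]
  if (!length(t_cols) || !length(c_cols))
    stop("conditions '", treatment, "' / '", control,
         "' not found in the design")
  missing_cols <- setdiff(c(t_cols, c_cols), names(tbl))
  if (length(missing_cols))
    stop("sample column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  res <- lapply(seq_len(nrow(tbl)), function(i) {
    tv <- as.numeric(tbl[i, t_cols]); cv <- as.numeric(tbl[i, c_cols])
    if (sum(!is.na(tv)) < 2L || sum(!is.na(cv)) < 2L) return(NULL)
    lfc <- log2_fold_change(tv, cv)
    tt <- equal_variance_ttest(tv, cv)
    data.frame(accession = tbl$accession[i], log2fc = lfc, t = tt$t,
               pvalue = tt$pvalue, stringsAsFactors = FALSE)
  })
  kept <- !vapply(res, is.null, TRUE)
  if (!any(kept)) stop("no protein has >= 2 observed replicates per group")
  out <- do.call(rbind, res[kept])
  out$adj_pvalue <- adjust_pvalues(out$pvalue, "BH")
  p_floor <- pmax(out$pvalue, .Machine$double.xmin)
  out$score <- protein_score(out$log2fc, p_floor, score_method)
  rownames(out) <- NULL
  attr(out, "skipped") <- tbl$accession[!kept]
  out
}

#' Select a differentially-expressed protein list for SEA
#'
#' Default gate: BH-adjusted p < 0.05, with an optional absolute log2
#' fold-change gate (commonly 0.6); both configurable.
#'
#' @param scores Output of [score_proteins()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_abs_lfc Optional minimum |log2FC| (default none).
#' @return Character vector of accessions passing the gates.
#' @export
select_significant <- function(scores, alpha = 0.05, min_abs_lfc = NULL) {
  keep <- scores$adj_pvalue < alpha
  if (!is.null(min_abs_lfc)) keep <- keep & abs(scores$log2fc) > min_abs_lfc
  scores$accession[keep]
}

#' Modified-peptide occupancy normalization
#'
#' Three-step normalization of modified-peptide abundance in a multiplexed
#' (e.g., TMT) experiment: (1) each peptide intensity is divided by the
#' total intensity of its channel; (2) the channel-normalized intensity is
#' divided by the summed channel-normalized intensity of the same
#' protein's unmodified peptides — cancelling protein-level abundance
#' changes; (3) per condition, the mean of this ratio over the condition's
#' channels is divided by the mean over the control channels.
#'
#' @param tbl data.frame with columns `peptide`, `protein`, `modifications`
#'   (comma-separated modification names, empty for unmodified peptides),
#'   plus one numeric intensity column per channel.
#' @param groups Named character vector mapping channel column names to
#'   condition labels.
#' @param control The control condition label.
#' @return data.frame with columns `peptide`, `protein`, `condition`,
#'   `ratio` for every modified peptide and non-control condition;
#'   attribute `excluded` lists modified peptides whose protein has no
#'   unmodified peptide.
#' @export
normalize_modified_peptides <- function(tbl, groups, control) {
  needed <- c("peptide", "protein", "modifications")
  stopifnot(all(needed %in% names(tbl)))
  channels <- names(groups)
  missing_cols <- setdiff(channels, names(tbl))
  if (length(missing_cols))
    stop("channel column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  if (!(control %in% groups)) stop("control condition '", control,
                                   "' not present in the design")
  V <- as.matrix(tbl[, channels, drop = FALSE])
  storage.mode(V) <- "double"
  if (any(V < 0, na.rm = TRUE)) stop("negative intensity encountered")
  totals <- colSums(V, na.rm = TRUE)
  if (any(totals == 0)) stop("zero total intensity in channel(s): ",
                             paste(channels[totals == 0], collapse = ", "))
  Vn <- sweep(V, 2L, totals, "/")                       # step 1

  modified <- nzchar(trimws2(as.character(tbl$modifications)))
  unmod_sum <- rowsum(ifelse(is.na(Vn), 0, Vn) * (!modified),
                      group = tbl$protein)               # per protein x channel
  prot_of <- match(tbl$protein, rownames(unmod_sum))

  excluded <- character()
  rows <- list()
  for (i in which(modified)) {
    denom <- unmod_sum[prot_of[i], ]
    if (all(denom == 0)) {
      excluded <- c(excluded, tbl$peptide[i])
      next
    }
    if (any(denom == 0))
      stop("protein ", tbl$protein[i], " has zero unmodified intensity in ",
           "some channels only; occupancy undefined there")
    r <- Vn[i, ] / denom                                 # step 2
    ctrl_mean <- mean(r[groups[channels] == control], na.rm = TRUE)
    for (cond in setdiff(unique(unname(groups)), control)) {
      cond_mean <- mean(r[groups[channels] == cond], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = tbl$peptide[i], protein = tbl$protein[i],
        condition = cond, ratio = cond_mean / ctrl_mean,  # step 3
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), protein = character(),
               condition = character(), ratio = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
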