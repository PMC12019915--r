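# Turn enriched PTM terms into an exact-modification list for a refined
# search-engine configuration (sea2mass / psea2mass).

# Shared selection + mapping core. `ranked_terms` must already be in the
# desired priority order; `stat` aligned with it.
terms_to_export <- function(ranked_terms, stat, vocab, top_k) {
  if (!is.null(top_k)) {
    keep <- seq_len(min(top_k, length(ranked_terms)))
    ranked_terms <- ranked_terms[keep]; stat <- stat[keep]
  }
  mapped <- if (length(ranked_terms)) keyword_to_modifications(vocab, ranked_terms)
            else list(entries = vocab$entries[0, , drop = FALSE],
                      unmatched = character())
  e <- mapped$entries
  if (!nrow(e)) {
    out <- data.frame(modification = character(), keyword = character(),
                      target = character(), position = character(),
                      mono_mass_delta = numeric(), source_statistic = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  } else {
    stat_of <- stat[match(e$keyword, ranked_terms)]
    out <- data.frame(modification = e$id, keyword = e$keyword,
                      target = e$target, position = e$position,
                      mono_mass_delta = e$mono_mass_delta,
                      source_statistic = stat_of, stringsAsFactors = FALSE)
    out <- out[!duplicated(out$modification), , drop = FALSE]
    out <- out[order(out$source_statistic, out$modification), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  class(out) <- c("modification_export", class(out))
  attr(out, "unmatched") <- mapped$unmatched
  out
}

#' Export enriched SEA terms as exact modifications
#'
#' Selects terms with adjusted p below `alpha` (optionally truncated to the
#' `top_k` most significant), maps each through the controlled vocabulary
#' to its exact modifications, and de-duplicates. Terms with no vocabulary
#' entry (e.g., umbrella keywords like "Phosphoprotein") are reported as
#' unmatched rather than dropped silently.
#'
#' @param results A `sea_result` from [run_sea()].
#' @param vocab A `ptm_vocabulary`.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param top_k Optional cap on the number of selected terms (default
#'   unlimited).
#' @return data.frame of class `modification_export` with columns
#'   `modification`, `keyword`, `target`, `position`, `mono_mass_delta`,
#'   `source_statistic`, `rank`, sorted by source statistic then name;
#'   attribute `unmatched` lists keywords without vocabulary entries.
#' @export
sea2mass <- function(results, vocab, alpha = 0.05, top_k = NULL) {
  stopifnot(inherits(results, "sea_result"))
  if (!nrow(results)) stop("'results' is empty")
  sel <- results[results$adj_pvalue < alpha, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no term passes alpha = ", alpha, "; empty export")
    return(terms_to_export(character(), numeric(), vocab, NULL))
  }
  sel <- sel[order(sel$adj_pvalue, sel$term), , drop = FALSE]
  terms_to_export(sel$term, sel$adj_pvalue, vocab, top_k)
}

#' Export enriched PSEA terms as exact modifications
#'
#' As [sea2mass()], but candidate terms are ranked by decreasing |NES|
#' before truncation to `top_k` (default 5, matching a refined-search
#' configuration built from the strongest few signals).
#'
#' @param results A `psea_result` from [run_psea()].
#' @inheritParams sea2mass
#' @param statistic Column used for the significance gate: `"adj_pvalue"`
#'   (default) or `"fdr_q"`.
#' @return A `modification_export`; see [sea2mass()].
#' @export
psea2mass <- function(results, vocab, alpha = 0.05, top_k = 5,
                      statistic = c("adj_pvalue", "fdr_q")) {
  stopifnot(inherits(results, "psea_result"))
  statistic <- match.arg(statistic)
  if (!nrow(results)) stop("'results' is empty")
  sel <- results[results[[statistic]] < alpha, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no term passes alpha = ", alpha, "; empty export")
    return(terms_to_export(character(), numeric(), vocab, NULL))
  }
  ord <- order(-abs(ifelse(is.na(sel$nes), -Inf, sel$nes)), sel$term)
  sel <- sel[ord, , drop = FALSE]
  terms_to_export(sel$term, sel[[statistic]], vocab, top_k)
}

# One-letter codes for residue names, used for the search-engine site field.
AA_ONE_LETTER <- c(
  Alanine = "A", Arginine = "R", Asparagine = "N", Aspartate = "D",
  "Aspartic acid" = "D", Cysteine = "C", Glutamate = "E",
  "Glutamic acid" = "E", Glutamine = "Q", Glycine = "G", Histidine = "H",
  Isoleucine = "I", Leucine = "L", Lysine = "K", Methionine = "M",
  Phenylalanine = "F", Proline = "P", Serine = "S", Threonine = "T",
  Tryptophan = "W", Tyrosine = "Y", Valine = "V")

#' Write a modification export
#'
#' `tsv`: the documented columns, bit-exact. `maxquant-xml`: one
#' `<modification>` element per row with `name`, `delta_mass` (monoisotopic
#' Daltons), `residues` (one-letter site codes where the target is a single
#' standard residue, otherwise the target text verbatim), and `position`
#' attributes — a minimal dialect for configuring variable modifications in
#' a search engine.
#'
#' @param export A `modification_export`.
#' @param path Output file path.
#' @param dialect `"tsv"` (default) or `"maxquant-xml"`.
#' @return Invisibly, `path`.
#' @export
write_modification_table <- function(export, path,
                                     dialect = c("tsv", "maxquant-xml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(export, "modification_export"))
  if (dialect == "tsv") {
    write_tsv(as.data.frame(export), path)
    return(invisible(path))
  }
  if (!nrow(export)) stop("maxquant-xml export requires a non-empty table")
  if (anyNA(export$mono_mass_delta))
    stop("modification '",
         export$modification[which(is.na(export$mono_mass_delta))[1L]],
         "' has no monoisotopic mass delta; cannot emit maxquant-xml")
  doc <- xml2::xml_new_root("modifications")
  for (i in seq_len(nrow(export))) {
    residues <- AA_ONE_LETTER[export$target[i]]
    if (is.na(residues)) residues <- export$target[i]
    xml2::xml_add_child(
      doc, "modification",
      name = export$modification[i],
      delta_mass = formatC(export$mono_mass_delta[i], format = "fg",
                           digits = 15),
      residues = unname(residues),
      position = export$position[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read back a modification export
#'
#' Round-trip readers for both dialects of [write_modification_table()].
#'
#' @param path File written by [write_modification_table()].
#' @param dialect `"tsv"` or `"maxquant-xml"`.
#' @return data.frame; for `tsv` the full export table, for `maxquant-xml`
#'   columns `modification`, `delta_mass`, `residues`, `position`.
#' @export
read_modification_table <- function(path, dialect = c("tsv", "maxquant-xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") return(read_tsv(path))
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//modification")
  data.frame(
    modification = xml2::xml_attr(nodes, "name"),
    delta_mass = as.numeric(xml2::xml_attr(nodes, "delta_mass")),
    residues = xml2::xml_attr(nodes, "residues"),
    position = xml2::xml_attr(nodes, "position"),
    stringsAsFactors = FALSE)
}
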