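# Parsing of the UniProt controlled vocabulary of protein modifications
# (the "ptmlist" dialect) and keyword -> exact-modification lookups.
#
# Each record is a block of two-letter line codes terminated by "//":
#   ID   O-phospho-L-threonine
#   AC   PTM-0255
#   FT   MOD_RES
#   TG   Threonine.
#   PP   Anywhere.
#   CF   H O3 P
#   MM   79.966331
#   MA   79.98
#   KW   Phosphothreonine.
#   DR   ...            (cross-references; ignored)
# A free-text header preamble before the first ID line is permitted.
# Continuation lines (a repeated code) concatenate with a single space.

VOCAB_COLUMNS <- c("id", "accession", "feature_key", "target", "position",
                   "mono_mass_delta", "avg_mass_delta", "correction_formula",
                   "keyword")

#' Parse a UniProt PTM controlled-vocabulary file
#'
#' Reads a ptmlist-dialect text file (plain or gzip-compressed) into a
#' `ptm_vocabulary` object: one entry per `ID ... //` record with the
#' modification name, vocabulary accession, feature key (`MOD_RES`,
#' `CROSSLNK`, `LIPID`, or `other`), target residue, position class,
#' monoisotopic and average mass deltas (Daltons, `NA` when absent),
#' correction formula, and parent PTM keyword. Unknown line codes are
#' ignored; trailing periods on ID/TG/PP/KW values are stripped.
#'
#' @param path Path to a ptmlist-style file (optionally `.gz`), or a
#'   character vector of lines.
#' @return An object of class `ptm_vocabulary`: a list with `entries`
#'   (data.frame, one row per modification) and `by_keyword` (named list of
#'   row indices per parent keyword).
#' @examples
#' vocab <- parse_ptm_vocabulary(
#'   system.file("extdata", "ptmlist_subset.txt", package = "ptmenrich"))
#' nrow(vocab$entries)
#' @export
parse_ptm_vocabulary <- function(path) {
  lines <- if (is.character(path) && length(path) > 1L) path else read_lines_enc(path)

  n <- length(lines)
  entries <- list()
  rec <- NULL
  rec_line <- 0L

  new_rec <- function() {
    list(id = NULL, accession = "", feature_key = "other", target = "Undefined",
         position = "", mono_mass_delta = NA_real_, avg_mass_delta = NA_real_,
         correction_formula = "", keyword = "")
  }

  parse_mass <- function(value, lineno, code) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("line ", lineno, ": ", code, " value '", value,
                       "' is not a decimal number")
    v
  }

  in_record <- FALSE
  seen_record <- FALSE
  for (i in seq_len(n)) {
    line <- lines[i]
    code <- substr(line, 1L, 2L)
    if (identical(code, "//")) {
      if (!in_record) next
      if (is.null(rec$id)) stop("record ending at line ", i, " has no ID line")
      if (!is.null(entries[[rec$id]]))
        stop("duplicate vocabulary ID: ", rec$id)
      entries[[rec$id]] <- rec
      rec <- NULL
      in_record <- FALSE
      seen_record <- TRUE
      next
    }
    if (nchar(line) < 6L) next
    value <- trimws2(substring(line, 6L))
    if (!in_record) {
      # free-text preamble/footer lines are skipped; but a properly coded
      # line after the first record that is not an ID opens a record
      # missing its ID line (an error at its terminator)
      coded <- grepl("^[A-Z][A-Z0-9]   ", line)
      if (!identical(code, "ID") && !(seen_record && coded)) next
      in_record <- TRUE
      rec <- new_rec()
      rec_line <- i
    }
    switch(code,
      ID = {
        v <- strip_trailing_period(value)
        rec$id <- if (is.null(rec$id)) v else paste(rec$id, v)
      },
      AC = rec$accession <- value,
      FT = rec$feature_key <- if (value %in% c("MOD_RES", "CROSSLNK", "LIPID"))
                                value else "other",
      TG = {
        v <- strip_trailing_period(value)
        rec$target <- if (identical(rec$target, "Undefined")) v
                      else paste(rec$target, v)
      },
      PP = rec$position <- if (nzchar(rec$position))
                             paste(rec$position, strip_trailing_period(value))
                           else strip_trailing_period(value),
      CF = rec$correction_formula <- if (nzchar(rec$correction_formula))
                                       paste(rec$correction_formula, value)
                                     else value,
      MM = rec$mono_mass_delta <- parse_mass(value, i, "MM"),
      MA = rec$avg_mass_delta <- parse_mass(value, i, "MA"),
      KW = rec$keyword <- strip_trailing_period(value),
      NULL)  # unknown codes (DR, ...) ignored
  }
  if (in_record)
    stop("unterminated final record starting at line ", rec_line,
         " (missing '//')")

  df <- if (length(entries)) {
    do.call(rbind, lapply(entries, function(r)
      data.frame(id = r$id, accession = r$accession, feature_key = r$feature_key,
                 target = r$target, position = r$position,
                 mono_mass_delta = r$mono_mass_delta,
                 avg_mass_delta = r$avg_mass_delta,
                 correction_formula = r$correction_formula,
                 keyword = r$keyword, stringsAsFactors = FALSE)))
  } else {
    data.frame(id = character(), accession = character(),
               feature_key = character(), target = character(),
               position = character(), mono_mass_delta = numeric(),
               avg_mass_delta = numeric(), correction_formula = character(),
               keyword = character(), stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  new_vocabulary(df)
}

new_vocabulary <- function(entries) {
  stopifnot(identical(names(entries), VOCAB_COLUMNS))
  kw <- entries$keyword
  by_keyword <- split(seq_len(nrow(entries)), kw)
  by_keyword <- by_keyword[nzchar(names(by_keyword))]
  structure(list(entries = entries, by_keyword = by_keyword),
            class = "ptm_vocabulary")
}

#' @export
print.ptm_vocabulary <- function(x, ...) {
  cat("PTM controlled vocabulary:", nrow(x$entries), "modifications,",
      length(x$by_keyword), "parent keywords\n")
  invisible(x)
}

#' Vocabulary keywords
#'
#' The set of non-empty parent PTM keywords present in a parsed vocabulary.
#'
#' @param vocab A `ptm_vocabulary`.
#' @return Character vector of keywords.
#' @export
vocabulary_keywords <- function(vocab) {
  stopifnot(inherits(vocab, "ptm_vocabulary"))
  names(vocab$by_keyword)
}

#' Map PTM keywords to exact modifications
#'
#' Looks up, in input order, every vocabulary entry whose parent keyword
#' matches one of `keywords`. Keywords with no vocabulary entry contribute
#' nothing but are reported in the `unmatched` component. Duplicate entries
#' (the same modification reached twice) are dropped.
#'
#' @param vocab A `ptm_vocabulary`.
#' @param keywords Non-empty character vector of PTM keyword strings.
#' @return List with `entries` (data.frame of matched vocabulary rows, in
#'   keyword order) and `unmatched` (character vector of keywords with no
#'   entry).
#' @export
keyword_to_modifications <- function(vocab, keywords) {
  stopifnot(inherits(vocab, "ptm_vocabulary"))
  if (!length(keywords)) stop("'keywords' must be non-empty")
  idx <- integer()
  unmatched <- character()
  for (k in keywords) {
    hit <- vocab$by_keyword[[k]]
    if (is.null(hit)) unmatched <- c(unmatched, k)
    else idx <- c(idx, hit)
  }
  idx <- idx[!duplicated(idx)]
  out <- vocab$entries[idx, , drop = FALSE]
  rownames(out) <- NULL
  list(entries = out, unmatched = unmatched)
}

#' Serialize a vocabulary back to ptmlist dialect
#'
#' Writes the parsed fields back out as `ID ... //` records; re-parsing the
#' result yields an identical entry collection (the parse is lossless for
#' the fields retained).
#'
#' @param vocab A `ptm_vocabulary`.
#' @param path Output file path (or omit to return the lines).
#' @return Invisibly, the character vector of lines written.
#' @export
write_ptm_vocabulary <- function(vocab, path = NULL) {
  stopifnot(inherits(vocab, "ptm_vocabulary"))
  e <- vocab$entries
  fmt_mass <- function(m) formatC(m, format = "fg", digits = 15)
  lines <- unlist(lapply(seq_len(nrow(e)), function(i) {
    r <- e[i, ]
    out <- paste0("ID   ", r$id)
    if (nzchar(r$accession)) out <- c(out, paste0("AC   ", r$accession))
    if (!identical(r$feature_key, "other")) out <- c(out, paste0("FT   ", r$feature_key))
    if (!identical(r$target, "Undefined")) out <- c(out, paste0("TG   ", r$target, "."))
    if (nzchar(r$position)) out <- c(out, paste0("PP   ", r$position, "."))
    if (nzchar(r$correction_formula)) out <- c(out, paste0("CF   ", r$correction_formula))
    if (!is.na(r$mono_mass_delta)) out <- c(out, paste0("MM   ", fmt_mass(r$mono_mass_delta)))
    if (!is.na(r$avg_mass_delta)) out <- c(out, paste0("MA   ", fmt_mass(r$avg_mass_delta)))
    if (nzchar(r$keyword)) out <- c(out, paste0("KW   ", r$keyword, "."))
    c(out, "//")
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Dump a vocabulary as TSV
#'
#' @param vocab A `ptm_vocabulary`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_vocabulary_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "ptm_vocabulary"))
  cols <- c("id", "accession", "feature_key", "target", "position",
            "mono_mass_delta", "avg_mass_delta", "keyword")
  write_tsv(vocab$entries[, cols], path)
}
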