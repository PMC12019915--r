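# Swiss-Prot flat-file parsing (AC/OS/KW/FT subset) and the
# protein <-> PTM-term annotation database.

#' Parse Swiss-Prot style flat-file records
#'
#' Reads a UniProtKB/Swiss-Prot text flat file (plain or gzip-compressed)
#' and extracts, per `//`-terminated record: the accession list (first AC
#' token is the primary accession), the organism name (first OS line with
#' continuations, trailing period stripped), the keyword set (KW lines
#' split on `;`), and the feature table as (feature key, note text) pairs.
#' Only the current FT dialect is supported: a feature key plus location
#' line, with qualifiers on `/note="..."` continuation lines. The pre-2019
#' columnar FT dialect (description on the feature line itself) is rejected.
#'
#' @param path Path to a `.dat` / `.dat.gz` file, or a character vector of
#'   lines.
#' @return List of raw records, each a list with `accessions` (character),
#'   `organism` (string), `keywords` (character), and `features`
#'   (data.frame with columns `key`, `note`).
#' @export
parse_flatfile_records <- function(path) {
  lines <- if (is.character(path) && length(path) > 1L) path else read_lines_enc(path)

  records <- list()
  rec <- NULL
  ordinal <- 0L

  new_rec <- function() list(accessions = character(), os_lines = character(),
                             keywords = character(), ft_key = character(),
                             ft_note_raw = character(), ft_open = FALSE)

  flush_record <- function(rec, ordinal) {
    if (!length(rec$accessions))
      stop("record ", ordinal, " has no AC line")
    notes <- vapply(rec$ft_note_raw, function(raw) {
      m <- regmatches(raw, regexpr('/note="[^"]*"', raw))
      if (length(m)) sub('^/note="', "", sub('"$', "", m)) else ""
    }, "", USE.NAMES = FALSE)
    organism <- strip_trailing_period(paste(rec$os_lines, collapse = " "))
    kw <- trimws2(unlist(strsplit(paste(rec$keywords, collapse = ";"), ";")))
    kw <- strip_trailing_period(kw)
    kw <- unique(kw[nzchar(kw)])
    list(accessions = rec$accessions,
         organism = organism,
         keywords = kw,
         features = data.frame(key = rec$ft_key, note = notes,
                               stringsAsFactors = FALSE))
  }

  in_record <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    code <- substr(line, 1L, 2L)
    if (identical(code, "//")) {
      if (!in_record) next
      ordinal <- ordinal + 1L
      records[[ordinal]] <- flush_record(rec, ordinal)
      in_record <- FALSE
      next
    }
    if (!in_record) {
      rec <- new_rec()
      in_record <- TRUE
    }
    if (nchar(line) < 6L) next
    content <- substring(line, 6L)
    switch(code,
      AC = {
        toks <- trimws2(unlist(strsplit(content, ";")))
        rec$accessions <- c(rec$accessions, toks[nzchar(toks)])
      },
      OS = rec$os_lines <- c(rec$os_lines, trimws2(content)),
      KW = rec$keywords <- c(rec$keywords, trimws2(content)),
      FT = {
        if (!grepl("^\\s", content)) {
          toks <- strsplit(trimws2(content), "\\s+")[[1L]]
          if (length(toks) > 2L)
            stop("line ", i, ": legacy columnar FT dialect is not supported; ",
                 "expected 'FT   KEY   location' with /note=\"...\" qualifiers")
          rec$ft_key <- c(rec$ft_key, toks[1L])
          rec$ft_note_raw <- c(rec$ft_note_raw, "")
          rec$ft_open <- TRUE
        } else if (rec$ft_open) {
          k <- length(rec$ft_note_raw)
          frag <- trimws2(content)
          rec$ft_note_raw[k] <- if (nzchar(rec$ft_note_raw[k]))
            paste(rec$ft_note_raw[k], frag) else frag
        }
      },
      NULL)
  }
  if (in_record)
    stop("unterminated final record (missing '//' after record ",
         ordinal + 1L, ")")
  records
}

PTM_FEATURE_KEYS <- c("MOD_RES", "CROSSLNK", "LIPID")

#' Build the protein-to-PTM-term annotation database
#'
#' Derives each protein's PTM term set from two sources: (1) its UniProt
#' keywords intersected with the PTM keyword universe, and (2) its
#' `MOD_RES` / `CROSSLNK` / `LIPID` features whose note — truncated at the
#' first `;` and stripped of surrounding whitespace — exactly matches a
#' controlled-vocabulary modification name, contributing that entry's
#' parent keyword. Proteins with no PTM terms are retained: they count
#' toward the population size in enrichment tests.
#'
#' @param records Raw records from [parse_flatfile_records()].
#' @param vocab A `ptm_vocabulary`.
#' @param ptm_keywords Optional supplementary PTM keyword list (e.g.,
#'   umbrella keywords such as "Phosphoprotein" from UniProt's keyword
#'   list) joined with the vocabulary's parent keywords to form the
#'   keyword universe.
#' @param source Provenance string stored in `meta`.
#' @return An object of class `ptm_annotation_db`.
#' @export
build_database <- function(records, vocab, ptm_keywords = character(),
                           source = "") {
  stopifnot(inherits(vocab, "ptm_vocabulary"))
  universe <- unique(c(vocabulary_keywords(vocab), ptm_keywords))

  id2kw <- vocab$entries$keyword
  names(id2kw) <- vocab$entries$id

  accs <- character(length(records))
  orgs <- character(length(records))
  kw_list <- vector("list", length(records))
  term_list <- vector("list", length(records))
  aliases <- character()

  for (i in seq_along(records)) {
    r <- records[[i]]
    primary <- r$accessions[1L]
    accs[i] <- primary
    orgs[i] <- r$organism
    kw_list[[i]] <- r$keywords
    terms <- intersect(r$keywords, universe)
    ft <- r$features
    ptm_ft <- ft$key %in% PTM_FEATURE_KEYS
    if (any(ptm_ft)) {
      notes <- trimws2(sub(";.*$", "", ft$note[ptm_ft]))
      hit_kw <- id2kw[notes]
      hit_kw <- hit_kw[!is.na(hit_kw) & nzchar(hit_kw)]
      terms <- union(terms, unname(hit_kw))
    }
    term_list[[i]] <- sort(terms)
    if (length(r$accessions) > 1L) {
      sec <- r$accessions[-1L]
      a <- rep(primary, length(sec)); names(a) <- sec
      aliases <- c(aliases, a)
    }
  }
  if (anyDuplicated(accs))
    stop("duplicate primary accession in input: ",
         accs[duplicated(accs)][1L])
  names(kw_list) <- accs
  names(term_list) <- accs

  new_annotation_db(
    accessions = accs, organisms = orgs, keywords = kw_list,
    ptm_terms = term_list, aliases = aliases,
    meta = list(source = source,
                vocabulary_size = nrow(vocab$entries),
                keyword_universe_size = length(universe),
                built = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                filter = ""))
}

new_annotation_db <- function(accessions, organisms, keywords, ptm_terms,
                              aliases, meta) {
  names(organisms) <- accessions
  term_index <- invert_membership(ptm_terms)
  organism_index <- split(accessions, organisms)
  structure(list(accessions = accessions, organisms = organisms,
                 keywords = keywords, ptm_terms = ptm_terms,
                 aliases = aliases, term_index = term_index,
                 organism_index = organism_index, meta = meta),
            class = "ptm_annotation_db")
}

# term -> sorted accession vector, from accession -> term-set list.
invert_membership <- function(term_list) {
  if (!length(term_list)) return(structure(list(), names = character()))
  lens <- lengths(term_list)
  long_acc <- rep(names(term_list), lens)
  long_term <- unlist(term_list, use.names = FALSE)
  idx <- split(long_acc, long_term)
  lapply(idx, function(a) sort(unique(a)))
}

#' @export
print.ptm_annotation_db <- function(x, ...) {
  cat("PTM annotation database:", length(x$accessions), "proteins,",
      length(x$term_index), "PTM terms,",
      length(x$organism_index), "organisms\n")
  if (nzchar(x$meta$filter %||% ""))
    cat("  organism filter:", x$meta$filter, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of proteins in a database
#' @param db A `ptm_annotation_db`.
#' @return Integer count.
#' @export
db_size <- function(db) length(db$accessions)

#' Resolve user accessions against a database
#'
#' Canonicalizes isoform suffixes (`P12345-2` -> `P12345`), resolves
#' secondary-accession aliases to primary records, and de-duplicates.
#'
#' @param db A `ptm_annotation_db`.
#' @param accessions Character vector of user accessions.
#' @return List with `mapped` (primary accessions found, first-occurrence
#'   order, unique) and `unmapped` (input accessions with no record).
#' @export
map_accessions <- function(db, accessions) {
  canon <- canonical_accession(accessions)
  resolved <- ifelse(canon %in% db$accessions, canon,
                     unname(db$aliases[canon]))
  unmapped <- unique(accessions[is.na(resolved)])
  mapped <- resolved[!is.na(resolved)]
  mapped <- mapped[!duplicated(mapped)]
  list(mapped = mapped, unmapped = unmapped)
}

#' Restrict a database to one organism
#'
#' Keeps proteins whose organism name contains `taxon_name` as a
#' case-insensitive substring and rebuilds all indexes.
#'
#' @param db A `ptm_annotation_db`.
#' @param taxon_name Non-empty taxonomy name fragment, e.g. "Homo sapiens".
#' @return A filtered `ptm_annotation_db`.
#' @export
filter_by_organism <- function(db, taxon_name) {
  stopifnot(inherits(db, "ptm_annotation_db"))
  if (!is.character(taxon_name) || length(taxon_name) != 1L ||
      !nzchar(taxon_name))
    stop("'taxon_name' must be a non-empty string")
  keep <- grepl(taxon_name, db$organisms, ignore.case = TRUE, fixed = FALSE)
  if (!any(keep))
    stop("no protein matches organism '", taxon_name,
         "'; the taxon is absent from this database")
  accs <- db$accessions[keep]
  meta <- db$meta
  meta$filter <- taxon_name
  new_annotation_db(accessions = accs, organisms = unname(db$organisms[accs]),
                    keywords = db$keywords[accs], ptm_terms = db$ptm_terms[accs],
                    aliases = db$aliases[db$aliases %in% accs], meta = meta)
}

#' PTM term frequencies
#'
#' One row per term in the database, with the number of annotated proteins,
#' sorted by descending count and then by term name.
#'
#' @param db A `ptm_annotation_db`.
#' @return data.frame with columns `term`, `count`.
#' @export
term_frequencies <- function(db) {
  stopifnot(inherits(db, "ptm_annotation_db"))
  terms <- names(db$term_index)
  counts <- lengths(db$term_index)
  ord <- order(-counts, terms)
  out <- data.frame(term = terms[ord], count = unname(counts[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

DB_FORMAT <- "ptmenrich-db"
DB_VERSION <- 1L

#' Save / load an annotation database
#'
#' The on-disk format is a versioned, gzip-compressed JSON payload; the
#' round trip is the identity on proteins, indexes, and metadata. Loading a
#' file with a newer version tag, or a corrupted payload, is an error.
#'
#' @param db A `ptm_annotation_db`.
#' @param path File path (conventionally `.json.gz`).
#' @return `save_database` invisibly returns `path`; `load_database`
#'   returns the `ptm_annotation_db`.
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "ptm_annotation_db"))
  payload <- list(
    format = DB_FORMAT, version = DB_VERSION, meta = db$meta,
    accessions = db$accessions, organisms = unname(db$organisms),
    keywords = db$keywords, ptm_terms = db$ptm_terms,
    alias_from = names(db$aliases) %||% character(),
    alias_to = unname(db$aliases))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  payload <- tryCatch({
    txt <- paste(read_lines_enc(path), collapse = "\n")
    jsonlite::fromJSON(txt, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }, error = function(e) stop("corrupted database file '", path, "': ",
                              conditionMessage(e)))
  if (!identical(payload$format, DB_FORMAT))
    stop("'", path, "' is not a ", DB_FORMAT, " file")
  if (payload$version != DB_VERSION)
    stop("database version ", payload$version,
         " is not supported by this build (expected ", DB_VERSION, ")")
  accs <- as.character(unlist(payload$accessions))
  as_chr_list <- function(x, n) {
    out <- lapply(x, function(v) as.character(unlist(v)))
    if (length(out) != n) stop("corrupted database file '", path,
                               "': field length mismatch")
    names(out) <- accs
    out
  }
  aliases <- as.character(unlist(payload$alias_to))
  names(aliases) <- as.character(unlist(payload$alias_from))
  new_annotation_db(
    accessions = accs,
    organisms = as.character(unlist(payload$organisms)),
    keywords = as_chr_list(payload$keywords, length(accs)),
    ptm_terms = as_chr_list(payload$ptm_terms, length(accs)),
    aliases = aliases,
    meta = lapply(payload$meta, function(v) if (is.numeric(v)) v else as.character(v)))
}

#' Build an annotation database from files
#'
#' Convenience wrapper: parse the flat file and the vocabulary, read an
#' optional supplementary PTM keyword list (one keyword per line, `#`
#' comments), and build.
#'
#' @param flatfile Path to the Swiss-Prot style flat file.
#' @param ptmlist Path to the controlled-vocabulary file.
#' @param keyword_file Optional path to a supplementary PTM keyword list.
#' @return A `ptm_annotation_db`.
#' @export
build_database_from_files <- function(flatfile, ptmlist, keyword_file = NULL) {
  vocab <- parse_ptm_vocabulary(ptmlist)
  extra <- if (!is.null(keyword_file)) read_protein_list(keyword_file)
           else character()
  build_database(parse_flatfile_records(flatfile), vocab,
                 ptm_keywords = extra, source = basename(flatfile))
}
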