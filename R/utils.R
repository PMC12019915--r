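# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Open a text connection for a path that may be gzip-compressed.
open_text <- function(path) {
  if (inherits(path, "connection")) return(path)
  stopifnot(is.character(path), length(path) == 1L)
  # gzfile() reads uncompressed text transparently, so it covers both cases
  gzfile(path, open = "rt")
}

# Read all lines, decoding UTF-8 with a Latin-1 fallback (historic UniProt
# files mix encodings).
read_lines_enc <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  bad <- !validUTF8(lines)
  if (any(bad)) lines[bad] <- iconv(lines[bad], from = "latin1", to = "UTF-8")
  lines
}

strip_trailing_period <- function(x) sub("\\.$", "", x)

trimws2 <- function(x) trimws(x, which = "both")

# Strip an isoform suffix ("P12345-2" -> "P12345").
canonical_accession <- function(x) sub("-[0-9]+$", "", x)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive independent per-term permutation sub-seeds so that adding
# or removing one term never perturbs another term's null distribution.
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(enc2utf8(s))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

term_seed <- function(seed, term) {
  as.integer((as.numeric(seed) %% 2147483647 + string_hash(term)) %% 2147483647)
}

# TSV writers/readers used by several modules: plain tab-separated text with
# a header, no quoting surprises, deterministic byte output.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a plain-text protein list
#'
#' One accession per line; blank lines and lines starting with `#` are
#' ignored; inline trailing comments after `#` are stripped.
#'
#' @param path Path to the text file.
#' @return Character vector of accessions in file order.
#' @export
read_protein_list <- function(path) {
  lines <- read_lines_enc(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws2(lines)
  lines[nzchar(lines)]
}

#' Read a two-column scored protein list
#'
#' Tab- or whitespace-separated columns `accession` and `score`; an optional
#' header line is detected (non-numeric second field); `#` comments allowed.
#'
#' @param path Path to the text file.
#' @return data.frame with columns `accession` (character), `score` (numeric).
#' @export
read_scored_list <- function(path) {
  lines <- read_lines_enc(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws2(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("scored list is empty: ", path)
  parts <- strsplit(lines, "[\t ]+")
  bad <- vapply(parts, length, 0L) < 2L
  if (any(bad)) stop("line ", which(bad)[1L], " of ", path,
                     " does not have two columns")
  acc <- vapply(parts, `[[`, "", 1L)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (is.na(sc[1L]) && length(sc) > 1L) {  # header line
    acc <- acc[-1L]; sc <- sc[-1L]
  }
  if (anyNA(sc)) stop("non-numeric score for accession ", acc[which(is.na(sc))[1L]])
  data.frame(accession = acc, score = sc, stringsAsFactors = FALSE)
}
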