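# Synthetic annotation databases, flat-file fixtures, scored lists, and
# intensity tables with known ground truth. Every generator is a pure
# function of its configuration (including the seed), so any result is
# reproducible and any stage of the pipeline is testable without
# downloads.

#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generators.
#' Defaults describe a mid-sized study: a few hundred proteins annotated
#' with a handful of PTM terms at moderate prevalence, one term whose
#' members receive a strong mean score shift against unit-variance noise
#' (treated-vs-control style scores), and triplicate intensity tables.
#'
#' @param n_proteins Number of proteins (>= 10; default 200).
#' @param n_terms Number of PTM terms (default 8).
#' @param prevalence Per-term annotation probability in (0, 1); scalar or
#'   length `n_terms` (default 0.2).
#' @param enriched_term Which term carries the planted signal (default the
#'   first).
#' @param delta Mean score shift for members of the enriched term (>= 0;
#'   default 3; 0 gives an exchangeable null).
#' @param noise Score standard deviation (default 1).
#' @param score_dist `"normal"` (default) or `"t3"` (heavy-tailed, t with
#'   3 df) for robustness checks.
#' @param organism Organism name written into every record.
#' @param n_replicates Replicates per condition in intensity tables
#'   (default 3).
#' @param lfc Planted log2 fold change for enriched-term proteins
#'   (default 1).
#' @param occupancy_ratio Planted modified-peptide occupancy ratio,
#'   treatment vs. control (default 0.5).
#' @param table_noise Multiplicative log2-scale noise SD for intensity
#'   tables (default 0.1, a typical replicate-level variation for
#'   multiplexed quantification; 0 gives noise-free tables for exact
#'   recovery checks).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_proteins = 200, n_terms = 8,
                              prevalence = 0.2, enriched_term = NULL,
                              delta = 3, noise = 1,
                              score_dist = c("normal", "t3"),
                              organism = "Homo sapiens (Human)",
                              n_replicates = 3, lfc = 1,
                              occupancy_ratio = 0.5, table_noise = 0.1,
                              seed = 1L) {
  score_dist <- match.arg(score_dist)
  if (n_proteins < 10) stop("'n_proteins' must be >= 10")
  if (n_terms < 1) stop("'n_terms' must be >= 1")
  prevalence <- as.numeric(unlist(prevalence))
  if (length(prevalence) == 1L) prevalence <- rep(prevalence, n_terms)
  if (length(prevalence) != n_terms)
    stop("'prevalence' must have length 1 or n_terms")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (delta < 0) stop("'delta' must be >= 0")
  if (noise <= 0) stop("'noise' must be > 0")
  terms <- sprintf("SynthPTM%02d", seq_len(n_terms))
  if (is.null(enriched_term)) enriched_term <- terms[1L]
  if (!(enriched_term %in% terms))
    stop("'enriched_term' must be one of the generated terms")
  structure(list(n_proteins = n_proteins, n_terms = n_terms,
                 terms = terms, prevalence = prevalence,
                 enriched_term = enriched_term, delta = delta,
                 noise = noise, score_dist = score_dist,
                 organism = organism, n_replicates = n_replicates,
                 lfc = lfc, occupancy_ratio = occupancy_ratio,
                 table_noise = table_noise, seed = as.integer(seed)),
            class = "sim_config")
}

# Synthetic vocabulary: one exact modification per synthetic keyword.
synthetic_vocabulary <- function(cfg) {
  n <- cfg$n_terms
  entries <- data.frame(
    id = sprintf("O-synthetic-mod-%02d-L-serine", seq_len(n)),
    accession = sprintf("PTM-9%03d", seq_len(n)),
    feature_key = "MOD_RES",
    target = "Serine",
    position = "Anywhere",
    mono_mass_delta = 10 + seq_len(n),
    avg_mass_delta = 10 + seq_len(n) + 0.01,
    correction_formula = "",
    keyword = cfg$terms,
    stringsAsFactors = FALSE)
  new_vocabulary(entries)
}

#' Simulate an annotation database
#'
#' Annotates each protein with each term independently at that term's
#' prevalence, and renders both a matching synthetic controlled vocabulary
#' and a Swiss-Prot dialect flat-file text that parses back to an equal
#' database. Term membership is emitted through KW lines, and additionally
#' through `FT MOD_RES` features (with the synthetic vocabulary's
#' modification name in the note) for a random half of the annotations,
#' exercising both build paths.
#'
#' @param cfg A [simulation_config()].
#' @return List with `db` (a `ptm_annotation_db`), `vocab` (the synthetic
#'   `ptm_vocabulary`), `flatfile` (character vector of flat-file lines),
#'   `ptmlist` (character vector of vocabulary lines), and `truth`
#'   (the membership matrix).
#' @export
simulate_database <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  vocab <- synthetic_vocabulary(cfg)
  accs <- sprintf("P%05d", seq_len(cfg$n_proteins))
  with_seed(cfg$seed, {
    member <- matrix(FALSE, cfg$n_proteins, cfg$n_terms,
                     dimnames = list(accs, cfg$terms))
    for (j in seq_len(cfg$n_terms))
      member[, j] <- stats::runif(cfg$n_proteins) < cfg$prevalence[j]
    via_ft <- member & matrix(stats::runif(length(member)) < 0.5,
                              nrow(member), ncol(member))
    lines <- character()
    for (i in seq_len(cfg$n_proteins)) {
      rec <- c(sprintf("ID   %s_SYNTH              Reviewed;         100 AA.",
                       accs[i]),
               sprintf("AC   %s;", accs[i]),
               sprintf("OS   %s.", cfg$organism))
      kw <- cfg$terms[member[i, ]]
      if (length(kw))
        rec <- c(rec, sprintf("KW   %s.", paste(kw, collapse = "; ")))
      ft_terms <- cfg$terms[via_ft[i, ]]
      for (t in ft_terms) {
        idx <- match(t, vocab$entries$keyword)
        rec <- c(rec,
                 sprintf("FT   MOD_RES         %d", 10 + idx),
                 sprintf("FT                   /note=\"%s; by synthesis\"",
                         vocab$entries$id[idx]))
      }
      lines <- c(lines, rec, "//")
    }
  })
  db <- build_database(parse_flatfile_records(lines), vocab,
                       source = "synthetic")
  list(db = db, vocab = vocab, flatfile = lines,
       ptmlist = write_ptm_vocabulary(vocab), truth = member)
}

#' Simulate a scored protein list with planted enrichment
#'
#' Members of the enriched term draw scores centred at `delta`, all other
#' proteins at 0, with SD `noise` (Gaussian by default, scaled t with 3 df
#' under `score_dist = "t3"`). With `delta = 0` the list is an
#' exchangeable null, used for calibration checks.
#'
#' @param db A `ptm_annotation_db` from [simulate_database()].
#' @param cfg The matching [simulation_config()].
#' @param seed Optional seed override (defaults to `cfg$seed + 1`).
#' @return data.frame with columns `accession`, `score`; attribute `truth`
#'   holds the enriched term and its member accessions.
#' @export
simulate_scored_list <- function(db, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "ptm_annotation_db"))
  if (is.null(seed)) seed <- cfg$seed + 1L
  accs <- db$accessions
  members <- db$term_index[[cfg$enriched_term]] %||% character()
  rnoise <- function(n) switch(cfg$score_dist,
    normal = stats::rnorm(n, 0, cfg$noise),
    t3 = stats::rt(n, df = 3) / sqrt(3) * cfg$noise)
  scores <- with_seed(seed, {
    s <- rnoise(length(accs))
    s[accs %in% members] <- s[accs %in% members] + cfg$delta
    s
  })
  out <- data.frame(accession = accs, score = scores,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(enriched_term = cfg$enriched_term,
                             members = members)
  out
}

#' Simulate expression and peptide tables with planted effects
#'
#' The expression table plants `cfg$lfc` as the log2 fold change of every
#' enriched-term protein (others unchanged) over `n_replicates` control
#' and treatment channels. The peptide table gives every protein one
#' modified and two unmodified peptides; modified-peptide occupancy is
#' scaled by `cfg$occupancy_ratio` under treatment for enriched-term
#' proteins and held constant otherwise, on top of the protein-level
#' abundance change (which the occupancy normalization must cancel).
#' `table_noise > 0` adds i.i.d. log2-scale Gaussian noise.
#'
#' @inheritParams simulate_scored_list
#' @return List with `expression` (data.frame: `accession` + sample
#'   columns), `peptides` (data.frame: `peptide`, `protein`,
#'   `modifications` + channel columns), `groups` /
#'   `peptide_groups` (named condition maps), and `truth`.
#' @export
simulate_expression_tables <- function(db, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "ptm_annotation_db"))
  if (is.null(seed)) seed <- cfg$seed + 2L
  accs <- db$accessions
  members <- db$term_index[[cfg$enriched_term]] %||% character()
  nr <- cfg$n_replicates
  ctrl_cols <- sprintf("control_%d", seq_len(nr))
  treat_cols <- sprintf("treatment_%d", seq_len(nr))
  groups <- c(rep("control", nr), rep("treatment", nr))
  names(groups) <- c(ctrl_cols, treat_cols)

  with_seed(seed, {
    base <- 2^stats::runif(length(accs), 18, 22)          # protein abundance
    lfc_vec <- ifelse(accs %in% members, cfg$lfc, 0)
    jitter <- function(n) 2^stats::rnorm(n, 0, cfg$table_noise)
    expr <- matrix(0, length(accs), 2 * nr,
                   dimnames = list(NULL, c(ctrl_cols, treat_cols)))
    for (r in seq_len(nr)) {
      expr[, ctrl_cols[r]] <- base * jitter(length(accs))
      expr[, treat_cols[r]] <- base * 2^lfc_vec * jitter(length(accs))
    }

    # Peptide table: channel layout control_1..nr then treatment_1..nr.
    pep_rows <- list()
    mod_name <- "O-synthetic-mod-01-L-serine"
    for (i in seq_along(accs)) {
      prot_ctrl <- base[i]
      prot_treat <- base[i] * 2^lfc_vec[i]
      occ <- if (accs[i] %in% members) cfg$occupancy_ratio else 1
      # two unmodified peptides split the backbone signal, one modified
      # peptide at 20% occupancy in control
      add_pep <- function(id, mods, vals) {
        names(vals) <- c(ctrl_cols, treat_cols)
        pep_rows[[length(pep_rows) + 1L]] <<- cbind(
          data.frame(peptide = id, protein = accs[i], modifications = mods,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals), check.names = FALSE))
      }
      for (p in 1:2)
        add_pep(sprintf("%s_pep%d", accs[i], p), "",
                c(rep(prot_ctrl * 0.4, nr), rep(prot_treat * 0.4, nr)) *
                  jitter(2 * nr))
      add_pep(sprintf("%s_pepM", accs[i]), mod_name,
              c(rep(prot_ctrl * 0.2, nr), rep(prot_treat * 0.2 * occ, nr)) *
                jitter(2 * nr))
    }
    peptides <- do.call(rbind, pep_rows)
    rownames(peptides) <- NULL
  })
  expression <- data.frame(accession = accs, expr, check.names = FALSE,
                           stringsAsFactors = FALSE)
  list(expression = expression, peptides = peptides,
       groups = groups, peptide_groups = groups,
       truth = list(enriched_term = cfg$enriched_term, members = members,
                    lfc = cfg$lfc, occupancy_ratio = cfg$occupancy_ratio))
}

#' Write a simulation to a fixture directory
#'
#' Materializes a full synthetic study: flat file, vocabulary, scored
#' list, expression and peptide tables, design files, and the
#' configuration as YAML.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_database(cfg)
  scored <- simulate_scored_list(sim$db, cfg)
  tables <- simulate_expression_tables(sim$db, cfg)
  paths <- c(flatfile = file.path(dir, "records.dat"),
             ptmlist = file.path(dir, "ptmlist.txt"),
             scores = file.path(dir, "scores.tsv"),
             expression = file.path(dir, "expression.tsv"),
             peptides = file.path(dir, "peptides.tsv"),
             design = file.path(dir, "design.tsv"),
             config = file.path(dir, "config.yaml"))
  writeLines(sim$flatfile, paths["flatfile"])
  writeLines(sim$ptmlist, paths["ptmlist"])
  write_tsv(scored, paths["scores"])
  write_tsv(tables$expression, paths["expression"])
  write_tsv(tables$peptides, paths["peptides"])
  write_tsv(data.frame(sample = names(tables$groups),
                       condition = unname(tables$groups),
                       stringsAsFactors = FALSE), paths["design"])
  cfg_list <- unclass(cfg)
  cfg_list$terms <- NULL
  yaml::write_yaml(cfg_list, paths["config"])
  invisible(paths)
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file as written by [write_simulation()] (or
#'   hand-authored with the same keys).
#' @return A `sim_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(simulation_config, raw)
}
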