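#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n desc
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_lgl map_int imap pmap keep
#' @importFrom stats rnorm runif rbeta sd setNames
NULL

# The five evidence columns, in their canonical order.  Everything downstream
# (assembly, training, scoring, ablation) indexes features by these names.
PEDIA_FEATURES <- c("cadd", "gestalt", "feature_match", "phenomizer", "boqa")

#' Construct a single case record
#'
#' A case record holds everything known about one patient prior to exome
#' scoring: the observed HPO terms, the molecularly confirmed diagnosis and
#' causal gene, the deleteriousness score of the causal variant (CADD-PHRED
#' scale), a per-syndrome facial-gestalt similarity vector, and an ethnicity
#' tag used by the exome background simulator.
#'
#' @param case_id Unique case identifier.
#' @param hpo_terms Character vector of HPO term ids (`"HP:NNNNNNN"`); must be
#'   nonempty.
#' @param diagnosis_id Syndrome identifier (OMIM-style string).
#' @param causal_gene Causal gene symbol (nonempty; trimmed, case-sensitive).
#' @param causal_variant_score Nonnegative deleteriousness score of the causal
#'   variant, CADD-PHRED scale.
#' @param gestalt_scores Named numeric vector of nonnegative per-syndrome
#'   gestalt similarities; may be empty (case without a usable photo).
#' @param ethnicity Free background tag (e.g. `"EUR"`, `"AFR"`, `"EAS"`).
#'
#' @return A one-row tibble with list-columns `hpo_terms` and
#'   `gestalt_scores`.
#' @export
case_record <- function(case_id, hpo_terms, diagnosis_id, causal_gene,
                        causal_variant_score, gestalt_scores = numeric(),
                        ethnicity = "EUR") {
  causal_gene <- trimws(causal_gene)
  rec <- tibble(
    case_id = as.character(case_id),
    hpo_terms = list(unique(as.character(hpo_terms))),
    diagnosis_id = as.character(diagnosis_id),
    causal_gene = causal_gene,
    causal_variant_score = as.numeric(causal_variant_score),
    gestalt_scores = list(unlist(gestalt_scores) %||% numeric()),
    ethnicity = as.character(ethnicity)
  )
  stop_if_violations(validate_cases(rec), "invalid case record")
  rec
}

#' Bundle cases (and optionally per-case score tables) into a cohort
#'
#' @param cases Tibble of case records, one row per case (see
#'   [case_record()]).
#' @param tables Optional named list of gene score tables keyed by `case_id`
#'   (see [validate_table()] for the expected shape).
#'
#' @return An object of class `pedia_cohort`: a list with elements `cases`
#'   and `tables`.
#' @export
as_cohort <- function(cases, tables = NULL) {
  cases <- as_tibble(cases)
  stop_if_violations(validate_cases(cases), "invalid cohort")
  if (!is.null(tables)) {
    unknown <- setdiff(names(tables), cases$case_id)
    if (length(unknown) > 0) {
      stop("tables refer to unknown case_ids: ", paste(unknown, collapse = ", "))
    }
  }
  structure(list(cases = cases, tables = tables), class = "pedia_cohort")
}

#' @export
print.pedia_cohort <- function(x, ...) {
  cat(sprintf(
    "<pedia_cohort> %d cases, %d diagnoses, %s score tables\n",
    nrow(x$cases), dplyr::n_distinct(x$cases$diagnosis_id),
    if (is.null(x$tables)) "no" else as.character(length(x$tables))
  ))
  invisible(x)
}

#' Validate case records
#'
#' Checks the case invariants: nonempty HPO term set, nonempty causal gene,
#' nonnegative causal-variant score, nonnegative gestalt entries, and unique
#' case ids.
#'
#' @param cases Tibble of case records.
#' @return Tibble of violations with columns `case_id`, `field`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_cases <- function(cases) {
  v <- list()
  add <- function(case_id, field, message) {
    v[[length(v) + 1]] <<- tibble(case_id = case_id, field = field, message = message)
  }
  dup <- cases$case_id[duplicated(cases$case_id)]
  for (d in unique(dup)) add(d, "case_id", "duplicate case_id")
  for (i in seq_len(nrow(cases))) {
    id <- cases$case_id[[i]]
    if (length(cases$hpo_terms[[i]]) == 0) {
      add(id, "hpo_terms", "hpo_terms must be nonempty")
    }
    if (is.na(cases$causal_gene[[i]]) || !nzchar(cases$causal_gene[[i]])) {
      add(id, "causal_gene", "causal_gene must be nonempty")
    }
    if (!is.finite(cases$causal_variant_score[[i]]) ||
        cases$causal_variant_score[[i]] < 0) {
      add(id, "causal_variant_score", "causal_variant_score must be finite and >= 0")
    }
    gs <- cases$gestalt_scores[[i]]
    if (length(gs) > 0 && (any(!is.finite(gs)) || any(gs < 0))) {
      add(id, "gestalt_scores", "gestalt_scores must be finite and >= 0")
    }
  }
  if (length(v) == 0) {
    tibble(case_id = character(), field = character(), message = character())
  } else {
    bind_rows(v)
  }
}

#' Validate a per-case gene score table
#'
#' A gene score table has one row per candidate gene with the five evidence
#' columns (`cadd`, `gestalt`, `feature_match`, `phenomizer`, `boqa`) and a
#' logical `label` marking the causal gene.  Invariants: all five scores
#' finite, gene symbols unique, exactly one `TRUE` label.
#'
#' @param table Tibble with columns `gene`, the five evidence scores, `label`.
#' @return Tibble of violations (`field`, `message`); zero rows iff valid.
#' @export
validate_table <- function(table) {
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1]] <<- tibble(field = field, message = message)
  }
  needed <- c("gene", PEDIA_FEATURES, "label")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0) {
    add("columns", paste("missing columns:", paste(missing_cols, collapse = ", ")))
  } else {
    dup <- unique(table$gene[duplicated(table$gene)])
    for (g in dup) add("gene", paste0("duplicate gene symbol: ", g))
    n_true <- sum(table$label)
    if (n_true != 1) add("label", sprintf("expected exactly one TRUE label, found %d", n_true))
    for (f in PEDIA_FEATURES) {
      if (any(!is.finite(table[[f]]))) add(f, paste0("non-finite values in ", f))
    }
  }
  if (length(v) == 0) tibble(field = character(), message = character()) else bind_rows(v)
}

stop_if_violations <- function(violations, context) {
  if (nrow(violations) > 0) {
    msgs <- apply(violations, 1, function(r) paste(r[!is.na(r)], collapse = ": "))
    stop(context, ":\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  invisible(NULL)
}

case_to_json_list <- function(cases, i) {
  gs <- cases$gestalt_scores[[i]]
  list(
    case_id = cases$case_id[[i]],
    hpo_terms = as.list(cases$hpo_terms[[i]]),
    diagnosis_id = cases$diagnosis_id[[i]],
    causal_gene = cases$causal_gene[[i]],
    causal_variant_score = cases$causal_variant_score[[i]],
    gestalt_scores = if (length(gs) == 0) setNames(list(), character()) else as.list(gs),
    ethnicity = cases$ethnicity[[i]]
  )
}

case_from_json_list <- function(x, file = "<json>") {
  needed <- c("case_id", "hpo_terms", "diagnosis_id", "causal_gene",
              "causal_variant_score")
  missing_f <- setdiff(needed, names(x))
  if (length(missing_f) > 0) {
    stop(sprintf("case in %s missing fields: %s", file,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  gs <- unlist(x$gestalt_scores) %||% numeric()
  tibble(
    case_id = as.character(x$case_id),
    hpo_terms = list(as.character(unlist(x$hpo_terms))),
    diagnosis_id = as.character(x$diagnosis_id),
    causal_gene = trimws(as.character(x$causal_gene)),
    causal_variant_score = as.numeric(x$causal_variant_score),
    gestalt_scores = list(gs),
    ethnicity = as.character(x$ethnicity %||% "unknown")
  )
}

#' Write a cohort's case records as one JSON file per case
#'
#' @param cohort A `pedia_cohort`.
#' @param dir Output directory (created if absent); one
#'   `<case_id>.json` per case.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- cohort$cases
  for (i in seq_len(nrow(cases))) {
    path <- file.path(dir, paste0(cases$case_id[[i]], ".json"))
    jsonlite::write_json(case_to_json_list(cases, i), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Load a cohort of case records
#'
#' Accepts either a directory of one-JSON-per-case files or a single file
#' (a JSON array, or JSON-lines with one case object per line).  All case
#' invariants are checked; unparseable files are reported by name.
#'
#' @param path Directory of `*.json` case files, or a single JSON / JSON-lines
#'   file.
#' @return A `pedia_cohort` (without score tables).
#' @export
load_cohort <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0) stop("no .json case files found in ", path)
    rows <- map(files, function(f) {
      x <- tryCatch(jsonlite::read_json(f),
                    error = function(e) stop("malformed JSON in ", f, ": ",
                                             conditionMessage(e), call. = FALSE))
      case_from_json_list(x, f)
    })
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    txt <- paste(lines, collapse = "\n")
    parsed <- tryCatch(jsonlite::parse_json(txt), error = function(e) NULL)
    if (!is.null(parsed) && is.list(parsed) && is.null(names(parsed))) {
      rows <- map(parsed, case_from_json_list, file = path)
    } else if (!is.null(parsed) && !is.null(names(parsed))) {
      rows <- list(case_from_json_list(parsed, path))
    } else {
      # JSON-lines: one object per nonblank line
      lines <- lines[nzchar(trimws(lines))]
      rows <- map(seq_along(lines), function(i) {
        x <- tryCatch(jsonlite::parse_json(lines[[i]]),
                      error = function(e) stop("malformed JSON on line ", i,
                                               " of ", path, call. = FALSE))
        case_from_json_list(x, sprintf("%s:%d", path, i))
      })
    }
  } else {
    stop("no such file or directory: ", path)
  }
  cases <- bind_rows(rows)
  stop_if_violations(validate_cases(cases), "cohort validation failed")
  as_cohort(cases)
}

#' Write a ranked result as TSV
#'
#' Emits the ranked candidate list of one case: `gene`, `pedia_score`,
#' `rank`, then the five input evidence scores, ordered by rank (UTF-8,
#' tab-separated, LF endings).
#'
#' @param result A ranked result from [rank_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_output <- function(result, path) {
  stopifnot(nrow(result) > 0)
  out <- result[, c("gene", "pedia_score", "rank", PEDIA_FEATURES)]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a ranked-output TSV back into a tibble
#'
#' @param path TSV written by [write_ranked_output()].
#' @return Tibble ordered by rank.
#' @export
read_ranked_output <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write per-case gene score tables as TSV files
#'
#' @param tables Named list of gene score tables keyed by case id.
#' @param dir Output directory; one `<case_id>.tsv` per table.
#' @return `dir`, invisibly.
#' @export
write_score_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(tables)) {
    readr::write_tsv(tables[[id]][, c("gene", PEDIA_FEATURES, "label")],
                     file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read per-case gene score tables from a directory of TSV files
#'
#' @param dir Directory of `<case_id>.tsv` files as written by
#'   [write_score_tables()].
#' @return Named list of score-table tibbles.
#' @export
read_score_tables <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  tables <- map(files, function(f) {
    tb <- readr::read_tsv(f, show_col_types = FALSE,
                          col_types = readr::cols(gene = "c", label = "l",
                                                  .default = "d"))
    stop_if_violations(validate_table(tb), paste("invalid score table", f))
    tb
  })
  names(tables) <- sub("\\.tsv$", "", basename(files))
  tables
}
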