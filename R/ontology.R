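#' Parse a minimal OBO 1.2 flat file into an ontology graph
#'
#' Reads `[Term]` stanzas and the `id`, `name`, `is_a` and `is_obsolete` tags.
#' Obsolete terms are recorded but excluded from the DAG.  The graph must be
#' acyclic with a single root (a non-obsolete term without `is_a` parents)
#' reachable from every term.
#'
#' @param path Path to an OBO 1.2 file.
#' @return An object of class `pedia_ontology`: list with `terms` (character),
#'   `parents` (named list, child -> character vector of parents), `names`
#'   (named character), `root`, `obsolete`, and a memoised `ancestors`
#'   closure (named list; each term's closure includes the term itself).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character()
  names_map <- character()
  parents <- list()
  obsolete <- character()

  cur_id <- NULL
  cur_name <- NA_character_
  cur_parents <- character()
  cur_obsolete <- FALSE
  in_term <- FALSE

  flush <- function() {
    if (is.null(cur_id)) return()
    if (cur_obsolete) {
      obsolete <<- c(obsolete, cur_id)
    } else {
      terms <<- c(terms, cur_id)
      names_map[cur_id] <<- cur_name
      parents[[cur_id]] <<- cur_parents
    }
  }

  for (line in lines) {
    line <- sub("!.*$", "", line)  # strip trailing comments
    line <- trimws(line)
    if (line == "[Term]") {
      flush()
      cur_id <- NULL; cur_name <- NA_character_
      cur_parents <- character(); cur_obsolete <- FALSE
      in_term <- TRUE
    } else if (grepl("^\\[", line)) {
      flush()
      cur_id <- NULL
      in_term <- FALSE
    } else if (in_term && grepl("^id:", line)) {
      cur_id <- trimws(sub("^id:", "", line))
    } else if (in_term && grepl("^name:", line)) {
      cur_name <- trimws(sub("^name:", "", line))
    } else if (in_term && grepl("^is_a:", line)) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", line)))
    } else if (in_term && grepl("^is_obsolete:", line)) {
      cur_obsolete <- tolower(trimws(sub("^is_obsolete:", "", line))) == "true"
    }
  }
  flush()

  build_ontology(terms, parents, names_map, obsolete)
}

build_ontology <- function(terms, parents, names_map = NULL, obsolete = character()) {
  if (length(terms) == 0) stop("ontology has no terms")
  # drop is_a edges pointing at obsolete/unknown terms
  parents <- lapply(parents[terms], function(p) intersect(p, terms))
  names(parents) <- terms
  roots <- terms[vapply(parents, length, 1L) == 0]
  if (length(roots) == 0) stop("ontology format error: no root term (is_a cycle?)")
  if (length(roots) > 1) {
    stop("ontology format error: multiple roots: ", paste(roots, collapse = ", "))
  }
  onto <- structure(
    list(terms = terms, parents = parents,
         names = names_map %||% setNames(rep(NA_character_, length(terms)), terms),
         root = roots, obsolete = obsolete),
    class = "pedia_ontology"
  )
  onto$ancestors <- compute_ancestor_closure(onto)
  onto
}

# Memoised ancestor closure over all is_a paths (multi-parent supported);
# detects cycles while walking.
compute_ancestor_closure <- function(onto) {
  closure <- vector("list", length(onto$terms))
  names(closure) <- onto$terms
  visiting <- character()
  walk <- function(t) {
    if (!is.null(closure[[t]])) return(closure[[t]])
    if (t %in% visiting) stop("ontology format error: is_a cycle through ", t)
    visiting <<- c(visiting, t)
    anc <- t
    for (p in onto$parents[[t]]) anc <- union(anc, walk(p))
    visiting <<- setdiff(visiting, t)
    closure[[t]] <<- anc
    anc
  }
  for (t in onto$terms) walk(t)
  closure
}

#' @export
print.pedia_ontology <- function(x, ...) {
  cat(sprintf("<pedia_ontology> %d terms, root %s, %d obsolete\n",
              length(x$terms), x$root, length(x$obsolete)))
  invisible(x)
}

#' Ancestor closure of a set of terms
#'
#' @param onto A `pedia_ontology`.
#' @param terms Character vector of term ids (must be in the DAG).
#' @return Character vector: union of each term's ancestors, including the
#'   terms themselves.
#' @export
term_closure <- function(onto, terms) {
  missing_t <- setdiff(terms, onto$terms)
  if (length(missing_t) > 0) {
    stop("terms not in ontology: ", paste(missing_t, collapse = ", "))
  }
  unique(unlist(onto$ancestors[terms], use.names = FALSE))
}

#' Write an ontology back to minimal OBO 1.2
#'
#' @param onto A `pedia_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in onto$terms) {
    nm <- onto$names[[t]]
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      if (!is.na(nm)) paste0("name: ", nm),
      paste0("is_a: ", onto$parents[[t]]),
      ""
    ), con)
  }
  for (t in onto$obsolete) {
    writeLines(c("[Term]", paste0("id: ", t), "is_obsolete: true", ""), con)
  }
  invisible(path)
}

#' Read a disease-to-HPO annotation catalog
#'
#' Minimal two-column TSV dialect: `disease_id <TAB> term_id`, one pair per
#' line; `#` comment lines skipped.
#'
#' @param path TSV path.
#' @param onto Optional ontology; if given, every annotated term must exist
#'   in it.
#' @return A named list mapping `disease_id` to a character vector of term
#'   ids (the annotation catalog).
#' @export
read_disease_annotations <- function(path, onto = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad) > 0) stop("malformed annotation line ", bad[1], " in ", path)
  df <- tibble(disease_id = map_chr(parts, 1), term_id = map_chr(parts, 2))
  catalog <- split(df$term_id, df$disease_id)
  catalog <- lapply(catalog, unique)
  validate_catalog(catalog, onto)
  catalog
}

validate_catalog <- function(catalog, onto = NULL) {
  if (any(vapply(catalog, length, 1L) == 0)) stop("catalog has empty term sets")
  if (!is.null(onto)) {
    unknown <- setdiff(unique(unlist(catalog)), onto$terms)
    if (length(unknown) > 0) {
      stop("annotated terms not in ontology: ", paste(unknown, collapse = ", "))
    }
  }
  invisible(catalog)
}

#' Write an annotation catalog as two-column TSV
#'
#' @param catalog Named list disease_id -> term ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_annotations <- function(catalog, path) {
  df <- tibble(disease_id = rep(names(catalog), lengths(catalog)),
               term_id = unlist(catalog, use.names = FALSE))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Information content of every ontology term under a disease catalog
#'
#' The information content of term `t` is `-ln(n_t / N)` where `n_t` counts
#' diseases annotated to `t` directly or via any descendant (i.e. whose
#' ancestor-propagated annotation closure contains `t`) and `N` is the number
#' of diseases in the catalog.  Terms that no disease reaches receive the
#' fallback `max(ic) + ln 2` (treated as maximally informative), which
#' preserves parent-to-child monotonicity.
#'
#' @param onto A `pedia_ontology`.
#' @param catalog Named list disease_id -> annotated term ids.
#' @return Named numeric vector of per-term information content (natural-log
#'   units); `ic[root] == 0`.
#' @export
compute_ic <- function(onto, catalog) {
  validate_catalog(catalog, onto)
  n_dis <- length(catalog)
  counts <- setNames(integer(length(onto$terms)), onto$terms)
  for (terms in catalog) {
    cl <- term_closure(onto, terms)
    counts[cl] <- counts[cl] + 1L
  }
  ic <- setNames(rep(NA_real_, length(onto$terms)), onto$terms)
  seen <- counts > 0
  ic[seen] <- -log(counts[seen] / n_dis)
  if (any(!seen)) ic[!seen] <- max(ic[seen]) + log(2)
  ic
}

#' Resnik similarity of two terms
#'
#' The maximum information content over the common ancestors of `t1` and
#' `t2` (each term counts as its own ancestor).  Zero when the only shared
#' ancestor is the root.
#'
#' @param t1,t2 Term ids (must be in the DAG).
#' @param onto A `pedia_ontology`.
#' @param ic Named IC vector from [compute_ic()].
#' @return Nonnegative similarity (natural-log units).
#' @export
resnik_term_sim <- function(t1, t2, onto, ic) {
  common <- intersect(term_closure(onto, t1), term_closure(onto, t2))
  max(ic[common])
}

# Dense term-by-term Resnik matrix; used to make repeated best-match-average
# queries cheap on small ontologies.
term_sim_matrix <- function(onto, ic) {
  n <- length(onto$terms)
  # binary term-by-ancestor incidence, then max IC over shared ancestors
  inc <- matrix(FALSE, n, n, dimnames = list(onto$terms, onto$terms))
  for (t in onto$terms) inc[t, onto$ancestors[[t]]] <- TRUE
  sim <- matrix(0, n, n, dimnames = list(onto$terms, onto$terms))
  ord <- order(ic[onto$terms])  # ascending; later (higher IC) overwrites
  for (a in onto$terms[ord]) {
    has <- inc[, a]
    sim[has, has] <- ic[[a]]
  }
  sim
}

#' Symmetric best-match-average semantic similarity (Phenomizer-style)
#'
#' Averages, in both directions, each term's best Resnik match on the other
#' side: `0.5 * (mean_q max_d sim(q, d) + mean_d max_q sim(q, d))` for query
#' terms `q` and disease annotation terms `d`.
#'
#' @param query_terms Nonempty character vector of query term ids.
#' @param disease_id Disease to compare against.
#' @param catalog Annotation catalog (named list).
#' @param onto A `pedia_ontology`.
#' @param ic Named IC vector.
#' @param sim Optional precomputed matrix from `term_sim_matrix()`.
#' @return Nonnegative similarity score.
#' @export
symmetric_bma_score <- function(query_terms, disease_id, catalog, onto, ic,
                                sim = NULL) {
  if (length(query_terms) == 0) stop("query_terms must be nonempty")
  if (!disease_id %in% names(catalog)) stop("disease not in catalog: ", disease_id)
  dterms <- catalog[[disease_id]]
  if (is.null(sim)) {
    m <- outer(query_terms, dterms,
               Vectorize(function(a, b) resnik_term_sim(a, b, onto, ic)))
  } else {
    m <- sim[query_terms, dterms, drop = FALSE]
  }
  0.5 * (mean(apply(m, 1, max)) + mean(apply(m, 2, max)))
}

#' Bayesian ontology query: posterior over diseases given observed terms
#'
#' Exact enumeration of the noisy-observation likelihood.  With query closure
#' `Q`, disease annotation closure `A` and term universe `T`, the likelihood
#' is `alpha^|Q\\A| * (1-alpha)^|T\\(Q u A)| * beta^|A\\Q| * (1-beta)^|A n Q|`
#' (false positives at rate `alpha`, false negatives at rate `beta`); the
#' posterior is the prior-weighted likelihood normalised over diseases.
#' Computed in log space.
#'
#' @param query_terms Character vector of observed term ids.
#' @param catalog Annotation catalog.
#' @param onto A `pedia_ontology`.
#' @param alpha False-positive probability, in (0,1).
#' @param beta False-negative probability, in (0,1).
#' @param prior Named prior over diseases (defaults to uniform); must sum
#'   to 1.
#' @param closures Optional precomputed per-disease annotation closures
#'   (named list), to avoid recomputation in repeated queries.
#' @return Tibble with columns `disease_id`, `posterior`; posteriors sum
#'   to 1.
#' @export
boqa_score <- function(query_terms, catalog, onto, alpha = 0.001, beta = 0.1,
                       prior = NULL, closures = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (!(beta > 0 && beta < 1)) stop("beta must be in (0,1)")
  diseases <- names(catalog)
  if (is.null(prior)) {
    prior <- setNames(rep(1 / length(diseases), length(diseases)), diseases)
  }
  if (abs(sum(prior[diseases]) - 1) > 1e-9) stop("prior must sum to 1")
  qc <- term_closure(onto, query_terms)
  n_terms <- length(onto$terms)
  if (is.null(closures)) closures <- lapply(catalog, function(ts) term_closure(onto, ts))
  loglik <- vapply(diseases, function(d) {
    ac <- closures[[d]]
    n_qa <- length(intersect(qc, ac))          # observed & annotated
    n_q_only <- length(qc) - n_qa              # observed, not annotated
    n_a_only <- length(ac) - n_qa              # annotated, missed
    n_neither <- n_terms - length(qc) - n_a_only
    n_q_only * log(alpha) + n_neither * log1p(-alpha) +
      n_a_only * log(beta) + n_qa * log1p(-beta)
  }, 1.0)
  lp <- loglik + log(prior[diseases])
  post <- exp(lp - max(lp))
  tibble(disease_id = diseases, posterior = as.numeric(post / sum(post)))
}

#' Closure-overlap feature match score
#'
#' Jaccard overlap of the ancestor closures of the query and the disease
#' annotation: `|closure(Q) n closure(A)| / |closure(Q) u closure(A)|`.
#' This is the package's clinical-feature similarity column; the scorer slot
#' in [score_all_diseases()] is pluggable so externally computed feature
#' scores can be injected instead.
#'
#' @inheritParams symmetric_bma_score
#' @return Score in `[0, 1]`.
#' @export
feature_match_score <- function(query_terms, disease_id, catalog, onto) {
  if (length(query_terms) == 0) stop("query_terms must be nonempty")
  qc <- term_closure(onto, query_terms)
  ac <- term_closure(onto, catalog[[disease_id]])
  length(intersect(qc, ac)) / length(union(qc, ac))
}

#' Score every disease in a catalog against a phenotype query
#'
#' Runs the three HPO-based scorers (feature match, symmetric
#' best-match-average, Bayesian ontology query) for each disease.
#'
#' @param query_terms Character vector of observed HPO term ids.
#' @param catalog Annotation catalog (named list, nonempty).
#' @param onto A `pedia_ontology`.
#' @param ic Named IC vector (computed from `onto`/`catalog` if omitted).
#' @param alpha,beta,prior Bayesian-query noise parameters and prior; see
#'   [boqa_score()].
#' @param sim Optional precomputed term similarity matrix.
#' @param feature_scorer Optional function `(query_terms, disease_id,
#'   catalog, onto)` replacing the feature-match column (the pluggable slot
#'   for externally computed clinical-feature scores); by default the
#'   closure-Jaccard of [feature_match_score()] is computed internally.
#' @return Tibble with one row per disease: `disease_id`, `feature_match`,
#'   `phenomizer`, `boqa` (posteriors sum to 1).
#' @export
score_all_diseases <- function(query_terms, catalog, onto, ic = NULL,
                               alpha = 0.001, beta = 0.1, prior = NULL,
                               sim = NULL, feature_scorer = NULL) {
  if (length(catalog) == 0) stop("catalog must be nonempty")
  if (is.null(ic)) ic <- compute_ic(onto, catalog)
  diseases <- names(catalog)
  closures <- lapply(catalog, function(ts) term_closure(onto, ts))
  qc <- term_closure(onto, query_terms)
  fm <- if (is.null(feature_scorer)) {
    vapply(closures, function(ac)
      length(intersect(qc, ac)) / length(union(qc, ac)), 1.0)
  } else {
    vapply(diseases, function(d) feature_scorer(query_terms, d, catalog, onto), 1.0)
  }
  ph <- vapply(diseases, function(d)
    symmetric_bma_score(query_terms, d, catalog, onto, ic, sim = sim), 1.0)
  bq <- boqa_score(query_terms, catalog, onto, alpha = alpha, beta = beta,
                   prior = prior, closures = closures)
  tibble(disease_id = diseases,
         feature_match = as.numeric(fm),
         phenomizer = as.numeric(ph)) |>
    left_join(bq, by = "disease_id") |>
    dplyr::rename(boqa = "posterior")
}
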