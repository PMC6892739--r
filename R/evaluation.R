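#' Gene-disjoint fold assignment
#'
#' Groups cases by causal gene so that every case sharing a causal gene
#' lands in the same fold — preventing the same disease variant from
#' appearing in both training and test sets — then packs gene groups into
#' `k` folds greedily largest-first (balancing case counts), with seeded
#' shuffling of equal-sized groups.
#'
#' @param cohort A `pedia_cohort`.
#' @param k Number of folds (requires at least `k` distinct causal genes).
#' @param seed Integer seed for the tie shuffle.
#' @return Tibble `case_id`, `fold` (0-based fold index), with attribute
#'   `k`.
#' @export
gene_disjoint_folds <- function(cohort, k = 10, seed = 1L) {
  cases <- cohort$cases
  genes <- unique(cases$causal_gene)
  if (length(genes) < k) {
    stop("fewer distinct causal genes (", length(genes), ") than folds (", k, ")")
  }
  groups <- split(cases$case_id, cases$causal_gene)
  sizes <- lengths(groups)
  ord <- with_local_seed(seed, {
    shuffled <- sample(seq_along(groups))     # random order breaks size ties
    shuffled[order(sizes[shuffled], decreasing = TRUE)]
  })
  fold_load <- integer(k)
  assignment <- integer(length(groups))
  for (g in ord) {
    f <- which.min(fold_load)                  # ties -> lowest fold index
    assignment[[g]] <- f
    fold_load[[f]] <- fold_load[[f]] + sizes[[g]]
  }
  out <- tibble(
    case_id = unlist(groups, use.names = FALSE),
    fold = rep(assignment - 1L, sizes)
  )
  out <- out[match(cases$case_id, out$case_id), ]
  structure(out, k = as.integer(k))
}

#' Top-k accuracy from per-case causal ranks
#'
#' @param per_case_rank Named integer vector (or tibble `case_id`, `rank`)
#'   of causal-gene ranks, all >= 1.
#' @param k Rank cutoff.
#' @return Fraction of cases whose causal gene ranks within the top `k`.
#' @export
topk_accuracy <- function(per_case_rank, k) {
  ranks <- if (is.data.frame(per_case_rank)) per_case_rank$rank else per_case_rank
  if (length(ranks) == 0) stop("empty rank map")
  mean(ranks <= k)
}

#' Rank-sensitivity curve
#'
#' Sensitivity at maximum rank `r` is the top-`r` accuracy; the curve's
#' values at 1 and 10 are the usual top-1 and top-10 accuracy rates.
#'
#' @param per_case_rank Causal ranks as in [topk_accuracy()].
#' @param max_rank Largest rank cutoff to evaluate.
#' @return Tibble `max_rank` (1..`max_rank`), `sensitivity` (non-decreasing).
#' @export
rank_sensitivity_curve <- function(per_case_rank, max_rank = 100) {
  stopifnot(max_rank >= 1)
  rs <- seq_len(max_rank)
  tibble(
    max_rank = rs,
    sensitivity = vapply(rs, function(r) topk_accuracy(per_case_rank, r), 1.0)
  )
}

new_eval_report <- function(per_case_rank, topk = c(1, 10), max_rank = 100,
                            combo = PEDIA_FEATURES, extra = list()) {
  structure(c(list(
    per_case_rank = per_case_rank,
    topk = tibble(k = topk,
                  accuracy = vapply(topk, function(k)
                    topk_accuracy(per_case_rank, k), 1.0)),
    curve = rank_sensitivity_curve(per_case_rank, max_rank),
    combo = combo
  ), extra), class = "pedia_eval")
}

#' @export
print.pedia_eval <- function(x, ...) {
  cat(sprintf("<pedia_eval> %d cases, features: %s\n",
              nrow(x$per_case_rank), paste(x$combo, collapse = "+")))
  for (i in seq_len(nrow(x$topk))) {
    cat(sprintf("  top-%-3d accuracy: %.3f\n", x$topk$k[[i]], x$topk$accuracy[[i]]))
  }
  invisible(x)
}

#' Tidy an evaluation report into per-case ranks
#'
#' @param x A `pedia_eval`.
#' @param ... Unused.
#' @return Tibble `case_id`, `rank`.
#' @method tidy pedia_eval
#' @export
tidy.pedia_eval <- function(x, ...) x$per_case_rank

#' One-row evaluation summary
#'
#' @param x A `pedia_eval`.
#' @param ... Unused.
#' @return Tibble with one `top_<k>` column per requested cutoff plus
#'   `n_cases` and `combo`.
#' @method glance pedia_eval
#' @export
glance.pedia_eval <- function(x, ...) {
  out <- as.list(setNames(x$topk$accuracy, paste0("top_", x$topk$k)))
  out$n_cases <- nrow(x$per_case_rank)
  out$combo <- paste(x$combo, collapse = "+")
  as_tibble(out)
}

#' Gene-disjoint cross-validation of the full pipeline
#'
#' For each fold, the cost `C` is selected and a model trained on the other
#' folds' tables, and the held-out cases are ranked.  Every case is scored
#' exactly once, by a model that never saw its causal gene.
#'
#' @param cohort A `pedia_cohort` with assembled score tables.
#' @param config A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment and internal shuffles.
#' @param features Feature columns used (default all five).
#' @param folds Optional precomputed [gene_disjoint_folds()] assignment
#'   (shared across ablation combos).
#' @param topk,max_rank Evaluation cutoffs.
#' @return A `pedia_eval` report (per-case ranks, top-k accuracies,
#'   rank-sensitivity curve), with the fold assignment attached.
#' @export
cross_validate <- function(cohort, config = classifier_config(), k = 10,
                           seed = 1L, features = PEDIA_FEATURES, folds = NULL,
                           topk = c(1, 10), max_rank = 100) {
  if (is.null(cohort$tables)) stop("cohort has no assembled score tables")
  if (is.null(folds)) folds <- gene_disjoint_folds(cohort, k, seed)
  kk <- attr(folds, "k")
  rank_rows <- list()
  for (f in 0:(kk - 1)) {
    test_ids <- folds$case_id[folds$fold == f]
    train_ids <- folds$case_id[folds$fold != f]
    if (length(test_ids) == 0) next
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, f)
    model <- train_model(cohort$tables[train_ids], fold_config, features)
    for (id in test_ids) {
      rank_rows[[length(rank_rows) + 1]] <- tibble(
        case_id = id, fold = f,
        rank = causal_rank(rank_genes(model, cohort$tables[[id]]))
      )
    }
  }
  per_case <- arrange(bind_rows(rank_rows), .data$case_id)
  new_eval_report(per_case, topk = topk, max_rank = max_rank, combo = features,
                  extra = list(folds = folds))
}

# derive independent 31-bit substream seeds from a base seed
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729 + 17) %% 2147483647)
}

#' Ablation over score combinations
#'
#' Re-runs gene-disjoint cross-validation for each requested subset of the
#' five evidence columns, shrinking the feature vector to the active columns
#' (a single-score combo therefore reduces to sorting by that score) and
#' sharing the fold assignment and seed across combos.
#'
#' @param cohort A `pedia_cohort` with tables.
#' @param combos List of nonempty character vectors of feature names.
#' @param config A [classifier_config()].
#' @param k,seed,topk,max_rank As in [cross_validate()].
#' @return Named list of `pedia_eval` reports, in the order of `combos`
#'   (names are `+`-joined feature sets).
#' @export
ablation_grid <- function(cohort, combos, config = classifier_config(), k = 10,
                          seed = 1L, topk = c(1, 10), max_rank = 100) {
  bad <- vapply(combos, function(cm)
    length(cm) == 0 || !all(cm %in% PEDIA_FEATURES), TRUE)
  if (any(bad)) stop("each combo must be a nonempty subset of: ",
                     paste(PEDIA_FEATURES, collapse = ", "))
  folds <- gene_disjoint_folds(cohort, k, seed)
  reports <- map(combos, function(cm)
    cross_validate(cohort, config, k = k, seed = seed, features = cm,
                   folds = folds, topk = topk, max_rank = max_rank))
  names(reports) <- map_chr(combos, paste, collapse = "+")
  reports
}

#' Summarise an ablation grid as one row per combination
#'
#' @param reports Output of [ablation_grid()].
#' @return Tibble `combo`, one `top_<k>` column per cutoff, `n_cases`.
#' @export
ablation_summary <- function(reports) {
  bind_rows(map(reports, glance))
}

#' Score-borrowing transfer evaluation for phenotype-only cases
#'
#' Evaluates cases that carry only phenotype information (a gestalt vector
#' and a diagnosis) by borrowing the molecular and clinical-feature columns
#' (`cadd`, `feature_match`, `phenomizer`, `boqa`) of a uniformly sampled
#' same-diagnosis donor case from the training cohort; the donor's gene
#' table and causal label are inherited while the gestalt column is replaced
#' with the test case's own gene-mapped gestalt scores.  Training cases
#' sharing a test case's causal variant (same causal gene and variant score)
#' are removed from the training set.  The sampling is repeated and top-k
#' accuracies are summarised as mean and SD over repeats (SD is 0 by
#' convention for a single repeat).
#'
#' @param train_cohort A `pedia_cohort` with tables.
#' @param phenotype_only_cases Tibble of case records to evaluate; their
#'   `gestalt_scores` are used, their (`causal_gene`,
#'   `causal_variant_score`) only for donor exclusion.
#' @param map A `gene_phenotype_map` used to map gestalt vectors to genes.
#' @param repeats Number of random donor selections (default 10).
#' @param seed Integer seed.
#' @param config A [classifier_config()].
#' @param topk Rank cutoffs (default 1 and 10).
#' @param fill Fill for genes without a mapped gestalt score.
#' @return Tibble `k`, `mean_accuracy`, `sd_accuracy` over repeats, with the
#'   per-repeat accuracies attached as attribute `per_repeat`.
#' @export
transfer_augment_evaluate <- function(train_cohort, phenotype_only_cases, map,
                                      repeats = 10, seed = 1L,
                                      config = classifier_config(),
                                      topk = c(1, 10), fill = 0) {
  train_cases <- train_cohort$cases
  donors_by_diag <- split(train_cases$case_id, train_cases$diagnosis_id)
  missing_diag <- setdiff(unique(phenotype_only_cases$diagnosis_id),
                          names(donors_by_diag))
  if (length(missing_diag) > 0) {
    stop("no donor case for diagnosis: ", paste(missing_diag, collapse = ", "))
  }
  # exclude training cases sharing a test case's causal variant
  test_variants <- paste(phenotype_only_cases$causal_gene,
                         phenotype_only_cases$causal_variant_score)
  excluded <- train_cases$case_id[
    paste(train_cases$causal_gene, train_cases$causal_variant_score) %in% test_variants]
  keep_ids <- setdiff(train_cases$case_id, excluded)
  model <- train_model(train_cohort$tables[keep_ids], config)

  per_repeat <- lapply(seq_len(repeats), function(r) {
    rep_seed <- derive_seed(seed, r)
    ranks <- with_local_seed(rep_seed, {
      vapply(seq_len(nrow(phenotype_only_cases)), function(i) {
        case <- phenotype_only_cases[i, ]
        donors <- donors_by_diag[[case$diagnosis_id]]
        donor_id <- donors[[sample.int(length(donors), 1)]]
        donor_tb <- train_cohort$tables[[donor_id]]
        gest <- map_scores_to_genes(case$gestalt_scores[[1]], map)
        v <- gest$score[match(donor_tb$gene, gest$gene)]
        aug <- donor_tb
        aug$gestalt <- ifelse(is.na(v), fill, v)
        causal_rank(rank_genes(model, aug))
      }, 1L)
    })
    vapply(topk, function(k) topk_accuracy(ranks, k), 1.0)
  })
  accs <- do.call(rbind, per_repeat)
  colnames(accs) <- paste0("top_", topk)
  out <- tibble(
    k = topk,
    mean_accuracy = unname(colMeans(accs)),
    sd_accuracy = if (repeats == 1) rep(0, length(topk))
                  else unname(apply(accs, 2, sd))
  )
  attr(out, "per_repeat") <- as_tibble(accs)
  out
}

#' Write an evaluation report as JSON plus TSV tables
#'
#' @param report A `pedia_eval`.
#' @param dir Output directory; writes `report.json`, `topk.tsv`,
#'   `curve.tsv`, `per_case_rank.tsv`.
#' @param prefix Optional filename prefix (used by the ablation command).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(nm) file.path(dir, paste0(prefix, nm))
  jsonlite::write_json(list(
    combo = report$combo,
    topk = setNames(as.list(report$topk$accuracy), paste0("top_", report$topk$k)),
    per_case_rank = setNames(as.list(report$per_case_rank$rank),
                             report$per_case_rank$case_id)
  ), p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(report$topk, p("topk.tsv"))
  readr::write_tsv(report$curve, p("curve.tsv"))
  readr::write_tsv(report$per_case_rank, p("per_case_rank.tsv"))
  invisible(dir)
}
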