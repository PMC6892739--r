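test_that("gene-disjoint folds keep shared causal genes together and partition the cohort", {
  cases <- random_cases(20, n_genes = 8)
  cohort <- as_cohort(cases)
  folds <- gene_disjoint_folds(cohort, k = 4, seed = 3)
  expect_setequal(folds$case_id, cases$case_id)
  expect_equal(anyDuplicated(folds$case_id), 0)
  by_gene <- split(folds$fold, cases$causal_gene[match(folds$case_id, cases$case_id)])
  for (f in by_gene) expect_equal(length(unique(f)), 1)
})

test_that("one case per gene with k genes gives one case per fold", {
  cases <- random_cases(10, n_genes = 10)
  cases$causal_gene <- sprintf("CG%02d", 1:10)  # force distinct
  folds <- gene_disjoint_folds(as_cohort(cases), k = 10, seed = 1)
  expect_equal(sort(as.vector(table(folds$fold))), rep(1L, 10))
  expect_error(gene_disjoint_folds(as_cohort(cases), k = 11),
               "fewer distinct causal genes")
})

test_that("fold partition audit holds over randomised cohorts", {
  set.seed(601)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    cases <- random_cases(n, n_genes = sample(5:12, 1))
    k <- sample(2:5, 1)
    folds <- gene_disjoint_folds(as_cohort(cases), k, seed = i)
    expect_setequal(folds$case_id, cases$case_id)
    gene_of <- setNames(cases$causal_gene, cases$case_id)
    spread <- tapply(folds$fold, gene_of[folds$case_id],
                     function(f) length(unique(f)))
    expect_true(all(spread == 1))
    expect_true(all(folds$fold %in% 0:(k - 1)))
  }
})

test_that("top-k accuracy and the rank-sensitivity curve match counting oracles", {
  ranks <- c(1, 2, 11, 3)
  expect_equal(topk_accuracy(ranks, 1), 0.25)
  expect_equal(topk_accuracy(ranks, 10), 0.75)
  expect_equal(topk_accuracy(rep(1, 5), 1), 1)
  expect_error(topk_accuracy(numeric(), 1), "empty")

  curve <- rank_sensitivity_curve(3, max_rank = 5)
  expect_equal(curve$sensitivity, c(0, 0, 1, 1, 1))

  set.seed(602)
  for (i in 1:20) {
    ranks <- sample.int(50, 30, replace = TRUE)
    k <- sample.int(20, 1)
    expect_equal(topk_accuracy(ranks, k), sum(ranks <= k) / length(ranks))
    curve <- rank_sensitivity_curve(ranks, 25)
    expect_equal(curve$sensitivity,
                 vapply(1:25, function(r) mean(ranks <= r), 1.0))
    expect_true(all(diff(curve$sensitivity) >= 0))
  }
  expect_equal(curve$sensitivity[1], topk_accuracy(ranks, 1))
})

test_that("cross-validation covers every case exactly once and never leaks genes", {
  cohort <- small_cohort(seed = 61, n_cases = 24, n_diseases = 8)
  report <- cross_validate(cohort, fast_config(), k = 4, seed = 5)
  expect_setequal(report$per_case_rank$case_id, cohort$cases$case_id)
  expect_equal(anyDuplicated(report$per_case_rank$case_id), 0)

  # audit: the causal gene of a held-out case never occurs as a causal gene
  # in its training folds
  folds <- report$folds
  gene_of <- setNames(cohort$cases$causal_gene, cohort$cases$case_id)
  for (f in unique(folds$fold)) {
    test_genes <- gene_of[folds$case_id[folds$fold == f]]
    train_genes <- gene_of[folds$case_id[folds$fold != f]]
    expect_equal(length(intersect(test_genes, train_genes)), 0)
  }
})

test_that("cross-validation is deterministic under a fixed seed", {
  cohort <- small_cohort(seed = 62, n_cases = 16, n_diseases = 6)
  r1 <- cross_validate(cohort, fast_config(seed = 4), k = 3, seed = 4)
  r2 <- cross_validate(cohort, fast_config(seed = 4), k = 3, seed = 4)
  expect_identical(r1$per_case_rank, r2$per_case_rank)
  expect_identical(r1$topk, r2$topk)
})

test_that("two-fold cross-validation equals two manually executed train/test passes", {
  cohort <- small_cohort(seed = 63, n_cases = 6, n_diseases = 3)
  cfg <- fast_config(seed = 8)
  folds <- gene_disjoint_folds(cohort, k = 2, seed = 8)
  report <- cross_validate(cohort, cfg, k = 2, seed = 8, folds = folds)

  manual <- list()
  for (f in 0:1) {
    test_ids <- folds$case_id[folds$fold == f]
    train_ids <- folds$case_id[folds$fold != f]
    cfg_f <- cfg
    cfg_f$seed <- pediar:::derive_seed(cfg$seed, f)
    model <- train_model(cohort$tables[train_ids], cfg_f)
    for (id in test_ids) {
      manual[[id]] <- causal_rank(rank_genes(model, cohort$tables[[id]]))
    }
  }
  got <- setNames(report$per_case_rank$rank, report$per_case_rank$case_id)
  expect_equal(got[names(manual)], unlist(manual))
})

test_that("ablation preserves combo order and reduces single scores to sorts", {
  cohort <- small_cohort(seed = 64, n_cases = 16, n_diseases = 6)
  combos <- list("cadd", c("cadd", "gestalt"), pediar:::PEDIA_FEATURES)
  reports <- ablation_grid(cohort, combos, fast_config(), k = 3, seed = 2)
  expect_equal(names(reports),
               c("cadd", "cadd+gestalt",
                 paste(pediar:::PEDIA_FEATURES, collapse = "+")))

  # single-feature combo: rank of causal gene equals a pure sort by cadd
  cadd_ranks <- reports[["cadd"]]$per_case_rank
  for (i in seq_len(nrow(cadd_ranks))) {
    tb <- cohort$tables[[cadd_ranks$case_id[i]]]
    sort_rank <- rank(-tb$cadd, ties.method = "min")[tb$label]
    expect_equal(cadd_ranks$rank[i], as.integer(sort_rank))
  }
  expect_error(ablation_grid(cohort, list(character()), fast_config()),
               "nonempty")
  expect_error(ablation_grid(cohort, list("nope"), fast_config()), "subset")
})

test_that("transfer evaluation borrows donor columns and keeps the test gestalt", {
  cohort <- small_cohort(seed = 65, n_cases = 16, n_diseases = 4)
  cases <- cohort$cases
  test_cases <- cases[1:4, ]
  train <- as_cohort(cases[5:16, ], cohort$tables[cases$case_id[5:16]])
  res <- transfer_augment_evaluate(train, test_cases, attr(cohort, "map"),
                                   repeats = 3, seed = 2,
                                   config = fast_config())
  expect_equal(res$k, c(1, 10))
  expect_true(all(res$mean_accuracy >= 0 & res$mean_accuracy <= 1))
  expect_true(all(res$sd_accuracy >= 0))
  pr <- attr(res, "per_repeat")
  expect_equal(nrow(pr), 3)

  # diagnosis without a donor is an error listing it
  orphan <- test_cases[1, ]
  orphan$diagnosis_id <- "OMIM:999999"
  expect_error(
    transfer_augment_evaluate(train, orphan, attr(cohort, "map"),
                              repeats = 1, seed = 1, config = fast_config()),
    "OMIM:999999")
})

test_that("transfer repeats collapse to SD zero when donors are unique", {
  cohort <- small_cohort(seed = 66, n_cases = 8, n_diseases = 8)
  cases <- cohort$cases
  # one training donor per diagnosis: cases 1..8 cycle over 8 diseases, so
  # use 4 of them as phenotype-only test cases and the rest as training,
  # then add back enough training so every test diagnosis has exactly 1 donor
  test_cases <- cases[1:4, ]
  test_cases$causal_variant_score <- test_cases$causal_variant_score + 1  # distinct variants
  train <- as_cohort(cases, cohort$tables)
  res <- transfer_augment_evaluate(train, test_cases, attr(cohort, "map"),
                                   repeats = 10, seed = 3,
                                   config = fast_config())
  expect_equal(res$sd_accuracy, c(0, 0))

  # repeats = 1: SD is 0 by convention
  res1 <- transfer_augment_evaluate(train, test_cases, attr(cohort, "map"),
                                    repeats = 1, seed = 3,
                                    config = fast_config())
  expect_equal(res1$sd_accuracy, c(0, 0))
})

test_that("evaluation reports serialise to JSON and TSV", {
  cohort <- small_cohort(seed = 67, n_cases = 12, n_diseases = 6)
  report <- cross_validate(cohort, fast_config(), k = 3, seed = 1)
  dir <- withr::local_tempdir()
  write_eval_report(report, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  curve <- readr::read_tsv(file.path(dir, "curve.tsv"), show_col_types = FALSE)
  expect_equal(curve$sensitivity, report$curve$sensitivity)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$topk$top_1, report$topk$accuracy[1])
})
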