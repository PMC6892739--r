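test_that("case table assembly fills unscored phenotype columns and labels the causal gene", {
  case <- case_record("c1", "HP:0000001", "OMIM:600001", "G2", 28)
  genes <- tibble::tibble(gene = c("G1", "G2", "G3"), score = c(5, 28, 12))
  gest <- tibble::tibble(gene = "G2", score = 0.8)
  empty <- tibble::tibble(gene = character(), score = numeric())
  tb <- assemble_case_table(case, genes, gest, empty, empty, empty, fill = 0)
  expect_equal(nrow(tb), nrow(genes))
  expect_equal(tb$gestalt, c(0, 0.8, 0))
  expect_equal(tb$feature_match, c(0, 0, 0))
  expect_equal(tb$label, c(FALSE, TRUE, FALSE))
  # causal gene missing from the candidate universe is an assembly error
  case2 <- case_record("c2", "HP:0000001", "OMIM:600001", "G9", 28)
  expect_error(assemble_case_table(case2, genes, gest, empty, empty, empty),
               "causal gene")
})

test_that("assembled columns equal independent dictionary lookups", {
  set.seed(501)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    genes <- tibble::tibble(gene = sprintf("G%02d", seq_len(n)),
                            score = runif(n, 0, 40))
    rand_map <- function() {
      k <- sample.int(n, sample.int(n, 1))
      tibble::tibble(gene = genes$gene[k], score = runif(length(k)))
    }
    maps <- list(g = rand_map(), f = rand_map(), p = rand_map(), b = rand_map())
    causal <- sample(genes$gene, 1)
    case <- case_record("cx", "HP:0000001", "OMIM:600001", causal, 30)
    tb <- assemble_case_table(case, genes, maps$g, maps$f, maps$p, maps$b,
                              fill = -1)
    for (colmap in list(c("gestalt", "g"), c("feature_match", "f"),
                      c("phenomizer", "p"), c("boqa", "b"))) {
      m <- maps[[colmap[2]]]
      expected <- vapply(tb$gene, function(g) {
        if (g %in% m$gene) m$score[m$gene == g] else -1
      }, 1.0, USE.NAMES = FALSE)
      expect_equal(tb[[colmap[1]]], expected, info = colmap[1])
    }
  }
})

test_that("a separable two-feature toy problem is separated exactly", {
  set.seed(502)
  tables <- lapply(1:6, function(i) {
    n <- 10
    tb <- random_table(n)
    tb$cadd <- runif(n, 0, 10); tb$gestalt <- runif(n, 0, 0.2)
    tb$feature_match <- 0.5; tb$phenomizer <- 1; tb$boqa <- 0.1  # constant
    tb$cadd[tb$label] <- 35; tb$gestalt[tb$label] <- 0.9
    tb
  })
  names(tables) <- sprintf("t%d", 1:6)
  model <- train_model(tables, fast_config())
  pooled <- dplyr::bind_rows(tables)
  scores <- dplyr::bind_rows(lapply(tables, function(tb) pedia_scores(model, tb)))
  expect_true(min(scores$pedia_score[pooled$label]) >
              max(scores$pedia_score[!pooled$label]))
})

test_that("training is deterministic and invariant to duplicating every row", {
  cohort <- small_cohort(seed = 51, n_cases = 12, n_diseases = 4)
  cfg <- fast_config(seed = 5)
  m1 <- train_model(cohort$tables, cfg)
  m2 <- train_model(cohort$tables, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)

  # duplicating every training row (each table listed twice) while halving
  # the per-row cost leaves the soft-margin objective, and hence the
  # decision function, unchanged
  doubled <- c(cohort$tables, setNames(cohort$tables,
                                       paste0(names(cohort$tables), "_b")))
  m3 <- train_model(doubled, fast_config(seed = 5, c_grid = cfg$c_grid / 2))
  probe <- cohort$tables[[1]]
  expect_equal(pedia_scores(m3, probe)$pedia_score,
               pedia_scores(m1, probe)$pedia_score, tolerance = 1e-6)
})

test_that("single-class training data is a training error", {
  tb <- random_table(5)
  tb$label <- FALSE
  expect_error(pediar:::fit_linear_svm(as.matrix(tb[, 2:6]), tb$label, 1,
                                       "balanced"),
               "single-class")
})

test_that("hyperparameter selection returns the argmax C with smallest-C ties", {
  cohort <- small_cohort(seed = 52, n_cases = 12, n_diseases = 4)
  # grid of one value: that value
  expect_equal(select_hyperparameter(cohort$tables,
                                     fast_config(c_grid = 2)), 2)
  # perfectly separable cohort: all C tie at top-1 = 1, smallest returned
  sep <- lapply(1:8, function(i) {
    tb <- random_table(8)
    tb$cadd <- runif(8, 0, 5); tb$cadd[tb$label] <- 39
    tb$gestalt[tb$label] <- max(tb$gestalt) + 1
    tb
  })
  names(sep) <- sprintf("s%d", 1:8)
  grid <- c(0.5, 2, 8)
  expect_equal(select_hyperparameter(sep, fast_config(c_grid = grid)), 0.5)
  expect_error(select_hyperparameter(sep[1:1],
                                     fast_config(internal_folds = 2)),
               "fewer training cases")
})

test_that("hyperparameter selection matches an independently scripted grid loop", {
  cohort <- small_cohort(seed = 53, n_cases = 14, n_diseases = 5)
  grid <- c(0.25, 1, 4)
  cfg <- classifier_config(c_grid = grid, internal_folds = 2, seed = 9)
  got <- select_hyperparameter(cohort$tables, cfg)

  # independent loop re-using only the low-level fit + rank primitives
  folds <- pediar:::make_internal_folds(length(cohort$tables), 2, 9)
  acc <- sapply(grid, function(C) {
    mean(sapply(folds, function(test_idx) {
      train <- cohort$tables[-test_idx]
      pooled <- pediar:::pool_tables(train, pediar:::PEDIA_FEATURES)
      scaler <- pediar:::fit_scaler(pooled$x)
      fit <- pediar:::fit_linear_svm(pediar:::apply_scaler(pooled$x, scaler),
                                     pooled$y, C, "balanced")
      model <- pediar:::new_pedia_model(fit, scaler, C,
                                        pediar:::PEDIA_FEATURES, cfg)
      mean(vapply(cohort$tables[test_idx], function(tb)
        causal_rank(rank_genes(model, tb)) == 1L, TRUE))
    }))
  })
  expect_equal(got, grid[which.max(acc)])
})

test_that("pedia scores are the standardised linear margin", {
  cohort <- small_cohort(seed = 54, n_cases = 10, n_diseases = 4)
  model <- train_model(cohort$tables, fast_config())
  tb <- cohort$tables[[3]]
  got <- pedia_scores(model, tb)
  x <- as.matrix(tb[, model$features])
  hand <- as.numeric(
    (scale(x, center = model$scaler$center, scale = model$scaler$scale) %*%
       model$weights) + model$bias)
  expect_equal(got$pedia_score, hand, tolerance = 1e-12)

  # a row at the scaler centre scores exactly the bias
  centre <- tb[1, ]
  centre[, model$features] <- as.list(model$scaler$center)
  expect_equal(pedia_scores(model, centre)$pedia_score, model$bias)

  # increasing a positively weighted feature increases the score
  wpos <- names(which(model$weights > 0))[1]
  bumped <- tb[1, ]; bumped[[wpos]] <- bumped[[wpos]] + 1
  expect_gt(pedia_scores(model, bumped)$pedia_score,
            pedia_scores(model, tb[1, ])$pedia_score)

  # non-finite features are a scoring error naming the gene
  broken <- tb; broken$cadd[2] <- Inf
  expect_error(pedia_scores(model, broken), broken$gene[2])
})

test_that("ranking sorts by score with lexicographic ties and competition ranks", {
  model <- structure(list(
    weights = c(cadd = 1, gestalt = 0, feature_match = 0, phenomizer = 0, boqa = 0),
    bias = 0, selected_C = 1,
    scaler = list(center = rep(0, 5), scale = rep(1, 5)),
    features = pediar:::PEDIA_FEATURES, config = NULL), class = "pedia_model")
  tb <- random_table(4)
  tb$gene <- c("G_b", "G_a", "G_c", "G_d")
  tb$cadd <- c(5, 5, 9, 1)
  tb$label <- c(TRUE, FALSE, FALSE, FALSE)
  ranked <- rank_genes(model, tb)
  expect_equal(ranked$gene, c("G_c", "G_a", "G_b", "G_d"))  # tie: G_a before G_b
  expect_equal(ranked$rank, c(1L, 2L, 2L, 4L))              # competition ranking
  expect_equal(causal_rank(ranked), 2L)
  expect_true(all(diff(ranked$pedia_score) <= 0))
})

test_that("ranking is invariant to strictly increasing score transforms", {
  cohort <- small_cohort(seed = 55, n_cases = 8, n_diseases = 4)
  model <- train_model(cohort$tables, fast_config())
  tb <- cohort$tables[[2]]
  ranked <- rank_genes(model, tb)
  # a model with doubled weights and shifted bias: monotone transform
  model2 <- model
  model2$weights <- model$weights * 2
  model2$bias <- model$bias * 2 + 3
  ranked2 <- rank_genes(model2, tb)
  expect_equal(ranked2$gene, ranked$gene)
  expect_equal(ranked2$rank, ranked$rank)
})

test_that("a single informative feature reproduces ranking by that feature", {
  set.seed(506)
  tables <- lapply(1:8, function(i) {
    tb <- random_table(10)
    tb$gestalt <- 0.3; tb$feature_match <- 0.3; tb$phenomizer <- 0.3; tb$boqa <- 0.3
    tb$cadd[tb$label] <- tb$cadd[tb$label] + 30
    tb
  })
  names(tables) <- sprintf("t%d", 1:8)
  model <- train_model(tables, fast_config())
  for (tb in tables) {
    ranked <- rank_genes(model, tb)
    by_cadd <- tb[order(-tb$cadd, tb$gene), ]
    expect_equal(ranked$gene, by_cadd$gene)
  }
})

test_that("weight contributions normalise absolute weights by channel", {
  mk <- function(w) structure(list(
    weights = setNames(w, pediar:::PEDIA_FEATURES), bias = 0, selected_C = 1,
    scaler = list(center = rep(0, 5), scale = rep(1, 5)),
    features = pediar:::PEDIA_FEATURES, config = NULL), class = "pedia_model")
  equal <- weight_contributions(mk(rep(1, 5)))
  expect_equal(setNames(equal$contribution, equal$component),
               c(variant = 0.2, features = 0.6, gestalt = 0.2))
  solo <- weight_contributions(mk(c(2, 0, 0, 0, 0)))
  expect_equal(solo$contribution, c(1, 0, 0))
  expect_error(weight_contributions(mk(rep(0, 5))), "zero")
  set.seed(507)
  for (i in 1:20) {
    w <- rnorm(5)
    wc <- weight_contributions(mk(w))
    expect_equal(sum(wc$contribution), 1, tolerance = 1e-12)
    expect_equal(wc$contribution[1], abs(w[1]) / sum(abs(w)))
    expect_equal(wc$contribution[3], abs(w[2]) / sum(abs(w)))
  }
})

test_that("models round-trip through JSON and tidy/glance expose the fit", {
  cohort <- small_cohort(seed = 56, n_cases = 8, n_diseases = 4)
  model <- train_model(cohort$tables, fast_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  tb <- cohort$tables[[1]]
  expect_equal(pedia_scores(back, tb), pedia_scores(model, tb),
               tolerance = 1e-12)

  td <- generics::tidy(model)
  expect_setequal(td$term, pediar:::PEDIA_FEATURES)
  expect_equal(sum(td$contribution), 1, tolerance = 1e-12)
  gl <- generics::glance(model)
  expect_equal(gl$selected_C, model$selected_C)
})
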