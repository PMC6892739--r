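#' Classifier configuration
#'
#' Controls the linear-SVM integration stage: the hyperparameter grid for
#' the soft-margin cost `C`, the number of internal cross-validation folds
#' used to select it (by top-1 accuracy), the fill value for candidate genes
#' with no mapped phenotype score, the class-weighting policy for the
#' extreme label imbalance (one causal row per table), and the seed for the
#' internal fold shuffle.
#'
#' @param c_grid Strictly increasing positive reals; default all integer
#'   powers of two from `2^-6` to `2^12`.
#' @param internal_folds Internal CV fold count (>= 2), default 5.
#' @param missing_fill Value used for unscored phenotype columns, default 0
#'   (absence of evidence = no similarity).
#' @param class_weighting `"balanced"` (inverse-frequency weights on the
#'   hinge loss) or `"none"`.
#' @param seed Integer seed controlling the internal fold shuffle.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(c_grid = 2^(-6:12), internal_folds = 5,
                              missing_fill = 0,
                              class_weighting = c("balanced", "none"),
                              seed = 1L) {
  stopifnot(length(c_grid) >= 1, all(c_grid > 0), !is.unsorted(c_grid, strictly = TRUE),
            internal_folds >= 2)
  structure(list(c_grid = c_grid, internal_folds = as.integer(internal_folds),
                 missing_fill = missing_fill,
                 class_weighting = match.arg(class_weighting),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Assemble the five-score feature table of one case
#'
#' The candidate-gene universe is the exome-derived per-gene score map
#' (spike-in guarantees the causal gene is present).  Each candidate gets
#' its deleteriousness score plus the four gene-mapped phenotype scores;
#' genes with no mapped value in a phenotype column take `fill`, keeping
#' "unscored" distinct from "scored 0" upstream.  The causal gene is
#' labelled `TRUE`.
#'
#' @param case One-row case-record tibble (see [case_record()]).
#' @param gene_scores Tibble `gene`, `score`: spiked per-gene deleteriousness
#'   map.
#' @param gestalt_by_gene,fm_by_gene,phen_by_gene,boqa_by_gene Tibbles
#'   `gene`, `score` from [map_scores_to_genes()].
#' @param fill Fill value for unscored phenotype columns.
#' @return A validated gene score table (tibble).
#' @export
assemble_case_table <- function(case, gene_scores, gestalt_by_gene, fm_by_gene,
                                phen_by_gene, boqa_by_gene, fill = 0) {
  if (!case$causal_gene %in% gene_scores$gene) {
    stop("assembly error: causal gene ", case$causal_gene,
         " absent from the candidate gene universe of case ", case$case_id)
  }
  lookup <- function(tb, genes) {
    v <- tb$score[match(genes, tb$gene)]
    ifelse(is.na(v), fill, v)
  }
  tb <- tibble(
    gene = gene_scores$gene,
    cadd = gene_scores$score,
    gestalt = lookup(gestalt_by_gene, gene_scores$gene),
    feature_match = lookup(fm_by_gene, gene_scores$gene),
    phenomizer = lookup(phen_by_gene, gene_scores$gene),
    boqa = lookup(boqa_by_gene, gene_scores$gene),
    label = gene_scores$gene == case$causal_gene
  )
  stop_if_violations(validate_table(tb), paste("invalid table for case", case$case_id))
  tb
}

pool_tables <- function(tables, features) {
  x <- as.matrix(bind_rows(tables)[, features, drop = FALSE])
  y <- unlist(map(tables, "label"), use.names = FALSE)
  list(x = x, y = y)
}

fit_scaler <- function(x) {
  center <- colMeans(x)
  # population (1/n) standard deviation: invariant under row duplication
  scale <- sqrt(colMeans(sweep(x, 2, center)^2))
  scale[!is.finite(scale) | scale == 0] <- 1  # constant columns pass through
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

svm_class_weights <- function(y, policy) {
  if (policy != "balanced") return(NULL)
  n <- length(y)
  c("TRUE" = n / (2 * sum(y)), "FALSE" = n / (2 * sum(!y)))
}

# Fit the linear SVM on standardised rows and orient the hyperplane so that
# causal-labelled training rows score higher on average (libsvm's decision
# sign depends on which label it meets first).
fit_linear_svm <- function(x_scaled, y, cost, class_weighting) {
  if (length(unique(y)) < 2) stop("training error: single-class training data")
  yf <- factor(ifelse(y, "TRUE", "FALSE"), levels = c("TRUE", "FALSE"))
  fit <- e1071::svm(x_scaled, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = svm_class_weights(y, class_weighting),
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  scores <- drop(x_scaled %*% w) + b
  if (mean(scores[y]) < mean(scores[!y])) {
    w <- -w
    b <- -b
  }
  list(weights = setNames(w, colnames(x_scaled)), bias = b)
}

make_internal_folds <- function(n, k, seed) {
  if (n < k) stop("fewer training cases (", n, ") than internal folds (", k, ")")
  idx <- with_local_seed(seed, sample.int(n))
  unname(split(idx, rep_len(seq_len(k), n)))  # seeded balanced split
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Select the SVM cost hyperparameter by internal cross-validation
#'
#' For each candidate `C`, cases are split into `internal_folds` folds
#' (seeded shuffle); a model is trained on the complement of each fold and
#' the held-out cases are ranked; the mean top-1 accuracy across folds is
#' the criterion.  The `C` with the highest top-1 accuracy wins; ties break
#' to the smallest `C`.
#'
#' @param training_tables Named list of gene score tables (>=
#'   `internal_folds` cases).
#' @param config A [classifier_config()].
#' @param features Feature columns to use (default all five).
#' @return The selected `C` (scalar).
#' @export
select_hyperparameter <- function(training_tables, config = classifier_config(),
                                  features = PEDIA_FEATURES) {
  n <- length(training_tables)
  folds <- make_internal_folds(n, config$internal_folds, config$seed)
  acc <- vapply(config$c_grid, function(C) {
    fold_acc <- vapply(folds, function(test_idx) {
      train <- training_tables[-test_idx]
      pooled <- pool_tables(train, features)
      scaler <- fit_scaler(pooled$x)
      svmfit <- fit_linear_svm(apply_scaler(pooled$x, scaler), pooled$y, C,
                               config$class_weighting)
      model <- new_pedia_model(svmfit, scaler, C, features, config)
      ranks <- vapply(training_tables[test_idx], function(tb)
        causal_rank(rank_genes(model, tb)), 1L)
      mean(ranks == 1L)
    }, 1.0)
    mean(fold_acc)
  }, 1.0)
  config$c_grid[[which.max(acc)]]  # which.max returns first max: smallest C
}

new_pedia_model <- function(svmfit, scaler, selected_C, features, config) {
  structure(list(weights = svmfit$weights, bias = svmfit$bias,
                 selected_C = selected_C, scaler = scaler,
                 features = features, config = config),
            class = "pedia_model")
}

#' Train the score-integration model
#'
#' Pools the rows of all training tables, fits the per-feature
#' standardisation on them, selects `C` by internal cross-validation when
#' the grid has more than one value, and fits a soft-margin linear SVM with
#' inverse-frequency class weights on the standardised rows.  Deterministic
#' given the config seed.
#'
#' @param training_tables Named list of gene score tables.
#' @param config A [classifier_config()].
#' @param features Feature columns (default all five).
#' @return A `pedia_model`: linear weights over the (standardised) features,
#'   bias, selected `C`, and the fitted scaler.
#' @export
train_model <- function(training_tables, config = classifier_config(),
                        features = PEDIA_FEATURES) {
  selected_C <- if (length(config$c_grid) == 1) {
    config$c_grid[[1]]
  } else {
    select_hyperparameter(training_tables, config, features)
  }
  pooled <- pool_tables(training_tables, features)
  scaler <- fit_scaler(pooled$x)
  svmfit <- fit_linear_svm(apply_scaler(pooled$x, scaler), pooled$y, selected_C,
                           config$class_weighting)
  new_pedia_model(svmfit, scaler, selected_C, features, config)
}

#' @export
print.pedia_model <- function(x, ...) {
  cat(sprintf("<pedia_model> linear SVM on %d features, C = %g\n",
              length(x$features), x$selected_C))
  cat("  weights:", paste(sprintf("%s=%.4g", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Compute PEDIA scores for a case table
#'
#' The PEDIA score of gene `g` is the signed, unnormalised margin
#' `w . standardize(x_g) + b` of its feature row — monotone in the geometric
#' distance to the hyperplane, with causal-like rows on the positive side.
#'
#' @param model A `pedia_model`.
#' @param table A gene score table.
#' @return Tibble `gene`, `pedia_score`.
#' @export
pedia_scores <- function(model, table) {
  x <- as.matrix(table[, model$features, drop = FALSE])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("scoring error: non-finite feature for gene ", table$gene[[bad[1, 1]]])
  }
  s <- drop(apply_scaler(x, model$scaler) %*% model$weights) + model$bias
  tibble(gene = table$gene, pedia_score = as.numeric(s))
}

#' Rank a case's candidate genes by PEDIA score
#'
#' Entries are ordered by descending score, ties broken lexicographically by
#' gene symbol; ranks are competition ranks (tied scores share the smallest
#' rank).  The causal rank is the rank of the labelled gene.
#'
#' @param model A `pedia_model`.
#' @param table A gene score table.
#' @return Tibble `gene`, `pedia_score`, `rank`, the five evidence columns
#'   and `label`, ordered by rank, with attributes `causal_rank` and class
#'   `pedia_ranked`.
#' @export
rank_genes <- function(model, table) {
  scored <- pedia_scores(model, table)
  out <- table |>
    left_join(scored, by = "gene") |>
    arrange(desc(.data$pedia_score), .data$gene) |>
    mutate(rank = rank_with_ties(.data$pedia_score))
  out <- out[, c("gene", "pedia_score", "rank", PEDIA_FEATURES, "label")]
  structure(out, class = c("pedia_ranked", class(out)),
            causal_rank = out$rank[which(out$label)])
}

# competition ("min") ranking of scores already sorted descending
rank_with_ties <- function(scores_desc) {
  as.integer(rank(-scores_desc, ties.method = "min"))
}

#' Causal-gene rank of a ranked result
#'
#' @param ranked A `pedia_ranked` tibble from [rank_genes()].
#' @return Integer rank of the labelled causal gene.
#' @export
causal_rank <- function(ranked) {
  attr(ranked, "causal_rank")
}

#' Relative evidence-channel contributions of a trained model
#'
#' Normalised absolute weights, aggregated into the three evidence channels:
#' the molecular variant score (`cadd`), the three clinical-feature scores
#' combined (`feature_match` + `phenomizer` + `boqa`), and the image-derived
#' gestalt score.  Contributions sum to 1.
#'
#' @param model A `pedia_model` trained on all five features.
#' @return Tibble `component` (`variant`, `features`, `gestalt`),
#'   `contribution`.
#' @export
weight_contributions <- function(model) {
  w <- abs(model$weights)
  if (sum(w) == 0) stop("weight contributions undefined: all weights are zero")
  w <- w / sum(w)
  get0 <- function(nm) if (nm %in% names(w)) unname(w[[nm]]) else 0
  tibble(
    component = c("variant", "features", "gestalt"),
    contribution = c(get0("cadd"),
                     get0("feature_match") + get0("phenomizer") + get0("boqa"),
                     get0("gestalt"))
  )
}

#' Serialize a trained model to JSON
#'
#' @param model A `pedia_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  cfg <- model$config
  obj <- list(
    weights = as.list(model$weights),
    bias = model$bias,
    selected_C = model$selected_C,
    scaler = list(center = as.list(setNames(model$scaler$center, model$features)),
                  scale = as.list(setNames(model$scaler$scale, model$features))),
    features = model$features,
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON path.
#' @return A `pedia_model` (without the training config).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  features <- unlist(obj$features)
  structure(list(
    weights = setNames(unlist(obj$weights)[features], features),
    bias = obj$bias,
    selected_C = obj$selected_C,
    scaler = list(center = setNames(unlist(obj$scaler$center)[features], features),
                  scale = setNames(unlist(obj$scaler$scale)[features], features)),
    features = features,
    config = NULL
  ), class = "pedia_model")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained model into one row per feature weight
#'
#' @param x A `pedia_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (weight on the standardised feature),
#'   `contribution` (normalised absolute weight).
#' @method tidy pedia_model
#' @export
tidy.pedia_model <- function(x, ...) {
  tibble(term = names(x$weights),
         estimate = unname(x$weights),
         contribution = abs(unname(x$weights)) / sum(abs(x$weights)))
}

#' One-row model summary
#'
#' @param x A `pedia_model`.
#' @param ... Unused.
#' @return Tibble with `selected_C`, `bias`, `n_features`.
#' @method glance pedia_model
#' @export
glance.pedia_model <- function(x, ...) {
  tibble(selected_C = x$selected_C, bias = x$bias,
         n_features = length(x$features))
}
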