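# Shared fixtures and independent brute-force oracles.
# The oracle code deliberately avoids the package's internal closure cache:
# ancestor sets are recomputed by breadth-first walks over the raw parent
# lists so that scorer tests compare two independent code paths.

# -- tiny hand-built DAG: root A; B,C children of A; D child of B and C -----
toy_ontology <- function() {
  pediar:::build_ontology(
    terms = c("A", "B", "C", "D", "E"),
    parents = list(A = character(), B = "A", C = "A", D = c("B", "C"), E = "C"),
    names_map = c(A = "root", B = "b", C = "c", D = "d", E = "e")
  )
}

# random rooted DAG over n terms; each later term attaches to 1-2 earlier ones
random_dag <- function(n, multi_parent_prob = 0.3) {
  terms <- sprintf("T%03d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- terms
  parents[[terms[[1]]]] <- character()
  for (i in seq_len(n)[-1]) {
    ps <- terms[[sample.int(i - 1, 1)]]
    if (i > 2 && runif(1) < multi_parent_prob) {
      ps <- union(ps, terms[[sample.int(i - 1, 1)]])
    }
    parents[[terms[[i]]]] <- ps
  }
  pediar:::build_ontology(terms, parents)
}

random_catalog <- function(onto, n_diseases, terms_per_disease = 3) {
  pool <- setdiff(onto$terms, onto$root)
  catalog <- lapply(seq_len(n_diseases), function(i) {
    sample(pool, min(terms_per_disease, length(pool)))
  })
  names(catalog) <- sprintf("D%02d", seq_len(n_diseases))
  catalog
}

# oracle ancestor closure: BFS over parent lists, includes the term itself
oracle_ancestors <- function(onto, term) {
  seen <- character()
  frontier <- term
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier])), seen)
  }
  seen
}

oracle_set_closure <- function(onto, terms) {
  unique(unlist(lapply(terms, oracle_ancestors, onto = onto)))
}

# oracle IC: exhaustive descendant-closure disease count
oracle_ic <- function(onto, catalog) {
  N <- length(catalog)
  disease_closures <- lapply(catalog, oracle_set_closure, onto = onto)
  ic <- sapply(onto$terms, function(t) {
    n_t <- sum(vapply(disease_closures, function(cl) t %in% cl, TRUE))
    if (n_t == 0) NA_real_ else -log(n_t / N)
  })
  if (anyNA(ic)) ic[is.na(ic)] <- max(ic, na.rm = TRUE) + log(2)
  ic
}

# oracle Resnik: enumerate the ancestor-set intersection
oracle_resnik <- function(t1, t2, onto, ic) {
  max(ic[intersect(oracle_ancestors(onto, t1), oracle_ancestors(onto, t2))])
}

# oracle symmetric best-match-average: direct O(|Q||D|) double loop
oracle_bma <- function(query, dterms, onto, ic) {
  m <- matrix(0, length(query), length(dterms))
  for (i in seq_along(query)) {
    for (j in seq_along(dterms)) {
      m[i, j] <- oracle_resnik(query[[i]], dterms[[j]], onto, ic)
    }
  }
  0.5 * (mean(apply(m, 1, max)) + mean(apply(m, 2, max)))
}

# oracle Bayesian query posterior: literal product formula, linear space
oracle_boqa <- function(query, catalog, onto, alpha, beta, prior = NULL) {
  qc <- oracle_set_closure(onto, query)
  Tn <- length(onto$terms)
  if (is.null(prior)) {
    prior <- setNames(rep(1 / length(catalog), length(catalog)), names(catalog))
  }
  lik <- sapply(names(catalog), function(d) {
    ac <- oracle_set_closure(onto, catalog[[d]])
    alpha^length(setdiff(qc, ac)) *
      (1 - alpha)^(Tn - length(union(qc, ac))) *
      beta^length(setdiff(ac, qc)) *
      (1 - beta)^length(intersect(ac, qc))
  })
  post <- lik * prior[names(catalog)]
  post / sum(post)
}

# -- random valid gene score tables ----------------------------------------
random_table <- function(n_genes = 8, causal = 1L) {
  genes <- sprintf("G%03d", sample.int(999, n_genes))
  tibble::tibble(
    gene = genes,
    cadd = runif(n_genes, 0, 40),
    gestalt = runif(n_genes),
    feature_match = runif(n_genes),
    phenomizer = runif(n_genes, 0, 5),
    boqa = runif(n_genes),
    label = seq_len(n_genes) == causal
  )
}

# random cohort of bare case records (no tables)
random_cases <- function(n_cases, n_genes = max(3, n_cases %/% 2)) {
  genes <- sprintf("CG%02d", seq_len(n_genes))
  tibble::tibble(
    case_id = sprintf("rc%03d", seq_len(n_cases)),
    hpo_terms = replicate(n_cases, sprintf("HP:%07d", sample.int(50, 3)),
                          simplify = FALSE),
    diagnosis_id = sprintf("OMIM:%06d", 600000 + sample.int(10, n_cases, TRUE)),
    causal_gene = sample(genes, n_cases, replace = TRUE),
    causal_variant_score = runif(n_cases, 10, 40),
    gestalt_scores = replicate(n_cases, c(S1 = runif(1)), simplify = FALSE),
    ethnicity = sample(c("EUR", "AFR"), n_cases, TRUE)
  )
}

# small fast study cohort used across classifier/evaluation tests
small_cohort <- function(seed = 11, n_cases = 30, n_diseases = 8) {
  generate_cohort(synthetic_config(
    n_cases = n_cases, n_diseases = n_diseases, n_terms = 60,
    terms_per_disease = 6, n_extra_genes = 30,
    n_background_genes = c(EUR = 40, AFR = 60),
    seed = seed
  ))
}

fast_config <- function(seed = 1, c_grid = 1, internal_folds = 2) {
  classifier_config(c_grid = c_grid, internal_folds = internal_folds, seed = seed)
}
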