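#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the statistical structure the pipeline consumes:
#' a rooted HPO-like DAG, a disease catalog annotated to it, a
#' syndrome-to-gene map with gene-level heterogeneity, noisy per-case HPO
#' queries (term dropout and unrelated noise terms), per-syndrome gestalt
#' vectors in which the true syndrome's score is shifted upward by
#' `gestalt_signal`, and per-ethnicity background exome score maps into
#' which the causal variant score is spiked.
#'
#' Default distributions: background per-gene deleteriousness `Beta(2, 5)`
#' scaled to `[0, 40]` (right-skewed, most genes low-scoring); causal scores
#' `Normal(28, 4)` truncated at 0 — plausible CADD-PHRED shapes, declared
#' here as simulation choices.  Ethnicity affects only the number of
#' background genes surviving filtering (African-ancestry backgrounds carry
#' more rare variants at a comparable score distribution).
#'
#' @param n_terms Number of ontology terms.
#' @param dag_branching Mean children per internal node (controls depth).
#' @param multi_parent_prob Probability a non-root term gets a second
#'   parent.
#' @param n_diseases Number of diseases (>= 2).
#' @param genes_per_disease Genes linked to each disease (>= 1; values > 1
#'   create locus heterogeneity).
#' @param terms_per_disease Annotation terms per disease.
#' @param term_dropout_rate Probability each annotation term is dropped from
#'   a case's query.
#' @param noise_term_rate Probability (per annotation term) of adding an
#'   unrelated noise term.
#' @param gestalt_signal Mean upward shift of the true syndrome's gestalt
#'   score over the noise baseline (>= 0).
#' @param gestalt_baseline_mean,gestalt_baseline_sd Baseline gestalt noise
#'   (truncated at 0).
#' @param n_background_genes Named integer vector: background genes per
#'   ethnicity tag.
#' @param background_score Function `(n)` drawing background per-gene
#'   deleteriousness scores.
#' @param causal_score Function `(n)` drawing causal-variant scores.
#' @param n_extra_genes Background-only genes added to the gene universe
#'   beyond the disease genes.
#' @param n_cases Number of cases (cases cycle over diseases).
#' @param seed Integer master seed; every stage derives its own substream.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_terms = 120, dag_branching = 3,
                             multi_parent_prob = 0.1,
                             n_diseases = 20, genes_per_disease = 2,
                             terms_per_disease = 8,
                             term_dropout_rate = 0.25, noise_term_rate = 0.1,
                             gestalt_signal = 0.5,
                             gestalt_baseline_mean = 0.2,
                             gestalt_baseline_sd = 0.1,
                             n_background_genes = c(EUR = 80, AFR = 120, EAS = 80),
                             background_score = function(n) 40 * rbeta(n, 2, 5),
                             causal_score = function(n) pmax(0, rnorm(n, 28, 4)),
                             n_extra_genes = 60,
                             n_cases = 100, seed = 42L) {
  stopifnot(n_diseases >= 2, genes_per_disease >= 1,
            terms_per_disease >= 1, terms_per_disease <= n_terms,
            term_dropout_rate >= 0, term_dropout_rate <= 1,
            noise_term_rate >= 0, noise_term_rate <= 1,
            gestalt_signal >= 0, n_cases >= 1,
            !is.null(names(n_background_genes)))
  structure(as.list(environment()), class = "synthetic_config")
}

hp_id <- function(i) sprintf("HP:%07d", i)

#' Generate a toy ontology, disease catalog and syndrome-gene map
#'
#' Builds a rooted DAG of `n_terms` terms (each non-root term attaches to a
#' random earlier term; with probability `multi_parent_prob` it receives a
#' second parent), annotates each of `n_diseases` diseases with
#' `terms_per_disease` non-root terms, and links each disease to
#' `genes_per_disease` distinct genes.  Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional seed override (defaults to the config seed).
#' @return List with `ontology` (a `pedia_ontology`), `catalog` (named list
#'   disease -> terms) and `map` (a `gene_phenotype_map`).
#' @export
make_ontology_and_catalog <- function(config, seed = config$seed) {
  stopifnot(config$terms_per_disease <= config$n_terms - 1)
  with_local_seed(derive_seed(seed, 1L), {
    n <- config$n_terms
    terms <- hp_id(seq_len(n))
    parents <- vector("list", n)
    names(parents) <- terms
    parents[[terms[[1]]]] <- character()
    for (i in 2:n) {
      # attach to a recent term with branching-limited window: gives depth
      lo <- max(1, i - config$dag_branching * 3)
      p1 <- terms[[sample(lo:(i - 1), 1)]]
      ps <- p1
      if (i > 2 && runif(1) < config$multi_parent_prob) {
        p2 <- terms[[sample.int(i - 1, 1)]]
        ps <- union(ps, p2)
      }
      parents[[terms[[i]]]] <- ps
    }
    onto <- build_ontology(terms, parents,
                           setNames(paste("term", seq_len(n)), terms))

    diseases <- sprintf("OMIM:%06d", 600000 + seq_len(config$n_diseases))
    catalog <- lapply(seq_len(config$n_diseases), function(d) {
      sample(terms[-1], config$terms_per_disease)
    })
    names(catalog) <- diseases

    genes <- sprintf("GENE%04d", seq_len(config$n_diseases * config$genes_per_disease))
    edges <- tibble(
      syndrome_id = rep(diseases, each = config$genes_per_disease),
      gene = genes
    )
    list(ontology = onto, catalog = catalog, map = gene_phenotype_map(edges))
  })
}

#' Simulate one case record for a disease
#'
#' The HPO query is the disease annotation after per-term dropout plus
#' unrelated noise terms (if everything is dropped one annotation term is
#' retained); the causal gene is sampled uniformly from the disease's genes;
#' the causal variant score is drawn from the causal distribution; the
#' gestalt vector holds truncated-normal baseline noise per syndrome with
#' `gestalt_signal` added to the true syndrome's entry.
#'
#' @param disease_id Disease to simulate.
#' @param catalog Annotation catalog.
#' @param map A `gene_phenotype_map`.
#' @param config A [synthetic_config()].
#' @param onto The ontology (for noise-term sampling).
#' @param seed Integer seed for this case.
#' @param case_id Case identifier.
#' @param ethnicity Ethnicity tag.
#' @return One-row case-record tibble.
#' @export
simulate_case <- function(disease_id, catalog, map, config, onto,
                          seed, case_id = "case", ethnicity = "EUR") {
  if (!disease_id %in% names(catalog)) stop("disease not in catalog: ", disease_id)
  with_local_seed(seed, {
    ann <- catalog[[disease_id]]
    keep <- ann[runif(length(ann)) >= config$term_dropout_rate]
    if (length(keep) == 0) keep <- sample(ann, 1)
    n_noise <- stats::rbinom(1, length(ann), config$noise_term_rate)
    noise_pool <- setdiff(setdiff(onto$terms, onto$root), ann)
    noise <- if (n_noise > 0) sample(noise_pool, min(n_noise, length(noise_pool)))
             else character()
    syndromes <- names(catalog)
    gest <- pmax(0, rnorm(length(syndromes), config$gestalt_baseline_mean,
                          config$gestalt_baseline_sd))
    names(gest) <- syndromes
    gest[[disease_id]] <- gest[[disease_id]] + config$gestalt_signal
    disease_genes <- syndrome_to_genes(map)[[disease_id]]
    causal_gene <- disease_genes[[sample.int(length(disease_genes), 1)]]
    case_record(
      case_id = case_id,
      hpo_terms = union(keep, noise),
      diagnosis_id = disease_id,
      causal_gene = causal_gene,
      causal_variant_score = config$causal_score(1),
      gestalt_scores = gest,
      ethnicity = ethnicity
    )
  })
}

sample_background <- function(config, map, ethnicity, seed) {
  with_local_seed(seed, {
    universe <- c(sort(unique(map$gene)),
                  sprintf("BG%04d", seq_len(config$n_extra_genes)))
    n_bg <- config$n_background_genes[[ethnicity]]
    genes <- sort(sample(universe, min(n_bg, length(universe))))
    tibble(gene = genes, score = config$background_score(length(genes)))
  })
}

#' Generate a full synthetic cohort with assembled score tables
#'
#' Produces `n_cases` cases cycling over the diseases and over the
#' configured ethnicities.  Per case: a background per-gene score map is
#' sampled for the case's ethnicity, the causal variant score is spiked in,
#' the three HPO similarity scores and the gestalt vector are computed at
#' disease level and mapped to genes, and the five-score table is assembled.
#' Every stage draws from its own seed substream, so adding cases never
#' perturbs earlier draws; the whole cohort is deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `pedia_cohort` with `cases`, `tables`, and the generating
#'   `ontology`, `catalog` and `map` attached as attributes.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  parts <- make_ontology_and_catalog(config)
  onto <- parts$ontology; catalog <- parts$catalog; gmap <- parts$map
  ic <- compute_ic(onto, catalog)
  sim <- term_sim_matrix(onto, ic)
  diseases <- names(catalog)
  ethnicities <- names(config$n_background_genes)

  rows <- list()
  tables <- list()
  for (i in seq_len(config$n_cases)) {
    disease <- diseases[[(i - 1) %% length(diseases) + 1]]
    eth <- ethnicities[[(i - 1) %% length(ethnicities) + 1]]
    id <- sprintf("case%04d", i)
    case <- simulate_case(disease, catalog, gmap, config, onto,
                          seed = derive_seed(config$seed, 1000L + i),
                          case_id = id, ethnicity = eth)
    bg <- sample_background(config, gmap, eth,
                            seed = derive_seed(config$seed, 2000L + i))
    spiked <- spike_in(bg, case$causal_gene, case$causal_variant_score)
    ds <- score_all_diseases(case$hpo_terms[[1]], catalog, onto, ic, sim = sim)
    tb <- assemble_case_table(
      case, spiked,
      gestalt_by_gene = map_scores_to_genes(case$gestalt_scores[[1]], gmap),
      fm_by_gene = map_scores_to_genes(setNames(ds$feature_match, ds$disease_id), gmap),
      phen_by_gene = map_scores_to_genes(setNames(ds$phenomizer, ds$disease_id), gmap),
      boqa_by_gene = map_scores_to_genes(setNames(ds$boqa, ds$disease_id), gmap),
      fill = 0
    )
    rows[[i]] <- case
    tables[[id]] <- tb
  }
  cohort <- as_cohort(bind_rows(rows), tables)
  attr(cohort, "ontology") <- onto
  attr(cohort, "catalog") <- catalog
  attr(cohort, "map") <- gmap
  cohort
}

#' Write a synthetic cohort and its generating resources to disk
#'
#' Emits the same dialects the pipeline's readers consume (dog-fooding the
#' parsers): a directory of case JSONs, a minimal OBO file, the annotation
#' TSV, morbidmap/mim2gene-dialect map files, per-case score-table TSVs and
#' per-case background gene-score TSVs.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(dir, "cases"))
  write_obo(attr(cohort, "ontology"), file.path(dir, "ontology.obo"))
  write_disease_annotations(attr(cohort, "catalog"), file.path(dir, "annotations.tsv"))
  write_gene_map(attr(cohort, "map"), file.path(dir, "morbidmap.tsv"),
                 file.path(dir, "mim2gene.tsv"))
  if (!is.null(cohort$tables)) write_score_tables(cohort$tables, file.path(dir, "tables"))
  invisible(dir)
}
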