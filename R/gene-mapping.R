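#' Parse OMIM-dialect mapping files into a syndrome-gene map
#'
#' Composes `morbidmap` (phenotype label with MIM number, comma-separated
#' gene symbols, gene MIM, cytoband) and `mim2gene` (MIM, entry type, gene
#' id, symbol) into a bidirectional syndrome-to-gene map.  The syndrome id
#' is the 6-digit MIM number extracted from the phenotype label, reported as
#' `"OMIM:NNNNNN"`; rows without one are skipped and counted.  All
#' comma-separated symbols on a morbidmap row are linked; when the row's
#' gene MIM resolves through mim2gene, that canonical symbol is linked too.
#' Comment lines (`#`) are skipped in both files.
#'
#' @param morbidmap_path Path to the morbidmap-dialect TSV.
#' @param mim2gene_path Optional path to the mim2gene-dialect TSV.
#' @return An object of class `gene_phenotype_map`: a tibble of unique
#'   `syndrome_id`, `gene` edges with attribute `n_unmapped` (skipped
#'   morbidmap rows).
#' @export
parse_gene_map <- function(morbidmap_path, mim2gene_path = NULL) {
  mim2symbol <- character()
  if (!is.null(mim2gene_path)) {
    lines <- readLines(mim2gene_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    for (i in seq_along(lines)) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 4) {
        stop(sprintf("malformed mim2gene line %d: expected >= 4 tab-separated fields", i))
      }
      sym <- trimws(f[[4]])
      if (nzchar(sym)) mim2symbol[trimws(f[[1]])] <- sym
    }
  }

  lines <- readLines(morbidmap_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  edges <- list()
  n_unmapped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) {
      stop(sprintf("malformed morbidmap line %d: expected >= 2 tab-separated fields", i))
    }
    mim <- stringr::str_match(f[[1]], "(\\d{6})")[, 2]
    if (is.na(mim)) { n_unmapped <- n_unmapped + 1L; next }
    genes <- trimws(strsplit(f[[2]], ",", fixed = TRUE)[[1]])
    genes <- genes[nzchar(genes)]
    if (length(f) >= 3) {
      canonical <- mim2symbol[trimws(f[[3]])]
      if (!is.na(canonical)) genes <- union(genes, canonical)
    }
    if (length(genes) == 0) { n_unmapped <- n_unmapped + 1L; next }
    edges[[length(edges) + 1]] <- tibble(syndrome_id = paste0("OMIM:", mim),
                                         gene = genes)
  }
  out <- if (length(edges) == 0) {
    tibble(syndrome_id = character(), gene = character())
  } else {
    dplyr::distinct(bind_rows(edges))
  }
  if (n_unmapped > 0) {
    message(n_unmapped, " morbidmap row(s) had no extractable syndrome MIM or gene and were skipped")
  }
  structure(out, class = c("gene_phenotype_map", class(out)), n_unmapped = n_unmapped)
}

#' Build a syndrome-gene map directly from an edge table
#'
#' @param edges Tibble (or data frame) with columns `syndrome_id`, `gene`.
#' @return A `gene_phenotype_map`.
#' @export
gene_phenotype_map <- function(edges) {
  edges <- dplyr::distinct(as_tibble(edges)[, c("syndrome_id", "gene")])
  structure(edges, class = c("gene_phenotype_map", class(edges)), n_unmapped = 0L)
}

#' Genes linked to each syndrome, and the inverse
#'
#' @param map A `gene_phenotype_map`.
#' @return For [syndrome_to_genes()], a named list syndrome_id -> gene
#'   symbols; for [gene_to_syndromes()], the exact inverse.
#' @export
syndrome_to_genes <- function(map) {
  split(map$gene, map$syndrome_id)
}

#' @rdname syndrome_to_genes
#' @export
gene_to_syndromes <- function(map) {
  split(map$syndrome_id, map$gene)
}

#' Map per-syndrome phenotype scores onto genes
#'
#' Each gene receives the maximum score over its linked syndromes that
#' appear in the score vector (a gene associated with several scored
#' syndromes keeps the highest).  Genes none of whose syndromes are scored
#' are absent from the output; syndromes in the vector with no gene link
#' contribute nothing (their count is attached as attribute `n_dropped`).
#'
#' @param scores Named numeric vector (or tibble `syndrome_id`, `score`) of
#'   per-syndrome scores.
#' @param map A `gene_phenotype_map`.
#' @return Tibble `gene`, `score`, sorted by gene, with attribute
#'   `n_dropped`.
#' @export
map_scores_to_genes <- function(scores, map) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$syndrome_id)
  }
  if (length(scores) == 0) {
    return(structure(tibble(gene = character(), score = numeric()), n_dropped = 0L))
  }
  df <- tibble(syndrome_id = names(scores), score = as.numeric(scores))
  n_dropped <- sum(!df$syndrome_id %in% map$syndrome_id)
  out <- df |>
    dplyr::inner_join(as_tibble(map), by = "syndrome_id") |>
    group_by(gene = .data$gene) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    arrange(.data$gene)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a syndrome-gene map as morbidmap/mim2gene-dialect TSVs
#'
#' Inverse of [parse_gene_map()] for maps whose syndrome ids carry 6-digit
#' MIM numbers; used by the simulator and round-trip tests.
#'
#' @param map A `gene_phenotype_map`.
#' @param morbidmap_path,mim2gene_path Output paths.
#' @return `morbidmap_path`, invisibly.
#' @export
write_gene_map <- function(map, morbidmap_path, mim2gene_path = NULL) {
  s2g <- syndrome_to_genes(map)
  lines <- imap(s2g, function(genes, sid) {
    mim <- stringr::str_match(sid, "(\\d{6})")[, 2]
    sprintf("Syndrome %s, %s (3)\t%s\t\t", mim, mim, paste(genes, collapse = ", "))
  })
  writeLines(unlist(lines), morbidmap_path)
  if (!is.null(mim2gene_path)) {
    genes <- sort(unique(map$gene))
    writeLines(sprintf("%06d\tgene\t%d\t%s", 100000 + seq_along(genes),
                       seq_along(genes), genes), mim2gene_path)
  }
  invisible(morbidmap_path)
}
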