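#' Default INFO key names for deleteriousness-annotated VCFs
#'
#' @return Named list with entries `deleteriousness`, `gene`, `allele_freq`,
#'   `consequence` giving the INFO keys read by [read_scored_variants()].
#' @export
default_annotation_keys <- function() {
  list(deleteriousness = "CADD_PHRED", gene = "GENE",
       allele_freq = "AF", consequence = "CSQ_CLASS")
}

split_info_field <- function(value, n_alt, allele) {
  # Per-allele (Number=A) values are comma-separated; scalar values recycle.
  if (is.na(value)) return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  if (length(parts) == n_alt) parts[[allele]] else parts[[1]]
}

#' Read deleteriousness-annotated variants from a VCF
#'
#' Parses a VCF 4.x file whose INFO column carries per-variant
#' deleteriousness, gene symbol, allele frequency and consequence class
#' under configurable keys.  Multi-allelic lines are split into one record
#' per ALT allele (per-allele INFO values are matched positionally).
#' Records missing the deleteriousness key are skipped and counted in a
#' warning.  Missing allele frequency is treated as 0 (assumed rare).
#'
#' @param vcf_path Path to a VCF file.
#' @param annotation_keys Named list of INFO keys (see
#'   [default_annotation_keys()]).
#' @return Tibble of variant records: `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gene`, `deleteriousness`, `allele_freq`, `consequence`.
#' @export
read_scored_variants <- function(vcf_path, annotation_keys = default_annotation_keys()) {
  if (!file.exists(vcf_path)) stop("no such VCF file: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info_str <- vcf@fix[, "INFO"]
  ks <- annotation_keys
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info_string(info_str[[i]])
    for (a in seq_along(alts)) {
      del <- split_info_field(info[[ks$deleteriousness]] %||% NA_character_,
                              length(alts), a)
      if (is.na(del)) { n_skipped <- n_skipped + 1L; next }
      af <- split_info_field(info[[ks$allele_freq]] %||% NA_character_,
                             length(alts), a)
      rows[[length(rows) + 1]] <- tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[[a]],
        gene = split_info_field(info[[ks$gene]] %||% NA_character_, length(alts), a),
        deleteriousness = as.numeric(del),
        allele_freq = if (is.na(af)) 0 else as.numeric(af),
        consequence = split_info_field(info[[ks$consequence]] %||% NA_character_,
                                       length(alts), a)
      )
    }
  }
  if (n_skipped > 0) {
    warning(n_skipped, " variant record(s) lacked the '",
            ks$deleteriousness, "' key and were skipped")
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(),
                  deleteriousness = numeric(), allele_freq = numeric(),
                  consequence = character()))
  }
  bind_rows(rows)
}

parse_info_string <- function(s) {
  if (is.na(s) || s == "." || s == "") return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) > 1) x[[2]] else "TRUE")
  names(vals) <- vapply(kv, `[[`, "", 1)
  vals
}

#' Write variant records as a minimal annotated VCF
#'
#' Companion writer used by the simulator and round-trip tests; emits one
#' line per record with the four annotation keys in INFO.
#'
#' @param records Tibble of variant records (see [read_scored_variants()]).
#' @param path Output path.
#' @param annotation_keys Named list of INFO keys.
#' @return `path`, invisibly.
#' @export
write_scored_variants <- function(records, path,
                                  annotation_keys = default_annotation_keys()) {
  ks <- annotation_keys
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Deleteriousness score">', ks$deleteriousness),
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Gene symbol">', ks$gene),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Allele frequency">', ks$allele_freq),
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Consequence class">', ks$consequence),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- pmap(records, function(chrom, pos, ref, alt, gene, deleteriousness,
                                 allele_freq, consequence, ...) {
    info <- sprintf("%s=%s;%s=%s;%s=%s;%s=%s",
                    ks$deleteriousness, format(deleteriousness, digits = 15),
                    ks$gene, gene,
                    ks$allele_freq, format(allele_freq, digits = 15),
                    ks$consequence, consequence)
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", chrom, pos, ref, alt, info)
  })
  writeLines(c(header, unlist(body)), path)
  invisible(path)
}

#' Filtering configuration for rare-disease variant triage
#'
#' A parameterised simplification of trio-style rare-disease filtering:
#' variants survive iff their allele frequency is at or below
#' `max_allele_freq`, their consequence class is allowed, and (when set)
#' their deleteriousness reaches `min_deleteriousness`.  Genotype and
#' inheritance-mode logic are intentionally not modelled.
#'
#' @param max_allele_freq Maximum population allele frequency (default 0.01).
#' @param allowed_consequences Character vector of retained consequence
#'   classes.
#' @param min_deleteriousness Optional deleteriousness floor.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_allele_freq = 0.01,
                          allowed_consequences = c("missense", "stop_gained",
                                                   "frameshift", "splice",
                                                   "inframe_indel"),
                          min_deleteriousness = NULL) {
  stopifnot(max_allele_freq >= 0, max_allele_freq <= 1)
  structure(list(max_allele_freq = max_allele_freq,
                 allowed_consequences = allowed_consequences,
                 min_deleteriousness = min_deleteriousness),
            class = "filter_config")
}

#' Filter variant records
#'
#' @param records Tibble of variant records.
#' @param config A [filter_config()].
#' @return The surviving records, input order preserved.  Idempotent.
#' @export
filter_variants <- function(records, config = filter_config()) {
  if (nrow(records) == 0) return(records)
  keep <- records$allele_freq <= config$max_allele_freq &
    records$consequence %in% config$allowed_consequences
  if (!is.null(config$min_deleteriousness)) {
    keep <- keep & records$deleteriousness >= config$min_deleteriousness
  }
  records[keep, , drop = FALSE]
}

#' Reduce variants to the per-gene maximum deleteriousness
#'
#' Each gene appearing in the (already filtered) records maps to the maximum
#' of its deleteriousness values, regardless of genotype — a
#' sensitivity-maximising heuristic for compound-heterozygous recessive
#' cases, where the second hit may score low.
#'
#' @param records Tibble of variant records with `gene` and
#'   `deleteriousness`.
#' @return Tibble `gene`, `score`, sorted by gene.
#' @export
gene_max_score <- function(records) {
  if (nrow(records) == 0) return(tibble(gene = character(), score = numeric()))
  records |>
    group_by(gene = .data$gene) |>
    summarise(score = max(.data$deleteriousness), .groups = "drop") |>
    arrange(.data$gene)
}

#' Spike a causal variant score into a background exome
#'
#' Returns the background per-gene score map with the causal gene's entry
#' raised to `max(background, causal_score)`; every other entry is untouched
#' and the input is not modified.  Guarantees the causal gene is present.
#'
#' @param background Tibble `gene`, `score` (a per-gene max map).
#' @param causal_gene Gene symbol to spike.
#' @param causal_score Nonnegative deleteriousness score of the causal
#'   variant.
#' @return Tibble `gene`, `score`, sorted by gene.
#' @export
spike_in <- function(background, causal_gene, causal_score) {
  stopifnot(causal_score >= 0)
  if (causal_gene %in% background$gene) {
    i <- match(causal_gene, background$gene)
    background$score[[i]] <- max(background$score[[i]], causal_score)
    out <- background
  } else {
    out <- bind_rows(background, tibble(gene = causal_gene, score = causal_score))
  }
  arrange(out, .data$gene)
}

#' Write a per-gene score map as two-column TSV
#'
#' @param scores Tibble `gene`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' Read a per-gene score map written by [write_gene_scores()]
#'
#' @param path TSV path.
#' @return Tibble `gene`, `score`.
#' @export
read_gene_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = "c", score = "d"))
}
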