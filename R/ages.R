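#' Taxonomic levels with homology evidence, per gene
#'
#' Maps every hit's subject taxon to its divergence level against the
#' (possibly collapsed) lineage and returns the distinct levels represented
#' for each gene — the trace-back of homolog presence through all
#' intermediate taxonomic levels. Subjects that do not fall under the
#' lineage root are unmappable; they are skipped and counted in attribute
#' `n_unmappable`.
#'
#' @param hits Filtered hit tibble (see [read_hit_table()]).
#' @param lineage Lineage tibble.
#' @param db Taxonomy tibble.
#' @return Tibble with columns `query`, `level`, `source` (distinct rows),
#'   attribute `n_unmappable`.
#' @export
levels_present <- function(hits, lineage, db) {
  hits <- tibble::as_tibble(hits)
  lv <- divergence_level(lineage, db, hits$taxid)
  n_unmappable <- sum(is.na(lv))
  out <- hits |>
    dplyr::mutate(level = lv) |>
    dplyr::filter(!is.na(.data$level)) |>
    dplyr::distinct(.data$query, .data$level, .data$source)
  structure(out, n_unmappable = n_unmappable)
}

#' Representativeness score of an age assignment
#'
#' Given the set of lineage levels at which a gene has homologs and its age
#' `k` (the oldest such level, `AP` in the field's notation), computes `RP`,
#' the number of represented levels among `2..k`, and the taxonomic
#' representativeness score
#' \deqn{L = 100 \times RP / (AP - 1)}{L = 100 * RP / (AP - 1)}
#' The youngest level is excluded from the denominator because presence in
#' the focal species is self-confirming; for the same reason a gene found
#' only at level 1 gets `L = 100` by convention. `L` ranges from
#' `100/(k-1)` (homologs only at the oldest level) to 100 (every
#' intermediate level represented); low scores flag putative contamination,
#' horizontal transfer, or false-positive matches.
#'
#' @param levels Integer vector of represented levels for one gene.
#' @param k Age level; defaults to `max(levels)`.
#' @return One-row tibble with columns `rp` and `score`.
#' @export
representativeness <- function(levels, k = max(levels)) {
  stopifnot(length(levels) > 0, k == max(levels))
  if (k == 1) {
    return(tibble::tibble(rp = 0L, score = 100))
  }
  rp <- length(unique(levels[levels >= 2 & levels <= k]))
  tibble::tibble(rp = rp, score = 100 * rp / (k - 1))
}

#' Oldest-level hit with the highest bitscore
#'
#' The optional "best distant hit" report: among a gene's hits at its age
#' level `k`, the one with maximal bitscore; ties broken by smaller
#' e-value, then lexicographically smallest subject id. Used to manually
#' vet genes with low representativeness.
#'
#' @param gene_hits Hit tibble for one gene with a `level` column.
#' @param k The gene's age level.
#' @return One-row tibble (subset of `gene_hits`).
#' @export
best_distant_hit <- function(gene_hits, k) {
  gene_hits |>
    dplyr::filter(.data$level == k) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject) |>
    dplyr::slice(1)
}

#' Assign gene ages by taxonomic trace-back
#'
#' The per-gene core of the pipeline. For every query gene: (i) the age
#' level `k` is the oldest lineage level with a surviving homology hit;
#' (ii) the representativeness score `L` summarises how many intermediate
#' levels between the focal species and level `k` carry at least one hit;
#' (iii) genes with `L` below `flag_threshold` (strict `<`) are flagged as
#' putative horizontal transfer, contamination, or false positives and
#' carry no usable age for family dating — they stay in the output with
#' their `k` and `L` so users can re-threshold; (iv) genes in
#' `all_query_ids` with no surviving hits are reported `"absent"`; (v) the
#' best distant hit at level `k` is reported.
#'
#' @param hits Filtered (and possibly source-merged) hit tibble.
#' @param lineage Lineage tibble (collapsed if applicable).
#' @param db Taxonomy tibble.
#' @param all_query_ids Full proteome id vector; defaults to the hit
#'   table's `all_queries` attribute.
#' @param flag_threshold Representativeness flagging threshold in percent
#'   (default 30).
#' @return Tibble, one row per gene, sorted by gene id, with columns
#'   `gene`, `age_level`, `level_name`, `level_rank`, `rp`, `score`,
#'   `status` (`assigned`/`flagged`/`absent`), `best_hit_subject`,
#'   `best_hit_bitscore`, `best_hit_taxid`, `evidence_source`. Attribute
#'   `n_unmappable` counts skipped hits.
#' @export
gene_ages <- function(hits, lineage, db, all_query_ids = NULL,
                      flag_threshold = 30) {
  stopifnot(flag_threshold > 0, flag_threshold <= 100)
  if (is.null(all_query_ids)) {
    all_query_ids <- attr(hits, "all_queries")
    if (is.null(all_query_ids)) all_query_ids <- unique(hits$query)
  }
  lp <- levels_present(hits, lineage, db)

  hits_lv <- tibble::as_tibble(hits) |>
    dplyr::mutate(level = divergence_level(lineage, db, .data$taxid)) |>
    dplyr::filter(!is.na(.data$level))

  per_gene <- lp |>
    dplyr::group_by(.data$query) |>
    dplyr::summarise(
      age_level = max(.data$level),
      rp = length(unique(.data$level[.data$level >= 2])),
      evidence_source = paste(sort(unique(
        .data$source[.data$level == max(.data$level)])), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      score = dplyr::if_else(.data$age_level == 1, 100,
                             100 * .data$rp / (.data$age_level - 1)),
      rp = dplyr::if_else(.data$age_level == 1, 0L, .data$rp),
      status = dplyr::if_else(.data$score < flag_threshold,
                              "flagged", "assigned")
    )

  best <- hits_lv |>
    dplyr::inner_join(dplyr::select(per_gene, "query", "age_level"),
                      by = "query") |>
    dplyr::filter(.data$level == .data$age_level) |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore), .data$evalue,
                   .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::select("query", best_hit_subject = "subject",
                  best_hit_bitscore = "bitscore", best_hit_taxid = "taxid")

  out <- per_gene |>
    dplyr::left_join(best, by = "query") |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(lineage), "level",
                    level_name = "name", level_rank = "rank"),
      by = c(age_level = "level")
    )

  absent <- detect_absent_genes(all_query_ids, hits)
  if (length(absent) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(query = absent,
                                                status = "absent"))
  }
  out <- out |>
    dplyr::rename(gene = "query") |>
    dplyr::select("gene", "age_level", "level_name", "level_rank", "rp",
                  "score", "status", "best_hit_subject",
                  "best_hit_bitscore", "best_hit_taxid",
                  "evidence_source") |>
    dplyr::arrange(.data$gene)
  structure(out, n_unmappable = attr(lp, "n_unmappable"))
}
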