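#' Read a tabular homology hit file
#'
#' Reads a BLAST/DIAMOND `outfmt 6`-style TSV (no header) and applies the
#' e-value filter used throughout the pipeline. Hits are never truncated by
#' rank or count: with databases covering tens of thousands of species, any
#' per-query cap on reported hits discards age-assignable information, so
#' every row passing the e-value filter is kept. Cells with several
#' semicolon-separated subject taxids expand to one record per taxid.
#' Malformed rows (non-numeric e-value/bitscore/taxid, too few fields) are
#' counted and dropped, not fatal; the count is attached as attribute
#' `n_malformed`.
#'
#' @param path Path to the TSV (gzip transparent).
#' @param evalue_max Inclusive e-value threshold; records with
#'   `evalue <= evalue_max` are emitted. Default `1e-5`. An e-value of 0 is
#'   the strongest possible hit and always passes.
#' @param columns Character vector naming the file's columns in order; must
#'   contain `qseqid`, `sseqid`, `evalue`, `bitscore`, `staxids`. Default is
#'   that five-column order.
#' @param source Provenance tag for every record: `"protein"` (annotated
#'   protein search) or `"genome"` (six-frame protein-vs-genome search).
#' @return A tibble of hit records with columns `query`, `subject`,
#'   `evalue`, `bitscore`, `taxid`, `source`. Attributes: `all_queries`
#'   (query ids seen before filtering, used for absent-gene detection),
#'   `n_malformed`, `n_filtered`.
#' @export
read_hit_table <- function(path, evalue_max = 1e-5,
                           columns = c("qseqid", "sseqid", "evalue",
                                       "bitscore", "staxids"),
                           source = c("protein", "genome")) {
  source <- match.arg(source)
  stopifnot(evalue_max > 0)
  mandatory <- c("qseqid", "sseqid", "evalue", "bitscore", "staxids")
  missing <- setdiff(mandatory, columns)
  if (length(missing) > 0) {
    stop("hit-table column map is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_tsv(
    path, col_names = columns,
    col_types = paste(rep("c", length(columns)), collapse = ""),
    progress = FALSE
  ))
  if (nrow(raw) == 0) {
    warning("empty hit file: ", path, call. = FALSE)
  }
  tbl <- tibble::tibble(
    query = raw$qseqid,
    subject = raw$sseqid,
    evalue = suppressWarnings(as.numeric(raw$evalue)),
    bitscore = suppressWarnings(as.numeric(raw$bitscore)),
    staxids = raw$staxids
  )
  ok <- !is.na(tbl$query) & !is.na(tbl$subject) &
    !is.na(tbl$evalue) & tbl$evalue >= 0 &
    !is.na(tbl$bitscore) & tbl$bitscore > 0 & !is.na(tbl$staxids)
  n_malformed <- sum(!ok)
  tbl <- tbl[ok, ]
  tbl <- tidyr::separate_rows(tbl, "staxids", sep = ";")
  tbl$taxid <- suppressWarnings(as.integer(tbl$staxids))
  n_malformed <- n_malformed + sum(is.na(tbl$taxid))
  tbl <- tbl[!is.na(tbl$taxid), ]
  all_queries <- unique(tbl$query)
  pass <- tbl$evalue <= evalue_max
  out <- dplyr::select(tbl[pass, ], "query", "subject", "evalue",
                       "bitscore", "taxid")
  out$source <- source
  structure(out,
            all_queries = all_queries,
            n_malformed = n_malformed,
            n_filtered = sum(!pass))
}

#' Genes with no surviving hits
#'
#' A gene that fails to match anything — including itself — after e-value
#' filtering receives no age and is reported with status `"absent"`.
#' Overly stringent e-value thresholds inflate this set.
#'
#' @param all_query_ids Character vector: the full query proteome.
#' @param hits Filtered hit tibble.
#' @return Character vector of absent gene ids (sorted).
#' @export
detect_absent_genes <- function(all_query_ids, hits) {
  sort(setdiff(all_query_ids, unique(hits$query)))
}

#' Merge protein-search and genome-search hits
#'
#' Takes the union of the two filtered hit streams with their `source` tags
#' preserved; downstream, a gene's age is the oldest level supported by
#' either source, so six-frame genome evidence can push young, annotation-
#' sensitive age assignments to older levels. No record is ever dropped;
#' duplicate (query, subject) pairs seen in both sources are both kept.
#'
#' @param protein_hits,genome_hits Hit tibbles filtered at the same
#'   threshold (either may be `NULL` or empty).
#' @return Combined hit tibble; attribute `all_queries` is the union of the
#'   inputs' attributes.
#' @export
merge_hit_sources <- function(protein_hits, genome_hits = NULL) {
  if (is.null(genome_hits)) return(protein_hits)
  if (is.null(protein_hits)) return(genome_hits)
  out <- dplyr::bind_rows(tibble::as_tibble(protein_hits),
                          tibble::as_tibble(genome_hits))
  structure(out,
            all_queries = union(attr(protein_hits, "all_queries"),
                                attr(genome_hits, "all_queries")))
}
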