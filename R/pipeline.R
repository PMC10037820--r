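#' Pipeline configuration
#'
#' Collects paths and thresholds for an end-to-end run. Mandatory inputs
#' are the taxonomy, the focal taxid and the protein hit table; the
#' genome-search hits, the all-vs-all self-hits and the evolutionary
#' distance table are optional, and the corresponding stages degrade
#' gracefully when they are missing (no six-frame merge; singleton
#' families; no HDF assessment).
#'
#' @param focal_taxid Focal species taxid.
#' @param taxonomy Path to `nodes.dmp` (with `names` alongside) or a
#'   lineage TSV, or an already-loaded taxonomy tibble.
#' @param names Path to `names.dmp` when `taxonomy` is a `nodes.dmp` path.
#' @param hits Path to the protein hit TSV, or a hit tibble.
#' @param genome_hits Optional six-frame protein-vs-genome hit table.
#' @param self_hits Optional all-vs-all hit table for family clustering.
#' @param distances Optional distance table (TSV with header columns
#'   `taxid`, `distance`, or a tibble).
#' @param all_query_ids Optional full proteome id vector; defaults to the
#'   query ids seen in the raw hit files.
#' @param evalue_max E-value threshold (default 1e-5).
#' @param flag_threshold Representativeness flag threshold in percent
#'   (default 30).
#' @param retention_fraction Level-retention fraction (default 0.10).
#' @param exclude_levels Level names collapsed unconditionally.
#' @param inflation MCL inflation (default 2).
#' @param alpha HDF significance level (default 0.05).
#' @param s_thr Detectability threshold override in bits.
#' @param query_length,database_size `m`, `n` for the Karlin–Altschul
#'   threshold when `s_thr` is `NULL`.
#' @param out_dir Optional output directory; when given, all result tables
#'   plus a run-metadata JSON are written there.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(focal_taxid, taxonomy, hits,
                            names = NULL, genome_hits = NULL,
                            self_hits = NULL, distances = NULL,
                            all_query_ids = NULL,
                            evalue_max = 1e-5, flag_threshold = 30,
                            retention_fraction = 0.10,
                            exclude_levels = character(),
                            inflation = 2, alpha = 0.05, s_thr = NULL,
                            query_length = 400, database_size = 1e10,
                            out_dir = NULL) {
  stopifnot(evalue_max > 0, flag_threshold > 0, flag_threshold <= 100,
            retention_fraction >= 0, retention_fraction < 1,
            inflation > 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the founder-event pipeline end to end
#'
#' Executes every stage in order: read and e-value-filter the hit tables
#' (merging genome-search evidence when present), build and collapse the
#' focal lineage, assign per-gene ages with representativeness scores,
#' cluster paralogs into families and date them by their oldest reliable
#' member, and — when a distance table is supplied — run the HDF test and
#' flag high-confidence founder events. Founder-event counts per level are
#' reported before and after HDF filtering. Outputs are fully
#' deterministic and sorted for diff-stability.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"founder_run"` with elements `lineage`,
#'   `ages`, `families`, `founder_counts` (with column `set` =
#'   `"all"` / `"high_confidence"`), `hdf` (or `NULL`), `metadata`.
#'   Written to `config$out_dir` when set (`lineage.tsv`,
#'   `gene_ages.tsv`, `families.tsv`, `founder_counts.tsv`,
#'   `hdf_assessments.tsv`, `run_metadata.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  db <- if (is.data.frame(config$taxonomy)) {
    validate_taxonomy(config$taxonomy)
  } else {
    load_taxonomy(config$taxonomy, config$names)
  }
  read_or_pass <- function(x, source) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    read_hit_table(x, evalue_max = config$evalue_max, source = source)
  }
  prot <- read_or_pass(config$hits, "protein")
  geno <- read_or_pass(config$genome_hits, "genome")
  hits <- merge_hit_sources(prot, geno)
  all_query_ids <- config$all_query_ids %||% attr(hits, "all_queries")

  lineage_full <- focal_lineage(db, config$focal_taxid)
  fractions <- hits |>
    dplyr::distinct(.data$taxid, .data$query) |>
    dplyr::count(.data$taxid, name = "n_genes") |>
    dplyr::mutate(fraction = .data$n_genes / length(all_query_ids))
  lineage <- collapse_levels(lineage_full, db, fractions,
                             retention_fraction = config$retention_fraction,
                             exclude_names = config$exclude_levels)

  ages <- gene_ages(hits, lineage, db, all_query_ids = all_query_ids,
                    flag_threshold = config$flag_threshold)

  aged_genes <- ages$gene[ages$status != "absent"]
  if (!is.null(config$self_hits)) {
    sh <- read_or_pass(config$self_hits, "protein")
    graph <- build_similarity_graph(
      dplyr::filter(sh, .data$query %in% aged_genes,
                    .data$subject %in% aged_genes))
    partition <- mcl_cluster(graph, inflation = config$inflation)
  } else {
    partition <- tibble::tibble(gene = character(0), family = integer(0))
  }
  families <- family_founder_age(partition, ages,
                                 singletons = setdiff(aged_genes,
                                                      partition$gene))

  hdf <- NULL
  if (!is.null(config$distances)) {
    distances <- if (is.data.frame(config$distances)) {
      tibble::as_tibble(config$distances)
    } else {
      readr::read_tsv(config$distances,
                      col_types = readr::cols(
                        taxid = readr::col_integer(),
                        distance = readr::col_double()),
                      progress = FALSE)
    }
    s_thr <- bitscore_threshold(config$query_length,
                                config$database_size,
                                config$evalue_max,
                                override = config$s_thr)
    hdf <- hdf_assess(hits, ages, distances, lineage, db, s_thr,
                      alpha = config$alpha)
    families <- family_confidence(families, hdf, ages)
  }

  counts_all <- founder_event_counts(families, lineage) |>
    dplyr::mutate(set = "all")
  founder_counts <- counts_all
  if (!is.null(hdf)) {
    founder_counts <- dplyr::bind_rows(
      counts_all,
      founder_event_counts(families, lineage,
                           high_confidence_only = TRUE) |>
        dplyr::mutate(set = "high_confidence"))
  }

  metadata <- list(
    package_version = as.character(utils::packageVersion("genefounder")),
    focal_taxid = config$focal_taxid,
    evalue_max = config$evalue_max,
    evalue_comparison = "inclusive (<=)",
    flag_threshold = config$flag_threshold,
    retention_fraction = config$retention_fraction,
    exclude_levels = config$exclude_levels,
    inflation = config$inflation,
    alpha = config$alpha,
    s_thr = config$s_thr,
    n_query_genes = length(all_query_ids),
    n_hits = nrow(hits),
    n_unmappable_hits = attr(ages, "n_unmappable"),
    n_absent = sum(ages$status == "absent"),
    n_flagged = sum(ages$status == "flagged"),
    n_families = nrow(families),
    input_md5 = input_checksums(config)
  )

  run <- structure(list(lineage = lineage, ages = ages,
                        families = families,
                        founder_counts = founder_counts, hdf = hdf,
                        metadata = metadata),
                   class = "founder_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

input_checksums <- function(config) {
  paths <- purrr::keep(
    list(taxonomy = config$taxonomy, names = config$names,
         hits = config$hits, genome_hits = config$genome_hits,
         self_hits = config$self_hits, distances = config$distances),
    ~ is.character(.x) && length(.x) == 1 && file.exists(.x))
  purrr::map(paths, ~ unname(tools::md5sum(.x)))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_lineage(run$lineage, file.path(out_dir, "lineage.tsv"))
  readr::write_tsv(run$ages, file.path(out_dir, "gene_ages.tsv"),
                   progress = FALSE)
  fams <- run$families |>
    dplyr::mutate(members = purrr::map_chr(.data$members, paste,
                                           collapse = ";"))
  readr::write_tsv(fams, file.path(out_dir, "families.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$founder_counts,
                   file.path(out_dir, "founder_counts.tsv"),
                   progress = FALSE)
  if (!is.null(run$hdf)) {
    readr::write_tsv(run$hdf, file.path(out_dir, "hdf_assessments.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$metadata,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.founder_run <- function(x, ...) {
  cat("founder-event run:", x$metadata$n_query_genes, "query genes,",
      nrow(x$lineage), "retained levels,",
      x$metadata$n_families, "families\n")
  cat("  absent:", x$metadata$n_absent,
      " flagged:", x$metadata$n_flagged, "\n")
  if (!is.null(x$hdf)) {
    cat("  high-confidence founder events:",
        sum(x$families$high_confidence, na.rm = TRUE), "of",
        sum(!is.na(x$families$founder_level)), "dated families\n")
  }
  invisible(x)
}
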