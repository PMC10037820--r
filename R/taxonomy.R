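#' Load a taxonomy from taxdump files or a lineage table
#'
#' Reads a local copy of an NCBI-taxdump-style taxonomy (`nodes.dmp` plus
#' `names.dmp`, pipe-with-tabs delimited) or, when `names` is `NULL`, a
#' four-column TSV (`taxid`, `parent_taxid`, `rank`, `name`). The result is
#' validated: exactly one root (a node that is its own parent), no dangling
#' parent pointers, no cycles.
#'
#' @param nodes Path to `nodes.dmp`, or to the four-column lineage TSV.
#' @param names Path to `names.dmp`; only rows of name class
#'   `"scientific name"` are used. `NULL` selects the TSV dialect.
#' @return A tibble with columns `taxid`, `parent_taxid`, `rank`, `name`,
#'   one row per taxon.
#' @examples
#' tf <- tempfile()
#' readr::write_tsv(tibble::tibble(
#'   taxid = c(1L, 2L, 3L), parent_taxid = c(1L, 1L, 2L),
#'   rank = c("no rank", "kingdom", "species"),
#'   name = c("root", "K", "S")), tf)
#' load_taxonomy(tf)
#' @export
load_taxonomy <- function(nodes, names = NULL) {
  if (is.null(names)) {
    tax <- readr::read_tsv(
      nodes,
      col_types = readr::cols(
        taxid = readr::col_integer(),
        parent_taxid = readr::col_integer(),
        rank = readr::col_character(),
        name = readr::col_character()
      ),
      progress = FALSE
    )
    missing <- setdiff(c("taxid", "parent_taxid", "rank", "name"),
                       base::names(tax))
    if (length(missing) > 0) {
      stop("lineage TSV is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tax <- dplyr::select(tax, "taxid", "parent_taxid", "rank", "name")
  } else {
    nd <- parse_dmp(nodes)
    nm <- parse_dmp(names)
    tax <- tibble::tibble(
      taxid = as.integer(purrr::map_chr(nd, 1)),
      parent_taxid = as.integer(purrr::map_chr(nd, 2)),
      rank = purrr::map_chr(nd, 3)
    )
    name_class <- purrr::map_chr(nm, ~ .x[min(4L, length(.x))])
    nm_tbl <- tibble::tibble(
      taxid = as.integer(purrr::map_chr(nm, 1)),
      name = purrr::map_chr(nm, 2)
    )[name_class == "scientific name", ]
    tax <- dplyr::left_join(tax, nm_tbl, by = "taxid")
  }
  validate_taxonomy(tax)
}

# Split one taxdump file into per-line fields ("a\t|\tb\t|\t...\t|")
parse_dmp <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
}

#' Validate a taxonomy table
#'
#' Checks the structural invariants a taxonomy must satisfy before it can be
#' walked: unique taxids, every parent resolvable, exactly one root, and an
#' acyclic parent relation.
#'
#' @param tax A data frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`.
#' @return The validated taxonomy as a tibble (invisibly usable in pipes).
#' @export
validate_taxonomy <- function(tax) {
  tax <- tibble::as_tibble(tax)
  if (anyDuplicated(tax$taxid) > 0) {
    stop("duplicated taxid(s): ",
         paste(unique(tax$taxid[duplicated(tax$taxid)]), collapse = ", "),
         call. = FALSE)
  }
  dangling <- setdiff(tax$parent_taxid, tax$taxid)
  if (length(dangling) > 0) {
    stop("dangling parent taxid(s) not present as nodes: ",
         paste(sort(dangling), collapse = ", "), call. = FALSE)
  }
  roots <- tax$taxid[tax$taxid == tax$parent_taxid]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root (own parent); found ",
         length(roots), call. = FALSE)
  }
  # Cycle check: chase parents from every node; a chain longer than the node
  # count that never reaches the root implies a cycle.
  parent <- stats::setNames(tax$parent_taxid, tax$taxid)
  cur <- tax$taxid
  for (i in seq_len(nrow(tax) + 1L)) {
    done <- cur == parent[as.character(cur)]
    if (all(done)) break
    cur <- ifelse(done, cur, unname(parent[as.character(cur)]))
    if (i > nrow(tax)) {
      stop("cycle detected in taxonomy parent pointers", call. = FALSE)
    }
  }
  tax
}

#' Build the focal species' ordered lineage
#'
#' Walks the parent chain from the focal taxon to the root and returns the
#' hierarchically ordered taxonomic levels, youngest to oldest. Level 1 is
#' the focal species itself; level N is the root. The level index is the
#' phylostratum used by all downstream age assignment.
#'
#' @param db Taxonomy tibble from [load_taxonomy()].
#' @param focal_taxid Integer taxid of the query species.
#' @return A tibble with columns `level`, `taxid`, `rank`, `name` and
#'   attribute `focal_taxid`, of class `"gf_lineage"`.
#' @export
focal_lineage <- function(db, focal_taxid) {
  focal_taxid <- as.integer(focal_taxid)
  if (!focal_taxid %in% db$taxid) {
    stop("focal taxid ", focal_taxid, " not found in taxonomy", call. = FALSE)
  }
  parent <- stats::setNames(db$parent_taxid, db$taxid)
  chain <- integer(0)
  t <- focal_taxid
  repeat {
    chain <- c(chain, t)
    p <- unname(parent[as.character(t)])
    if (p == t) break
    t <- p
  }
  out <- tibble::tibble(level = seq_along(chain), taxid = chain) |>
    dplyr::left_join(dplyr::select(db, "taxid", "rank", "name"), by = "taxid")
  new_lineage(out, focal_taxid)
}

new_lineage <- function(tbl, focal_taxid) {
  structure(
    tbl,
    focal_taxid = as.integer(focal_taxid),
    class = c("gf_lineage", class(tibble::as_tibble(tbl)))
  )
}

#' Divergence level of subject taxa relative to the focal species
#'
#' For each subject taxid, finds the youngest lineage level whose taxon
#' contains the subject — equivalently the lowest-common-ancestor level with
#' the focal species. Subjects not contained under the lineage root are
#' unmappable and return `NA` (callers discard those hits and report the
#' count).
#'
#' @param lineage Lineage tibble from [focal_lineage()] (possibly collapsed).
#' @param db Taxonomy tibble.
#' @param subject_taxid Integer vector of subject taxids.
#' @return Integer vector of level indices, `NA` where unmappable.
#' @export
divergence_level <- function(lineage, db, subject_taxid) {
  parent <- stats::setNames(db$parent_taxid, db$taxid)
  level_of <- stats::setNames(lineage$level, lineage$taxid)
  uniq <- unique(as.integer(subject_taxid))
  lev <- vapply(uniq, function(t) {
    for (i in seq_len(length(parent) + 1L)) {
      hit <- level_of[as.character(t)]
      if (!is.na(hit)) return(as.integer(hit))
      p <- parent[as.character(t)]
      if (is.na(p) || p == t) return(NA_integer_)
      t <- unname(p)
    }
    NA_integer_
  }, integer(1))
  unname(lev[match(as.integer(subject_taxid), uniq)])
}

#' Collapse taxonomic levels lacking genomic representation
#'
#' A level is retained only if at least one species diverging at that level
#' matches more than `retention_fraction` of the query proteome (strict
#' inequality), mirroring the rule that excludes taxa represented in the
#' database by a handful of sequences rather than genomic data. Level 1 (the
#' focal species) and level N (the root) are always retained. Interior levels
#' named in `exclude_names` are removed unconditionally — the escape hatch
#' for non-monophyletic levels. Remaining levels are renumbered contiguously;
#' the old-to-new index map is attached as attribute `level_map` (a dropped
#' old level maps to the next retained older level, which is where its
#' species re-map on the collapsed lineage).
#'
#' @param lineage Lineage tibble from [focal_lineage()].
#' @param db Taxonomy tibble.
#' @param species_fractions Data frame with columns `taxid` and `fraction`
#'   (proportion of all query proteins matched by that species, in `[0,1]`).
#' @param retention_fraction Retention threshold; default 0.10.
#' @param exclude_names Character vector of level names to drop
#'   unconditionally.
#' @return A collapsed lineage tibble with columns `level`, `old_level`,
#'   `taxid`, `rank`, `name`, attribute `level_map`.
#' @export
collapse_levels <- function(lineage, db, species_fractions,
                            retention_fraction = 0.10,
                            exclude_names = character()) {
  stopifnot(all(species_fractions$fraction >= 0),
            all(species_fractions$fraction <= 1))
  n <- nrow(lineage)
  old_level <- if ("old_level" %in% names(lineage)) lineage$old_level else lineage$level
  supported <- rep(FALSE, n)
  if (nrow(species_fractions) > 0) {
    lv <- divergence_level(lineage, db, species_fractions$taxid)
    ok <- !is.na(lv) & species_fractions$fraction > retention_fraction
    supported[unique(lv[ok])] <- TRUE
  }
  keep <- supported
  keep[c(1L, n)] <- TRUE
  bad_excl <- intersect(exclude_names, lineage$name[c(1L, n)])
  if (length(bad_excl) > 0) {
    warning("focal species and root levels cannot be excluded; ignoring: ",
            paste(bad_excl, collapse = ", "), call. = FALSE)
  }
  keep[lineage$name %in% setdiff(exclude_names, bad_excl)] <- FALSE
  keep[c(1L, n)] <- TRUE

  new_idx <- cumsum(keep)
  # dropped level j re-maps to the next retained older level
  map_new <- vapply(seq_len(n), function(j) {
    jj <- j
    while (!keep[jj]) jj <- jj + 1L
    new_idx[jj]
  }, integer(1))
  out <- tibble::tibble(
    level = new_idx[keep],
    old_level = old_level[keep],
    taxid = lineage$taxid[keep],
    rank = lineage$rank[keep],
    name = lineage$name[keep]
  )
  res <- new_lineage(out, attr(lineage, "focal_taxid"))
  attr(res, "level_map") <- tibble::tibble(
    old_level = old_level, new_level = map_new, retained = keep
  )
  res
}

#' Write a lineage table to TSV
#'
#' @param lineage Lineage tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lineage, path) {
  readr::write_tsv(tibble::as_tibble(lineage), path, progress = FALSE)
  invisible(path)
}
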