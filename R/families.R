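#' Build a paralog similarity graph from all-vs-all hits
#'
#' Converts an all-vs-all self-search hit table into an undirected weighted
#' graph over query genes. Edge weight is the negative log10 of the best
#' (smallest) e-value observed between the pair in either direction, capped
#' at `cap_exponent`; an e-value of exactly 0 (underflow in the aligner)
#' maps to the cap. Self-pairs contribute the vertex but no edge.
#'
#' @param self_hits Hit tibble from [read_hit_table()], filtered at the same
#'   e-value threshold as the main search.
#' @param cap_exponent Weight cap for `-log10(evalue)`; default 200.
#' @return An object of class `"similarity_graph"`: a list with `vertices`
#'   (sorted character vector) and `edges` (tibble `from`, `to`, `weight`
#'   with `from < to`).
#' @export
build_similarity_graph <- function(self_hits, cap_exponent = 200) {
  self_hits <- tibble::as_tibble(self_hits)
  vertices <- sort(unique(c(self_hits$query, self_hits$subject)))
  pairs <- self_hits |>
    dplyr::mutate(
      from = pmin(.data$query, .data$subject),
      to = pmax(.data$query, .data$subject),
      weight = pmin(ifelse(.data$evalue <= 0, Inf, -log10(.data$evalue)),
                    cap_exponent)
    ) |>
    dplyr::filter(.data$from != .data$to)
  edges <- if (nrow(pairs) == 0) {
    tibble::tibble(from = character(0), to = character(0),
                   weight = numeric(0))
  } else {
    pairs |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to)
  }
  structure(list(vertices = vertices, edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity graph:", length(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Markov clustering of the similarity graph
#'
#' Partitions genes into families by Markov clustering (MCL): self-loops
#' equal to each column's maximum edge weight are added (weight 1 for
#' isolated vertices), the weighted adjacency matrix is column-normalised
#' into a stochastic flow matrix, and expansion (matrix squaring) alternates
#' with inflation (entrywise power `inflation` followed by renormalisation)
#' and pruning of entries below `epsilon` until the flow matrix stops
#' changing. Clusters are read from the attractor structure of the limit
#' matrix: attractors (vertices with positive return flow) that exchange
#' flow form one attractor system, and every vertex joins the system
#' receiving the largest share of its outgoing flow, ties going to the
#' system containing the lexicographically smallest attractor. The result
#' is deterministic: vertices are processed in lexicographic order.
#'
#' @param graph `"similarity_graph"` from [build_similarity_graph()].
#' @param inflation Inflation exponent (> 1); default 2. Larger values give
#'   finer clusters.
#' @param expansion Expansion power (matrix power per iteration); default 2.
#' @param epsilon Pruning threshold on flow entries; default 1e-6.
#' @param max_iter Iteration cap; if reached without convergence the current
#'   hard clustering is returned with attribute `converged = FALSE` and a
#'   warning.
#' @param tol Convergence tolerance on the max absolute change of the flow
#'   matrix; default 1e-8.
#' @return Tibble with columns `gene`, `family` (integer ids, numbered by
#'   each family's lexicographically smallest member); attribute
#'   `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2,
                        epsilon = 1e-6, max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1,
            expansion >= 2, epsilon >= 0, max_iter >= 1)
  v <- graph$vertices
  n <- length(v)
  if (n == 0) {
    return(structure(tibble::tibble(gene = character(0),
                                    family = integer(0)),
                     converged = TRUE))
  }
  A <- matrix(0, n, n, dimnames = list(v, v))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$from, v)
    j <- match(graph$edges$to, v)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  # self-loops at the column maximum (the canonical MCL convention);
  # a small constant loop would let strong pairwise edges oscillate and
  # shatter tight pairs into singletons
  loops <- apply(A, 2, max)
  diag(A) <- ifelse(loops > 0, loops, 1)
  normalize <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) { # re-anchor emptied columns on their own vertex
      M[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    sweep(M, 2, cs, "/")
  }
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx[Mx < epsilon] <- 0
    Mx <- normalize(Mx)
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current hard clustering",
            call. = FALSE)
  }
  part <- read_mcl_clusters(M, v)
  structure(part, converged = converged)
}

# Interpret a (near-)limit MCL flow matrix as a hard partition.
read_mcl_clusters <- function(M, v) {
  n <- length(v)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # attractor systems: union attractors that exchange any flow
  sys_id <- seq_along(attractors)
  find <- function(x) { while (sys_id[x] != x) x <- sys_id[x]; x }
  for (ai in seq_along(attractors)) {
    for (bi in seq_along(attractors)) {
      if (bi <= ai) next
      a <- attractors[ai]; b <- attractors[bi]
      if (M[a, b] > 0 || M[b, a] > 0) {
        ra <- find(ai); rb <- find(bi)
        sys_id[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  systems <- split(attractors, roots)
  # assign each vertex to the system with the largest incoming flow share
  assign_sys <- integer(n)
  for (jx in seq_len(n)) {
    flow <- vapply(systems, function(s) sum(M[s, jx]), numeric(1))
    if (max(flow) <= 0) {
      # isolated vertex unreached by any attractor: its own singleton
      assign_sys[jx] <- NA_integer_
      next
    }
    # tolerance on ties: exact-tie flows can differ in the last bits
    best <- which(flow >= max(flow) - 1e-9)
    if (length(best) > 1) {
      lead <- vapply(systems[best], function(s) v[min(s)], character(1))
      best <- best[order(lead)][1]
    }
    assign_sys[jx] <- best
  }
  members <- split(v[!is.na(assign_sys)], assign_sys[!is.na(assign_sys)])
  members <- c(members, as.list(v[is.na(assign_sys)]))
  lead <- vapply(members, min, character(1))
  members <- members[order(lead)]
  tibble::tibble(
    gene = unlist(members, use.names = FALSE),
    family = rep.int(seq_along(members),
                     vapply(members, length, integer(1)))
  ) |>
    dplyr::arrange(.data$gene)
}

#' Date gene families by their oldest reliable member
#'
#' A gene family's age inferences are one evolutionary event, not
#' independent values: limited traceability of some paralogs is compensated
#' by dating the whole family at the oldest *reliable* member age. Flagged
#' members (low representativeness) are excluded from the maximum; a family
#' whose members are all flagged gets an `NA` founder level. Genes absent
#' from the partition (no self-hits) can be appended as singleton families
#' via `singletons`.
#'
#' @param partition Tibble `gene`, `family` from [mcl_cluster()].
#' @param ages Gene-age tibble from [gene_ages()].
#' @param singletons Character vector of genes to add as singleton families
#'   (default none).
#' @return Tibble, one row per family: `family`, `founder_level`,
#'   `n_members`, `members` (list column of sorted gene ids).
#' @export
family_founder_age <- function(partition, ages, singletons = character()) {
  partition <- tibble::as_tibble(partition)
  singletons <- setdiff(singletons, partition$gene)
  if (length(singletons) > 0) {
    extra <- tibble::tibble(
      gene = sort(singletons),
      family = max(partition$family, 0L) + seq_along(singletons)
    )
    partition <- dplyr::bind_rows(partition, extra)
  }
  partition |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(ages), "gene", "age_level", "status"),
      by = "gene"
    ) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      founder_level = if (any(.data$status == "assigned", na.rm = TRUE)) {
        max(.data$age_level[.data$status == "assigned"], na.rm = TRUE)
      } else NA_integer_,
      n_members = dplyr::n(),
      members = list(sort(.data$gene)),
      .groups = "drop"
    ) |>
    dplyr::mutate(founder_level = as.integer(.data$founder_level)) |>
    dplyr::arrange(.data$family)
}

#' Family-corrected gene ages
#'
#' Each member's age, corrected to its family's founder level (never
#' younger than its own assigned age).
#'
#' @param families Tibble from [family_founder_age()].
#' @param ages Gene-age tibble.
#' @return Tibble `gene`, `family`, `age_level`, `corrected_level`.
#' @export
corrected_ages <- function(families, ages) {
  families |>
    dplyr::select("family", "founder_level", "members") |>
    tidyr::unnest_longer("members", values_to = "gene") |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(ages), "gene", "age_level"),
      by = "gene"
    ) |>
    dplyr::transmute(.data$gene, .data$family, .data$age_level,
                     corrected_level = .data$founder_level) |>
    dplyr::arrange(.data$gene)
}

#' Founder-event counts per taxonomic level
#'
#' Each family is one founder event at its founder level; this tallies
#' events per lineage level (zero-filled), optionally restricted to
#' high-confidence families.
#'
#' @param families Tibble from [family_founder_age()] (optionally carrying
#'   a `high_confidence` column from [family_confidence()]).
#' @param lineage Lineage tibble (gives the full level range and names).
#' @param high_confidence_only Count only families with
#'   `high_confidence == TRUE`.
#' @return Tibble `level`, `level_name`, `n_founder_events`.
#' @export
founder_event_counts <- function(families, lineage,
                                 high_confidence_only = FALSE) {
  fams <- dplyr::filter(families, !is.na(.data$founder_level))
  if (high_confidence_only) {
    stopifnot("high_confidence" %in% names(fams))
    fams <- dplyr::filter(fams, .data$high_confidence)
  }
  counts <- dplyr::count(fams, level = .data$founder_level,
                         name = "n_founder_events")
  tibble::as_tibble(lineage) |>
    dplyr::select("level", level_name = "name") |>
    dplyr::left_join(counts, by = "level") |>
    dplyr::mutate(n_founder_events = dplyr::coalesce(
      .data$n_founder_events, 0L))
}
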