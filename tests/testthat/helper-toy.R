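# Small hand-built fixtures, constructed independently of the package's
# own simulator so they can serve as oracles for it.

# Ladder taxonomy: a root, a chain of ancestors, a focal species at the
# bottom, and `species_per_level` extra species diverging at each level.
chain_taxonomy <- function(n_levels, species_per_level = 1) {
  anc <- function(j) if (j == n_levels) 1L else 100L + j
  rows <- data.frame(taxid = 1L, parent_taxid = 1L, rank = "no rank",
                     name = "cellular organisms")
  if (n_levels > 2) {
    for (j in (n_levels - 1):2) {
      rows <- rbind(rows, data.frame(
        taxid = anc(j), parent_taxid = anc(j + 1L), rank = "clade",
        name = paste0("level", j)))
    }
  }
  focal <- 1000L
  rows <- rbind(rows, data.frame(taxid = focal, parent_taxid = anc(2L),
                                 rank = "species", name = "focal"))
  ring <- NULL
  for (j in 2:n_levels) {
    for (k in seq_len(species_per_level)) {
      sp <- 1000L * j + k
      rows <- rbind(rows, data.frame(
        taxid = sp, parent_taxid = anc(j), rank = "species",
        name = paste0("sp", j, "_", k)))
      ring <- rbind(ring, data.frame(taxid = sp, level = j))
    }
  }
  list(tax = tibble::as_tibble(rows), focal = focal,
       ring = tibble::as_tibble(ring))
}

# Quick hit-record builder with sensible defaults.
make_hits <- function(query, taxid, evalue = 1e-20, bitscore = 100,
                      subject = NULL, source = "protein") {
  n <- max(length(query), length(taxid))
  subject <- subject %||% paste0("s", seq_len(n))
  tibble::tibble(query = rep_len(query, n), subject = rep_len(subject, n),
                 evalue = rep_len(evalue, n),
                 bitscore = rep_len(bitscore, n),
                 taxid = as.integer(rep_len(taxid, n)),
                 source = rep_len(source, n))
}

# All ancestors of a taxid (inclusive), by explicit chain walk.
ancestor_set <- function(tax, t) {
  parent <- stats::setNames(tax$parent_taxid, tax$taxid)
  out <- integer(0)
  repeat {
    out <- c(out, t)
    p <- unname(parent[as.character(t)])
    if (is.na(p) || p == t) break
    t <- p
  }
  out
}

# Independent LCA oracle: the smallest lineage level whose taxon is an
# ancestor of the subject (ancestor-set intersection).
lca_level_oracle <- function(tax, lineage, subject) {
  anc <- ancestor_set(tax, subject)
  shared <- lineage$level[lineage$taxid %in% anc]
  if (length(shared) == 0) NA_integer_ else min(shared)
}

# Random connected undirected graph on n vertices with weights in {1, 10}:
# a random spanning tree plus random extra edges.
random_connected_graph <- function(n) {
  v <- sprintf("v%02d", seq_len(n))
  edges <- NULL
  if (n > 1) {
    for (i in 2:n) {
      j <- sample.int(i - 1, 1)
      edges <- rbind(edges, data.frame(from = v[j], to = v[i]))
    }
    extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- extra[stats::runif(nrow(extra)) < 0.3, , drop = FALSE]
    if (nrow(pick) > 0) {
      edges <- rbind(edges, data.frame(from = v[pick[, 1]],
                                       to = v[pick[, 2]]))
    }
    edges <- unique(edges)
    edges$weight <- sample(c(1, 10), nrow(edges), replace = TRUE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  structure(list(vertices = v, edges = tibble::as_tibble(edges)),
            class = "similarity_graph")
}

# Canonical form of a partition for comparison: sorted list of sorted
# member vectors.
canonical_partition <- function(part) {
  m <- split(part$gene, part$family)
  m <- lapply(m, sort)
  unname(m[order(vapply(m, `[`, "", 1))])
}
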