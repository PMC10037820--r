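test_that("similarity graph weights are capped -log10 best e-values", {
  sh <- tibble::tibble(
    query = c("a", "a", "b", "c"),
    subject = c("b", "c", "a", "c"),
    evalue = c(1e-50, 0, 1e-30, 0),
    bitscore = 100, taxid = 1L, source = "protein")
  g <- build_similarity_graph(sh)
  w <- function(u, v) g$edges$weight[g$edges$from == u & g$edges$to == v]
  expect_equal(w("a", "b"), 50) # direct transform
  expect_equal(w("a", "c"), 200) # e-value 0 hits the cap
  # reciprocal pair: single edge at the best (smallest) e-value
  sh2 <- tibble::tibble(query = c("x", "y"), subject = c("y", "x"),
                        evalue = c(1e-10, 1e-30), bitscore = 50,
                        taxid = 1L, source = "protein")
  g2 <- build_similarity_graph(sh2)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$weight, 30)
  # self-pairs contribute the vertex but no edge
  expect_true("c" %in% g$vertices)
  expect_false(any(g$edges$from == g$edges$to))
})

test_that("MCL respects components, isolates, and weak bridges", {
  # two disconnected triangles: exactly their components
  tri <- tibble::tibble(
    query = c("a", "a", "b", "x", "x", "y"),
    subject = c("b", "c", "c", "y", "z", "z"),
    evalue = 1e-10, bitscore = 50, taxid = 1L, source = "protein")
  p <- mcl_cluster(build_similarity_graph(tri))
  expect_equal(canonical_partition(p),
               list(c("a", "b", "c"), c("x", "y", "z")))

  # isolated vertex: singleton cluster
  iso <- tibble::tibble(query = "solo", subject = "solo", evalue = 0,
                        bitscore = 500, taxid = 1L, source = "protein")
  p_iso <- mcl_cluster(build_similarity_graph(iso))
  expect_equal(p_iso$gene, "solo")
  expect_equal(nrow(p_iso), 1)

  # barbell: triangles joined by one weak edge (weight ratio 10:1)
  # splits at the bridge; checked against the independent reference
  bar <- tibble::tibble(
    query = c("a", "a", "b", "x", "x", "y", "c"),
    subject = c("b", "c", "c", "y", "z", "z", "x"),
    evalue = c(rep(1e-10, 6), 1e-1),
    bitscore = 50, taxid = 1L, source = "protein")
  g <- build_similarity_graph(bar, cap_exponent = 200)
  p_bar <- mcl_cluster(g)
  expect_equal(canonical_partition(p_bar),
               list(c("a", "b", "c"), c("x", "y", "z")))
  expect_equal(canonical_partition(p_bar),
               canonical_partition(mcl_reference(g)))
})

test_that("MCL partition properties hold on random graphs", {
  set.seed(23)
  for (i in 1:25) {
    g <- random_connected_graph(sample(2:8, 1))
    p <- mcl_cluster(g)
    # partition: every vertex in exactly one cluster
    expect_setequal(p$gene, g$vertices)
    expect_equal(nrow(p), length(g$vertices))
    # permutation invariance: relabel genes, partition structure unchanged
    perm <- sample(length(g$vertices))
    relabel <- stats::setNames(sprintf("w%02d", perm), g$vertices)
    g2 <- structure(list(
      vertices = sort(unname(relabel[g$vertices])),
      edges = dplyr::arrange(
        dplyr::mutate(g$edges,
                      from0 = unname(relabel[from]),
                      to0 = unname(relabel[to]),
                      from = pmin(from0, to0), to = pmax(from0, to0),
                      from0 = NULL, to0 = NULL),
        from, to)), class = "similarity_graph")
    p2 <- mcl_cluster(g2)
    back <- canonical_partition(
      tibble::tibble(gene = names(relabel)[match(p2$gene, relabel)],
                     family = p2$family))
    expect_equal(back, canonical_partition(p))
  }
})

test_that("family founder age is the oldest reliable member age", {
  ages <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e", "f"),
    age_level = c(2L, 5L, 3L, 4L, 2L, 7L),
    status = c("assigned", "assigned", "assigned", "assigned",
               "assigned", "flagged"))
  part <- tibble::tibble(gene = c("a", "b", "c", "e", "f"),
                         family = c(1L, 1L, 1L, 2L, 2L))
  fams <- family_founder_age(part, ages, singletons = "d")
  expect_equal(fams$founder_level[1], 5L) # max of {2,5,3}
  # flagged member excluded from the max: oracle = assigned-only subset
  expect_equal(fams$founder_level[2], 2L)
  # singleton assigned gene keeps its own age
  expect_equal(fams$founder_level[fams$n_members == 1], 4L)

  # all-flagged family: founder unassigned
  all_flag <- family_founder_age(
    tibble::tibble(gene = "f", family = 1L), ages)
  expect_true(is.na(all_flag$founder_level))

  # founder-age dominance: corrected age >= own age for every member
  # with a reliable (assigned) age of its own
  corr <- dplyr::left_join(corrected_ages(fams, ages),
                           dplyr::select(ages, "gene", "status"),
                           by = "gene")
  ok <- !is.na(corr$corrected_level) & corr$status == "assigned"
  expect_true(all(corr$corrected_level[ok] >= corr$age_level[ok]))
})

test_that("founder-event counts tally one event per family per level", {
  toy <- chain_taxonomy(5)
  lin <- focal_lineage(toy$tax, toy$focal)
  fams <- tibble::tibble(
    family = 1:4, founder_level = c(2L, 2L, 4L, NA),
    n_members = 1L, members = as.list(letters[1:4]))
  counts <- founder_event_counts(fams, lin)
  expect_equal(counts$n_founder_events, c(0L, 2L, 0L, 1L, 0L))
  # total families with an age = total founder events
  expect_equal(sum(counts$n_founder_events),
               sum(!is.na(fams$founder_level)))
})
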