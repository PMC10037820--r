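test_that("load_taxonomy reads both dialects and validates structure", {
  # minimal valid three-node chain, TSV dialect
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    taxid = c(1L, 2L, 3L), parent_taxid = c(1L, 1L, 2L),
    rank = c("no rank", "kingdom", "species"),
    name = c("root", "K", "S")), tf)
  db <- load_taxonomy(tf)
  expect_equal(nrow(db), 3)
  expect_equal(sum(db$taxid == db$parent_taxid), 1)

  # taxdump dialect round-trips through the simulator's writer
  dir <- withr::local_tempdir()
  b <- simulate_dataset(sim_config(seed = 5, n_levels = 5,
                                   n_families = 3), dir = dir)
  db2 <- load_taxonomy(file.path(dir, "nodes.dmp"),
                       file.path(dir, "names.dmp"))
  expect_equal(nrow(db2), nrow(b$taxonomy))
  expect_setequal(db2$name, b$taxonomy$name)

  # dangling parent names the offender
  bad <- tibble::tibble(taxid = c(1L, 5L), parent_taxid = c(1L, 99L),
                        rank = "x", name = c("r", "n5"))
  expect_error(validate_taxonomy(bad), "99")

  # two roots rejected
  two <- tibble::tibble(taxid = c(1L, 2L), parent_taxid = c(1L, 2L),
                        rank = "x", name = c("a", "b"))
  expect_error(validate_taxonomy(two), "exactly one root")
})

test_that("every parent chain of a valid taxonomy ends at a single root", {
  # oracle: walk the chain from each of 30 nodes and collect fixed points
  toy <- chain_taxonomy(n_levels = 6, species_per_level = 5)
  db <- validate_taxonomy(toy$tax)
  fixed_points <- unique(vapply(db$taxid, function(t) {
    a <- ancestor_set(db, t)
    a[length(a)]
  }, integer(1)))
  expect_equal(fixed_points, 1L)
})

test_that("focal_lineage orders levels youngest to oldest", {
  toy <- chain_taxonomy(4)
  lin <- focal_lineage(toy$tax, toy$focal)
  expect_equal(lin$level, 1:4)
  expect_equal(lin$taxid[1], toy$focal)
  expect_equal(lin$taxid[4], 1L)

  # degenerate: focal = root
  lin_root <- focal_lineage(toy$tax, 1L)
  expect_equal(nrow(lin_root), 1)

  expect_error(focal_lineage(toy$tax, 424242L), "not found")
})

test_that("lineage levels are strictly nested on a 10-level chain", {
  toy <- chain_taxonomy(10, species_per_level = 2)
  lin <- focal_lineage(toy$tax, toy$focal)
  expect_equal(lin$level, 1:10)
  # species contained in each level's clade, from the ring truth table
  members <- lapply(lin$level, function(j) {
    c(toy$focal, toy$ring$taxid[toy$ring$level <= j])
  })
  for (j in 2:10) {
    expect_true(all(members[[j - 1]] %in% members[[j]]))
    expect_gt(length(members[[j]]), length(members[[j - 1]]))
  }
})

test_that("divergence_level matches the ancestor-intersection LCA oracle", {
  toy <- chain_taxonomy(7, species_per_level = 3)
  lin <- focal_lineage(toy$tax, toy$focal)
  expect_equal(divergence_level(lin, toy$tax, toy$focal), 1L)
  # species hanging off the root only
  root_sp <- toy$ring$taxid[toy$ring$level == 7][1]
  expect_equal(divergence_level(lin, toy$tax, root_sp), 7L)
  # planted level-4 ring member
  lvl4 <- toy$ring$taxid[toy$ring$level == 4][2]
  expect_equal(divergence_level(lin, toy$tax, lvl4), 4L)
  # full sweep against the oracle
  got <- divergence_level(lin, toy$tax, toy$ring$taxid)
  want <- vapply(toy$ring$taxid, lca_level_oracle, integer(1),
                 tax = toy$tax, lineage = lin)
  expect_equal(got, want)
})

test_that("divergence_level is order-preserving along ancestry", {
  toy <- chain_taxonomy(8, species_per_level = 2)
  lin <- focal_lineage(toy$tax, toy$focal)
  lv <- divergence_level(lin, toy$tax, toy$ring$taxid)
  # a deeper-ring species never maps younger than a shallower-ring one
  expect_true(all(diff(lv[order(toy$ring$level)]) >= 0))
})

test_that("collapse_levels retains only represented levels", {
  toy <- chain_taxonomy(5, species_per_level = 1)
  lin <- focal_lineage(toy$tax, toy$focal)
  ring <- toy$ring

  # nothing below threshold: unchanged
  fr_all <- tibble::tibble(taxid = ring$taxid, fraction = 0.5)
  kept <- collapse_levels(lin, toy$tax, fr_all)
  expect_equal(kept$level, 1:5)
  expect_equal(kept$taxid, lin$taxid)

  # level 3's only species under-represented: level 3 removed, level 4
  # renumbered to 3
  fr <- dplyr::mutate(fr_all,
                      fraction = ifelse(ring$level == 3, 0.05, 0.5))
  coll <- collapse_levels(lin, toy$tax, fr)
  expect_false(lin$taxid[3] %in% coll$taxid)
  expect_equal(coll$level, 1:4)
  expect_equal(coll$old_level, c(1L, 2L, 4L, 5L))
  map <- attr(coll, "level_map")
  expect_equal(map$new_level[map$old_level == 3], 3L)
  expect_false(map$retained[map$old_level == 3])

  # boundary: exactly the retention fraction is NOT enough (strict >)
  fr_b <- dplyr::mutate(fr_all,
                        fraction = ifelse(ring$level == 2, 0.10, 0.5))
  coll_b <- collapse_levels(lin, toy$tax, fr_b)
  expect_false(lin$taxid[2] %in% coll_b$taxid)

  # species and root levels survive even with zero support
  fr0 <- tibble::tibble(taxid = ring$taxid, fraction = 0)
  coll0 <- collapse_levels(lin, toy$tax, fr0)
  expect_equal(coll0$taxid, c(toy$focal, 1L))
})

test_that("collapse_levels honours name exclusion and is idempotent", {
  toy <- chain_taxonomy(6, species_per_level = 2)
  lin <- focal_lineage(toy$tax, toy$focal)
  fr <- tibble::tibble(taxid = toy$ring$taxid, fraction = 0.5)

  excl <- collapse_levels(lin, toy$tax, fr, exclude_names = "level4")
  expect_false("level4" %in% excl$name)
  expect_equal(excl$level, 1:5)

  expect_warning(
    collapse_levels(lin, toy$tax, fr,
                    exclude_names = "cellular organisms"),
    "cannot be excluded")

  # idempotence: collapsing the collapsed lineage changes nothing
  fr2 <- dplyr::mutate(fr, fraction = ifelse(toy$ring$level %in% c(3, 5),
                                             0.01, 0.5))
  once <- collapse_levels(lin, toy$tax, fr2)
  twice <- collapse_levels(once, toy$tax, fr2)
  expect_equal(twice$level, once$level)
  expect_equal(twice$taxid, once$taxid)
})
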