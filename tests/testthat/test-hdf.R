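make_fit <- function(a, r, c) {
  structure(list(a = a, r = r, c = c, n_points = 8L, status = "ok",
                 points = NULL), class = "decay_fit")
}

test_that("decay points are best-hit bitscores per sampled species", {
  dist <- tibble::tibble(taxid = c(11L, 12L, 13L, 14L, 15L),
                         distance = c(0.4, 0.8, 1.2, 1.6, 2.0))
  hits <- tibble::tibble(
    query = "g", subject = sprintf("s%d", 1:4),
    evalue = 1e-20, bitscore = c(60, 85, 40, 30),
    taxid = c(11L, 11L, 12L, 13L), source = "protein")
  pts <- collect_decay_points(hits, dist)
  # species with several hits: the maximum bitscore
  expect_equal(pts$bitscore[pts$taxid == 11L], 85)
  # 5 table species, 3 with hits -> 3 points; the others are candidates
  expect_equal(nrow(pts), 3)
  expect_setequal(setdiff(dist$taxid, pts$taxid), c(14L, 15L))
})

test_that("decay fitting recovers exact parameters and handles edge cases", {
  # noiseless exponential: exact recovery
  d <- c(0.1, 0.5, 1.0)
  fit <- fit_bitscore_decay(
    tibble::tibble(distance = d, bitscore = 100 * exp(-2 * d)))
  expect_equal(fit$a, 100, tolerance = 1e-6)
  expect_equal(fit$r, 2, tolerance = 1e-6)
  expect_equal(fit$c, 0, tolerance = 1e-6)
  expect_equal(fit$status, "ok")
  # predicted curve is positive and non-increasing
  mu <- fit$a * exp(-fit$r * seq(0, 5, by = 0.1))
  expect_true(all(mu > 0))
  expect_true(all(diff(mu) <= 0))

  # two points: insufficient data
  two <- fit_bitscore_decay(
    tibble::tibble(distance = c(0.1, 0.5), bitscore = c(90, 40)))
  expect_equal(two$status, "insufficient_data")

  # all distances equal: degenerate
  deg <- fit_bitscore_decay(
    tibble::tibble(distance = rep(0.5, 4), bitscore = c(90, 80, 85, 88)))
  expect_equal(deg$status, "degenerate")

  # flat scores: r = 0 boundary
  flat <- fit_bitscore_decay(
    tibble::tibble(distance = c(0.1, 0.5, 1.5), bitscore = rep(70, 3)))
  expect_equal(flat$r, 0, tolerance = 1e-8)
  expect_equal(flat$a, 70, tolerance = 1e-6)

  # broom-style accessors
  expect_equal(tidy(fit)$estimate[1], fit$a)
  expect_equal(glance(fit)$status, "ok")
})

test_that("bitscore threshold follows the Karlin-Altschul identity", {
  expect_equal(bitscore_threshold(400, 1e10, 1e-5), log2(4e17),
               tolerance = 1e-12)
  expect_equal(bitscore_threshold(400, 1e10, 1e-5), 58.47,
               tolerance = 1e-3)
  # exact power of two
  expect_equal(bitscore_threshold(2^20, 2^25, 2^5), 40)
  # user override wins regardless of m, n
  expect_equal(bitscore_threshold(400, 1e10, 1e-5, override = 25), 25)
  expect_error(bitscore_threshold(-1, 1e10, 1e-5), "positive")
})

test_that("hdf probability follows the Gaussian decay model", {
  # mu(d*) = S_thr: exactly one half
  fit <- make_fit(a = 100, r = 1, c = 0.1)
  d_star <- log(100 / 50) / 1 # mu = 50
  expect_equal(hdf_probability(fit, d_star, 50), 0.5)
  # far above threshold: vanishing probability
  expect_lt(hdf_probability(make_fit(500, 0, 0.05), 1, 50), 1e-6)
  # deterministic limits at c = 0
  expect_equal(hdf_probability(make_fit(100, 2, 0), 3, 50), 1)
  expect_equal(hdf_probability(make_fit(100, 0, 0), 3, 50), 0)
  # p is non-decreasing in distance
  p <- hdf_probability(fit, seq(0, 5, by = 0.05), 50)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
})

test_that("hdf probability agrees with a Monte-Carlo oracle", {
  # oracle: sample scores at the fitted parameters, count detection
  # failures below threshold
  set.seed(99)
  fit <- make_fit(a = 120, r = 1.5, c = 0.08)
  s_thr <- 58.47
  for (d in c(0.2, 0.5, 0.8)) {
    mu <- fit$a * exp(-fit$r * d)
    draws <- mu * (1 + fit$c * stats::rnorm(1e5))
    expect_lt(abs(hdf_probability(fit, d, s_thr) - mean(draws < s_thr)),
              0.01)
  }
})

test_that("founder classification uses the nearest next-level outgroup", {
  dist_lv <- tibble::tibble(taxid = c(11L, 12L, 13L, 14L),
                            distance = c(0.3, 0.9, 1.1, 2.0),
                            level = c(3L, 4L, 4L, 5L))
  # k=3: outgroup is taxid 12 (closest with level > 3)
  fit_strong <- make_fit(a = 1000, r = 0.1, c = 0.05)
  cls <- classify_founder(3, fit_strong, dist_lv, s_thr = 58.47)
  expect_equal(cls$outgroup_taxid, 12L)
  expect_equal(cls$verdict, "high_confidence")
  # weak gene: ambiguous
  fit_weak <- make_fit(a = 60, r = 2, c = 0.2)
  expect_equal(classify_founder(3, fit_weak, dist_lv, 58.47)$verdict,
               "hdf_ambiguous")
  # k at the deepest sampled level: untestable
  expect_equal(classify_founder(5, fit_strong, dist_lv, 58.47)$verdict,
               "untestable")
  # unusable fit: untestable
  bad <- structure(list(a = NA, r = NA, c = NA, n_points = 2L,
                        status = "insufficient_data"),
                   class = "decay_fit")
  expect_equal(classify_founder(3, bad, dist_lv, 58.47)$verdict,
               "untestable")
})

test_that("family confidence requires a high-confidence oldest member", {
  fams <- tibble::tibble(
    family = 1:3, founder_level = c(5L, 5L, 4L), n_members = c(2L, 2L, 1L),
    members = list(c("a", "b"), c("c", "d"), "e"))
  ages <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                         age_level = c(5L, 3L, 3L, 5L, 4L))
  assess <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    verdict = c("high_confidence", "hdf_ambiguous", "high_confidence",
                "hdf_ambiguous", "untestable"))
  out <- family_confidence(fams, assess, ages)
  # member with p < alpha AND the family's oldest age: high confidence
  expect_true(out$high_confidence[1])
  # only a younger member passes: not high confidence
  expect_false(out$high_confidence[2])
  expect_equal(out$hdf_status[2], "hdf_ambiguous")
  # untestable singleton reported as such
  expect_equal(out$hdf_status[3], "untestable")
})
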