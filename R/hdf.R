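#' Detectability threshold in bits
#'
#' The bitscore below which an alignment would no longer survive the
#' pipeline's e-value filter, from the Karlin–Altschul identity
#' `E = m * n * 2^(-S)`: `S_thr = log2(m * n / E_thr)`. A fixed
#' user-supplied threshold overrides the transform.
#'
#' @param query_length Query length `m` in residues.
#' @param database_size Database size `n` in residues.
#' @param evalue_max E-value threshold (default 1e-5).
#' @param override Fixed threshold in bits; returned as-is when non-`NULL`.
#' @return Threshold in bits.
#' @examples
#' bitscore_threshold(400, 1e10, 1e-5) # ~58.47 bits
#' @export
bitscore_threshold <- function(query_length, database_size,
                               evalue_max = 1e-5, override = NULL) {
  if (!is.null(override)) return(override)
  if (query_length <= 0 || database_size <= 0 || evalue_max <= 0) {
    stop("query_length, database_size and evalue_max must be positive",
         call. = FALSE)
  }
  log2(query_length * database_size / evalue_max)
}

#' Best-hit bitscore per distance-table species
#'
#' For each (gene, species) pair where the species appears in the
#' evolutionary-distance table and has at least one hit, records the point
#' `(d, max bitscore)` — the closest homolog in that species. Species in
#' the table with no hit for a gene are that gene's candidates for the HDF
#' evaluation.
#'
#' @param hits Filtered hit tibble.
#' @param distances Tibble with columns `taxid` and `distance`
#'   (substitutions/site to the focal species, from a published tree).
#' @return Tibble `gene`, `taxid`, `distance`, `bitscore` (one row per
#'   gene-species pair with evidence).
#' @export
collect_decay_points <- function(hits, distances) {
  stopifnot(all(distances$distance >= 0))
  tibble::as_tibble(hits) |>
    dplyr::inner_join(dplyr::select(tibble::as_tibble(distances),
                                    "taxid", "distance"),
                      by = "taxid") |>
    dplyr::group_by(gene = .data$query, .data$taxid) |>
    dplyr::summarise(distance = .data$distance[1],
                     bitscore = max(.data$bitscore), .groups = "drop") |>
    dplyr::arrange(.data$gene, .data$distance)
}

#' Fit an exponential bitscore-decay model for one gene
#'
#' Bitscores of true homologs decay approximately exponentially with
#' evolutionary distance; the fitted curve `mu(d) = a * exp(-r * d)`
#' predicts the expected bitscore of an undetected homolog in a distant
#' species. Parameters `(a, r)` minimise the sum of squared residuals
#' subject to `a > 0`, `r >= 0` (profiled amplitude + 1-D search over `r`,
#' polished by constrained `nls`). The relative noise scale `c` is the
#' root-mean-square of the relative residuals `(S_i - mu(d_i)) / mu(d_i)`.
#' Fewer than 3 points gives status `"insufficient_data"`; all distances
#' equal gives `"degenerate"` — either way the gene is untestable
#' downstream.
#'
#' @param points Data frame with columns `distance` and `bitscore`, one row
#'   per species with evidence.
#' @return Object of class `"decay_fit"`: list with `a`, `r`, `c`,
#'   `n_points`, `status` (`"ok"`, `"insufficient_data"`, `"degenerate"`)
#'   and the input `points`. Supports [tidy()], [glance()] and
#'   `ggplot2::autoplot()`.
#' @export
fit_bitscore_decay <- function(points) {
  points <- tibble::as_tibble(points)
  d <- points$distance
  s <- points$bitscore
  n <- length(d)
  fit <- list(a = NA_real_, r = NA_real_, c = NA_real_, n_points = n,
              status = "ok", points = points)
  if (n < 3) {
    fit$status <- "insufficient_data"
    return(structure(fit, class = "decay_fit"))
  }
  if (diff(range(d)) == 0) {
    fit$status <- "degenerate"
    return(structure(fit, class = "decay_fit"))
  }
  stopifnot(all(s > 0), all(d >= 0))
  # profiled amplitude: for fixed r the LS-optimal a is closed-form
  a_of_r <- function(r) {
    e <- exp(-r * d)
    max(sum(s * e) / sum(e * e), .Machine$double.eps)
  }
  rss <- function(r) {
    mu <- a_of_r(r) * exp(-r * d)
    sum((s - mu)^2)
  }
  # deterministic initialisation from the score range
  i_max <- which.max(s); i_min <- which.min(s)
  r0 <- if (d[i_min] != d[i_max]) {
    max(0, log(s[i_max] / s[i_min]) / (d[i_min] - d[i_max]))
  } else 0
  r_hi <- max(1, 10 * r0, 100 / max(d))
  opt <- stats::optimize(rss, c(0, r_hi), tol = 1e-10)
  r_hat <- opt$minimum
  if (rss(0) <= opt$objective) r_hat <- 0 # boundary beats interior
  a_hat <- a_of_r(r_hat)
  polished <- tryCatch({
    nl <- stats::nls(bitscore ~ a * exp(-r * distance), data = points,
                     start = list(a = a_hat, r = r_hat),
                     lower = c(a = .Machine$double.eps, r = 0),
                     algorithm = "port",
                     control = stats::nls.control(warnOnly = TRUE))
    cf <- stats::coef(nl)
    list(a = unname(cf["a"]), r = unname(cf["r"]))
  }, error = function(e) NULL)
  if (!is.null(polished)) {
    mu_p <- polished$a * exp(-polished$r * d)
    if (sum((s - mu_p)^2) <= rss(r_hat) + 1e-12) {
      a_hat <- polished$a
      r_hat <- polished$r
    }
  }
  mu <- a_hat * exp(-r_hat * d)
  fit$a <- a_hat
  fit$r <- r_hat
  fit$c <- sqrt(mean(((s - mu) / mu)^2))
  structure(fit, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("bitscore decay fit (", x$status, "): a = ",
      format(x$a, digits = 4), " bits, r = ", format(x$r, digits = 4),
      " per subst/site, c = ", format(x$c, digits = 3),
      ", n = ", x$n_points, "\n", sep = "")
  invisible(x)
}

#' Probability of homology detection failure
#'
#' Probability that the best hit in a species at distance `d` falls below
#' the detectability threshold purely through bitscore decay: the observed
#' score is modelled as Gaussian with mean `mu(d) = a * exp(-r * d)` and
#' standard deviation `c * mu(d)`, so
#' `p = Phi((S_thr - mu(d)) / (c * mu(d)))`. With `c = 0` the model is
#' deterministic: `p` is 1 when `mu(d) < S_thr` and 0 otherwise.
#'
#' @param fit `"decay_fit"` with status `"ok"`.
#' @param d Evolutionary distance(s), substitutions/site (>= 0).
#' @param s_thr Detectability threshold in bits
#'   (see [bitscore_threshold()]).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
hdf_probability <- function(fit, d, s_thr) {
  stopifnot(inherits(fit, "decay_fit"), all(d >= 0), s_thr > 0)
  if (fit$status != "ok") {
    stop("hdf_probability requires a fit with status 'ok', got '",
         fit$status, "'", call. = FALSE)
  }
  mu <- fit$a * exp(-fit$r * d)
  if (fit$c == 0) {
    return(as.numeric(mu < s_thr))
  }
  stats::pnorm((s_thr - mu) / (fit$c * mu))
}

#' Classify one gene's age assignment against its nearest outgroup
#'
#' The HDF test for a gene assigned to level `k`: the outgroup is the
#' distance-table species with the smallest evolutionary distance among
#' those diverging deeper than `k` (the "closest species of the next
#' taxonomic level"). The gene's founder assignment is `high_confidence`
#' when the probability of missing it there by bitscore decay alone is
#' below `alpha` (strict), `hdf_ambiguous` otherwise, and `untestable` when
#' no such outgroup is sampled (the assigned level is at or beyond the
#' distance table's deepest level) or the decay fit is unusable.
#'
#' @param k Assigned age level.
#' @param fit `"decay_fit"` for the gene.
#' @param distances_lv Tibble `taxid`, `distance`, `level` (divergence
#'   levels of the distance-table species).
#' @param s_thr Detectability threshold in bits.
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `outgroup_taxid`, `outgroup_distance`, `mu`,
#'   `p`, `verdict`.
#' @export
classify_founder <- function(k, fit, distances_lv, s_thr, alpha = 0.05) {
  empty <- tibble::tibble(outgroup_taxid = NA_integer_,
                          outgroup_distance = NA_real_,
                          mu = NA_real_, p = NA_real_,
                          verdict = "untestable")
  out_sp <- distances_lv |>
    dplyr::filter(!is.na(.data$level), .data$level > k) |>
    dplyr::arrange(.data$distance, .data$taxid)
  if (nrow(out_sp) == 0 || fit$status != "ok") {
    return(empty)
  }
  og <- out_sp[1, ]
  mu <- fit$a * exp(-fit$r * og$distance)
  p <- hdf_probability(fit, og$distance, s_thr)
  tibble::tibble(
    outgroup_taxid = as.integer(og$taxid),
    outgroup_distance = og$distance,
    mu = mu,
    p = p,
    verdict = dplyr::if_else(p < alpha, "high_confidence", "hdf_ambiguous")
  )
}

#' HDF assessment for every assigned gene
#'
#' Runs the whole per-gene HDF chain — collect decay points, fit the decay
#' curve, locate the nearest next-level outgroup, compute the failure
#' probability — across a gene-age table. Genes with status other than
#' `"assigned"` are reported `untestable` (no usable age), as are genes
#' with unusable fits or no sampled outgroup beyond their level.
#'
#' @param hits Filtered hit tibble.
#' @param ages Gene-age tibble from [gene_ages()].
#' @param distances Tibble `taxid`, `distance`.
#' @param lineage,db Lineage and taxonomy used to map distance-table
#'   species to divergence levels.
#' @param s_thr Detectability threshold in bits.
#' @param alpha Significance level (default 0.05).
#' @return Tibble, one row per gene in `ages`: `gene`, `age_level`,
#'   `outgroup_taxid`, `outgroup_distance`, `mu`, `s_thr`, `p`, `verdict`,
#'   `fit_status`.
#' @export
hdf_assess <- function(hits, ages, distances, lineage, db, s_thr,
                       alpha = 0.05) {
  distances_lv <- tibble::as_tibble(distances) |>
    dplyr::mutate(level = divergence_level(lineage, db, .data$taxid))
  points <- collect_decay_points(hits, distances)
  pts_by_gene <- split(points, points$gene)
  ages_tbl <- tibble::as_tibble(ages)
  res <- purrr::pmap_dfr(
    list(ages_tbl$gene, ages_tbl$age_level, ages_tbl$status),
    function(g, k, status) {
      base <- tibble::tibble(gene = g, age_level = k)
      if (is.na(status) || status != "assigned") {
        return(dplyr::bind_cols(base, tibble::tibble(
          outgroup_taxid = NA_integer_, outgroup_distance = NA_real_,
          mu = NA_real_, p = NA_real_, verdict = "untestable",
          fit_status = "not_fitted")))
      }
      fit <- fit_bitscore_decay(
        pts_by_gene[[g]] %||%
          tibble::tibble(distance = numeric(0), bitscore = numeric(0)))
      cls <- classify_founder(k, fit, distances_lv, s_thr, alpha)
      dplyr::bind_cols(base, cls, tibble::tibble(fit_status = fit$status))
    }
  )
  res$s_thr <- s_thr
  res |>
    dplyr::select("gene", "age_level", "outgroup_taxid",
                  "outgroup_distance", "mu", "s_thr", "p", "verdict",
                  "fit_status") |>
    dplyr::arrange(.data$gene)
}

#' High-confidence flags for gene families
#'
#' A family's founder event is high confidence when at least one member
#' both passes the HDF test (`verdict == "high_confidence"`) and carries
#' the family's oldest assignable age — the member that actually dates the
#' founder event. Families where no member could be tested are reported
#' `"untestable"`.
#'
#' @param families Tibble from [family_founder_age()].
#' @param assessments Tibble from [hdf_assess()].
#' @param ages Gene-age tibble.
#' @return `families` with added columns `high_confidence` (logical) and
#'   `hdf_status` (`"high_confidence"`, `"hdf_ambiguous"`,
#'   `"untestable"`).
#' @export
family_confidence <- function(families, assessments, ages) {
  member_tbl <- families |>
    dplyr::select("family", "founder_level", "members") |>
    tidyr::unnest_longer("members", values_to = "gene") |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(ages), "gene", "age_level"),
      by = "gene") |>
    dplyr::left_join(
      dplyr::select(assessments, "gene", "verdict"), by = "gene")
  summary <- member_tbl |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      high_confidence = any(
        .data$verdict == "high_confidence" &
          .data$age_level == .data$founder_level, na.rm = TRUE),
      any_testable = any(.data$verdict != "untestable", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(hdf_status = dplyr::case_when(
      high_confidence ~ "high_confidence",
      any_testable ~ "hdf_ambiguous",
      TRUE ~ "untestable"
    )) |>
    dplyr::select("family", "high_confidence", "hdf_status")
  dplyr::left_join(families, summary, by = "family")
}
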