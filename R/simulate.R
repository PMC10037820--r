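#' Configuration for the synthetic founder-event simulator
#'
#' Bundles and validates the generative parameters: a ladder taxonomy of
#' `n_levels` nested levels with `species_per_level` database species
#' diverging at each level, gene families with a shared birth level,
#' per-gene exponential bitscore decay (`a * exp(-r * d)`) with relative
#' Gaussian noise `c`, stochastic gene loss per (gene, level-ring), and
#' optional planted contaminants. A homolog is emitted as a hit only when
#' its realised bitscore reaches the detectability threshold `s_thr`
#' (defaulting to the Karlin–Altschul transform of `evalue_max`), with the
#' e-value back-computed as `m * n * 2^(-S)` so the files are
#' self-consistent with the pipeline's own threshold arithmetic.
#'
#' @param seed Integer seed; the bundle is deterministic given the seed.
#' @param n_levels Number of lineage levels (>= 3).
#' @param species_per_level Database species per divergence ring.
#' @param n_families Number of gene families.
#' @param genes_per_family Length-2 integer range of family sizes.
#' @param birth_weights Per-level birth probabilities (default uniform).
#' @param a_meanlog,a_sdlog Log-normal parameters of the initial bitscore
#'   `a` (bits).
#' @param r_shape,r_scale Gamma parameters of the decay rate `r`
#'   (per substitution/site).
#' @param noise Relative noise scale `c` (>= 0).
#' @param level_distances Evolutionary distance of each level's ring
#'   (strictly increasing; level 1 is 0). Default roughly doubles per
#'   level starting at 0.05 substitutions/site.
#' @param loss_prob Per-(gene, ring) loss probability.
#' @param contamination Fraction of extra contaminant genes appended as
#'   singleton families (hits only at the focal species plus one random
#'   distant ring, level >= 5).
#' @param query_length,database_size Nominal `m` and `n` (residues) for the
#'   e-value back-computation.
#' @param evalue_max Pipeline e-value threshold the bundle is built for.
#' @param s_thr Detection threshold in bits; `NULL` means
#'   `bitscore_threshold(query_length, database_size, evalue_max)`.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_levels = 8L,
                       species_per_level = 3L,
                       n_families = 50L,
                       genes_per_family = c(1L, 4L),
                       birth_weights = NULL,
                       a_meanlog = log(150),
                       a_sdlog = 0.3,
                       r_shape = 2,
                       r_scale = 0.5,
                       noise = 0.05,
                       level_distances = NULL,
                       loss_prob = 0.05,
                       contamination = 0,
                       query_length = 400,
                       database_size = 1e10,
                       evalue_max = 1e-5,
                       s_thr = NULL) {
  if (n_levels < 3) stop("n_levels must be >= 3", call. = FALSE)
  if (species_per_level < 1) {
    stop("at least one species per level ring is required", call. = FALSE)
  }
  if (is.null(birth_weights)) birth_weights <- rep(1, n_levels)
  stopifnot(length(birth_weights) == n_levels, all(birth_weights >= 0),
            sum(birth_weights) > 0)
  if (is.null(level_distances)) {
    level_distances <- c(0, 0.05 * 2^(seq_len(n_levels - 1) - 1))
  }
  stopifnot(length(level_distances) == n_levels,
            all(diff(level_distances) > 0), level_distances[1] == 0)
  stopifnot(noise >= 0, loss_prob >= 0, loss_prob <= 1,
            contamination >= 0, contamination <= 1)
  if (contamination > 0 && n_levels < 5) {
    stop("contamination requires n_levels >= 5 (contaminants hit a ",
         "distant ring at level >= 5)", call. = FALSE)
  }
  if (is.null(s_thr)) {
    s_thr <- bitscore_threshold(query_length, database_size, evalue_max)
  }
  structure(list(
    seed = as.integer(seed), n_levels = as.integer(n_levels),
    species_per_level = as.integer(species_per_level),
    n_families = as.integer(n_families),
    genes_per_family = as.integer(genes_per_family),
    birth_weights = birth_weights, a_meanlog = a_meanlog,
    a_sdlog = a_sdlog, r_shape = r_shape, r_scale = r_scale,
    noise = noise, level_distances = level_distances,
    loss_prob = loss_prob, contamination = contamination,
    query_length = query_length, database_size = database_size,
    evalue_max = evalue_max, s_thr = s_thr
  ), class = "sim_config")
}

# Ladder taxonomy: focal chain of ancestors plus a species ring per level.
# Level-j ring species are children of the level-j ancestor, so they
# diverge from the focal species exactly at level j.
sim_taxonomy <- function(config) {
  n <- config$n_levels
  anc_taxid <- function(j) if (j == n) 1L else 100L + j # level-j ancestor
  focal <- 1000L
  ranks <- c("species", "genus", "family", "order", "class", "phylum",
             "kingdom", "superkingdom")
  rank_of <- function(j) {
    if (j == n) "no rank" else ranks[min(j, length(ranks))]
  }
  rows <- list(tibble::tibble(
    taxid = 1L, parent_taxid = 1L, rank = "no rank",
    name = "cellular organisms"))
  for (j in seq(n - 1, 2)) {
    rows <- c(rows, list(tibble::tibble(
      taxid = anc_taxid(j), parent_taxid = anc_taxid(j + 1L),
      rank = rank_of(j), name = sprintf("clade_L%d", j))))
  }
  rows <- c(rows, list(tibble::tibble(
    taxid = focal, parent_taxid = anc_taxid(2L), rank = "species",
    name = "focal species")))
  for (j in 2:n) {
    for (k in seq_len(config$species_per_level)) {
      rows <- c(rows, list(tibble::tibble(
        taxid = 1000L * j + k, parent_taxid = anc_taxid(j),
        rank = "species", name = sprintf("sp_L%d_%d", j, k))))
    }
  }
  list(taxonomy = dplyr::bind_rows(rows), focal_taxid = focal)
}

#' Simulate a complete pipeline input bundle
#'
#' Generates, deterministically for a given seed, a synthetic taxonomy,
#' protein hit table, all-vs-all self-hit table, distance table and truth
#' table that share the statistical structure the pipeline assumes: a
#' database species carries a homolog of a gene iff it diverges no deeper
#' than the gene's birth level and no loss event applies; the realised
#' bitscore is `a * exp(-r * d) * (1 + c * eps)` with standard-normal
#' `eps`; a hit is emitted iff the realised bitscore reaches `s_thr`, with
#' the e-value back-computed from the Karlin–Altschul identity.
#' Contaminant genes hit only the focal species and one random distant
#' ring, reproducing the low-representativeness signature the flagging
#' rule targets. Within-family self-hits get e-values far below any
#' sensible threshold so clustering sees clean families.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, all tables are
#'   written there (`nodes.dmp`, `names.dmp`, `protein_hits.tsv`,
#'   `self_hits.tsv`, `distances.tsv`, `truth_genes.tsv`,
#'   `truth_families.tsv`) in the exact dialects the pipeline reads.
#' @return List with elements `taxonomy`, `focal_taxid`, `hits`,
#'   `self_hits`, `distances`, `truth_genes`, `truth_families`, `config`
#'   (and `dir` when written).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    taxo <- sim_taxonomy(config)
    n <- config$n_levels
    species <- taxo$taxonomy |>
      dplyr::filter(.data$taxid >= 2000L) |>
      dplyr::mutate(ring = .data$taxid %/% 1000L,
                    within = .data$taxid %% 1000L,
                    distance = config$level_distances[.data$ring] *
                      (1 + 0.01 * (.data$within - 1)))

    sizes <- sample(seq(config$genes_per_family[1],
                        config$genes_per_family[2]),
                    config$n_families, replace = TRUE)
    fam_birth <- sample.int(n, config$n_families, replace = TRUE,
                            prob = config$birth_weights)
    genes <- tibble::tibble(
      family = rep.int(seq_len(config$n_families), sizes),
      birth_level = rep.int(fam_birth, sizes)
    )
    n_cont <- round(config$contamination * nrow(genes))
    if (n_cont > 0) {
      cont <- tibble::tibble(
        family = max(genes$family) + seq_len(n_cont),
        birth_level = sample(5:n, n_cont, replace = TRUE),
        contaminant = TRUE
      )
      genes <- dplyr::bind_rows(
        dplyr::mutate(genes, contaminant = FALSE), cont)
    } else {
      genes$contaminant <- FALSE
    }
    genes <- genes |>
      dplyr::mutate(
        gene = sprintf("g%04d", dplyr::row_number()),
        a = stats::rlnorm(dplyr::n(), config$a_meanlog, config$a_sdlog),
        r = stats::rgamma(dplyr::n(), shape = config$r_shape,
                          scale = config$r_scale)
      )

    mn <- config$query_length * config$database_size
    emit_evalue <- function(s) mn * 2^(-s)

    hit_rows <- purrr::pmap(
      list(genes$gene, genes$birth_level, genes$contaminant,
           genes$a, genes$r),
      function(g, b, cont, a, r) {
        # self-hit against the focal species (distance 0)
        s_self <- a * (1 + config$noise * stats::rnorm(1))
        rows <- list()
        if (s_self >= config$s_thr) {
          rows <- c(rows, list(tibble::tibble(
            qseqid = g, sseqid = paste0("self_", g),
            evalue = emit_evalue(s_self), bitscore = round(s_self, 1),
            staxids = taxo$focal_taxid)))
        }
        if (cont) {
          # contaminant: strong hits to every species of one distant ring
          ring <- b # birth_level stores the planted ring (>= 5)
          sp <- species[species$ring == ring, ]
          s_hit <- a * (1 + config$noise * stats::rnorm(nrow(sp)))
          keep <- s_hit >= config$s_thr
          if (any(keep)) {
            rows <- c(rows, list(tibble::tibble(
              qseqid = g, sseqid = paste0("p_", sp$taxid[keep], "_", g),
              evalue = emit_evalue(s_hit[keep]),
              bitscore = round(s_hit[keep], 1),
              staxids = sp$taxid[keep])))
          }
          return(dplyr::bind_rows(rows))
        }
        sp <- species[species$ring <= b, ]
        if (nrow(sp) > 0) {
          lost <- stats::runif(nrow(sp)) < config$loss_prob
          mu <- a * exp(-r * sp$distance)
          s_hit <- mu * (1 + config$noise * stats::rnorm(nrow(sp)))
          keep <- !lost & s_hit >= config$s_thr
          if (any(keep)) {
            rows <- c(rows, list(tibble::tibble(
              qseqid = g, sseqid = paste0("p_", sp$taxid[keep], "_", g),
              evalue = emit_evalue(s_hit[keep]),
              bitscore = round(s_hit[keep], 1),
              staxids = sp$taxid[keep])))
          }
        }
        dplyr::bind_rows(rows)
      })
    hits <- dplyr::bind_rows(hit_rows)

    # all-vs-all: every within-family pair far below any e-value threshold
    self_hits <- genes |>
      dplyr::group_by(.data$family) |>
      dplyr::reframe({
        g <- sort(gene)
        pairs <- expand.grid(qseqid = g, sseqid = g,
                             stringsAsFactors = FALSE)
        tibble::as_tibble(pairs)
      }) |>
      dplyr::mutate(
        evalue = dplyr::if_else(.data$qseqid == .data$sseqid,
                                0, emit_evalue(300)),
        bitscore = dplyr::if_else(.data$qseqid == .data$sseqid, 500, 300),
        staxids = taxo$focal_taxid
      ) |>
      dplyr::select(-"family")

    distances <- species |>
      dplyr::transmute(taxid = .data$taxid, distance = .data$distance)

    truth_genes <- genes |>
      dplyr::select("gene", "family", "birth_level", "a", "r",
                    "contaminant")
    truth_families <- genes |>
      dplyr::filter(!.data$contaminant) |>
      dplyr::group_by(.data$family) |>
      dplyr::summarise(founder_level = max(.data$birth_level),
                       n_members = dplyr::n(), .groups = "drop")

    bundle <- list(
      taxonomy = taxo$taxonomy, focal_taxid = taxo$focal_taxid,
      hits = hits, self_hits = self_hits, distances = distances,
      truth_genes = truth_genes, truth_families = truth_families,
      config = config
    )
    if (!is.null(dir)) {
      write_sim_bundle(bundle, dir)
      bundle$dir <- dir
    }
    bundle
  })
}

# Serialise the bundle in the pipeline's input dialects.
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- bundle$taxonomy
  readr::write_lines(
    sprintf("%d\t|\t%d\t|\t%s\t|", tx$taxid, tx$parent_taxid, tx$rank),
    file.path(dir, "nodes.dmp"))
  readr::write_lines(
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", tx$taxid, tx$name),
    file.path(dir, "names.dmp"))
  fmt_hits <- function(h) {
    tibble::tibble(
      qseqid = h$qseqid, sseqid = h$sseqid,
      evalue = formatC(h$evalue, format = "e", digits = 6),
      bitscore = formatC(h$bitscore, format = "fg"),
      staxids = h$staxids)
  }
  readr::write_tsv(fmt_hits(bundle$hits),
                   file.path(dir, "protein_hits.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(fmt_hits(bundle$self_hits),
                   file.path(dir, "self_hits.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(bundle$distances, file.path(dir, "distances.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$truth_genes,
                   file.path(dir, "truth_genes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth_families,
                   file.path(dir, "truth_families.tsv"), progress = FALSE)
  invisible(dir)
}

#' Simulate noisy bitscore-decay points for one gene
#'
#' Draws `S_i = a * exp(-r * d_i) * (1 + c * eps_i)` with standard-normal
#' `eps_i`, the generative model behind [fit_bitscore_decay()]; used for
#' parameter-recovery studies.
#'
#' @param a,r True decay parameters.
#' @param c Relative noise scale.
#' @param d Numeric vector of distances.
#' @return Tibble `distance`, `bitscore`.
#' @export
simulate_decay_points <- function(a, r, c, d) {
  tibble::tibble(
    distance = d,
    bitscore = pmax(a * exp(-r * d) * (1 + c * stats::rnorm(length(d))),
                    .Machine$double.eps)
  )
}
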