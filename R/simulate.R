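#' Configuration for the MERFISH-like tissue simulator
#'
#' Defines a seeded synthetic experiment with the statistical structure the
#' downstream analysis assumes: cells scattered over a rectangular tissue
#' region, amyloid plaques outlined by four perimeter points, a
#' three-state microglial mixture (homeostatic, DAM, lymphoid-DAM) whose
#' composition is enriched for disease states near plaque edges,
#' negative-binomial panel counts with state-program effects, lognormal
#' cell volumes, and a trimodal lognormal nuclear-intensity mixture.
#'
#' @param seed Integer master seed. Stage-level seeds are derived from it so
#'   each generation stage is independently reproducible.
#' @param n_cells Number of regular (QC-passing by design) cells.
#' @param n_genes Panel size (default 100, up to 398). The panel always
#'   contains the bundled lymphoid, interferon, DAM and homeostatic marker
#'   genes (35 ids), padded with filler genes; `n_genes` must be >= 35.
#' @param n_plaques Number of plaques.
#' @param region Named numeric vector `c(xmin, xmax, ymin, ymax)` in
#'   micrometres.
#' @param plaque_radius_range Range (min, max) of vertex distances from the
#'   plaque centre, micrometres.
#' @param frac_states Marginal proportions of the three states, in order
#'   homeostatic, DAM, lymphoid-DAM; must sum to 1.
#' @param proximity_enrichment Multiplier (>= 1) applied to the odds of the
#'   DAM and lymphoid-DAM states for cells within `proximity_cutoff_um` of
#'   a plaque edge.
#' @param proximity_cutoff_um Generative proximity cutoff, micrometres.
#' @param nb_mean_baseline Geometric-mean expected counts per gene per
#'   cell at baseline.
#' @param baseline_sdlog Gene-to-gene lognormal spread of baseline means
#'   (default 0.5): panel genes span a range of expression levels, as in
#'   real panels, which is what makes expression-matched control binning
#'   meaningful. Per-gene baselines are recorded in the ground truth.
#' @param nb_dispersion Negative-binomial size (gamma shape) shared by all
#'   genes; larger values approach Poisson.
#' @param effect_log2fc Named log2 elevations of program genes, names among
#'   `homeostatic`, `dam`, `lymphoid`. Homeostatic cells express the
#'   homeostatic program; DAM cells the DAM program; lymphoid-DAM cells
#'   both the DAM and the lymphoid programs.
#' @param volume_lognormal Named vector `c(meanlog, sdlog)` for cell volume
#'   in cubic micrometres.
#' @param intensity_mixture Data frame with columns `component`
#'   (`low`/`medium`/`high`), `mean` (arithmetic mean intensity, arbitrary
#'   units), `sdlog`, `weight`. Defaults place the outer component means a
#'   factor 1.25^2 from the centre so the reference-fold-change cutoffs
#'   (factor 1.25 about the population mean) fall at the geometric midpoint
#'   between adjacent components; weights 0.2/0.6/0.2.
#' @param intensity_link `"state"` ties each nucleus to the component of its
#'   state (lymphoid-DAM -> low, homeostatic -> medium, DAM -> high),
#'   mirroring the reduced PU.1 signal of the lymphoid subset; `"mixture"`
#'   draws components from the mixture weights regardless of state.
#' @param sample_ids Sample identifiers; cells are split evenly.
#' @param sample_depth Per-sample multiplicative depth factors (global
#'   count differences that sample normalization must remove).
#' @param program_genes Optional named list overriding the program gene
#'   sets (names among `homeostatic`, `dam`, `lymphoid`); sets must be
#'   disjoint and drawn from the panel. `NULL` uses the bundled marker
#'   signatures.
#' @param dropout_cells Named counts of deliberately QC-failing cells to
#'   inject, names among `low_transcripts` (< 40 total molecules),
#'   `low_volume` (< 100 cubic micrometres) and `low_genes` (exactly 10
#'   detected genes). Their ids are recorded in the ground truth.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_cells = 8000L,
                              n_genes = 100L,
                              n_plaques = 40L,
                              region = c(xmin = 0, xmax = 1000,
                                         ymin = 0, ymax = 1000),
                              plaque_radius_range = c(10, 20),
                              frac_states = c(homeostatic = 0.7,
                                              DAM = 0.2,
                                              lymphoid_DAM = 0.1),
                              proximity_enrichment = 5,
                              proximity_cutoff_um = 15,
                              nb_mean_baseline = 2.5,
                              baseline_sdlog = 0.5,
                              nb_dispersion = 5,
                              effect_log2fc = c(homeostatic = 1,
                                                dam = 3,
                                                lymphoid = 3),
                              volume_lognormal = c(meanlog = log(300),
                                                   sdlog = 0.4),
                              intensity_mixture = default_intensity_mixture(),
                              intensity_link = c("state", "mixture"),
                              sample_ids = c("s1", "s2"),
                              sample_depth = c(1, 1.3),
                              program_genes = NULL,
                              dropout_cells = c(low_transcripts = 20L,
                                                low_volume = 20L,
                                                low_genes = 20L)) {
  intensity_link <- match.arg(intensity_link)
  cfg <- list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes), n_plaques = as.integer(n_plaques),
    region = region, plaque_radius_range = plaque_radius_range,
    frac_states = frac_states,
    proximity_enrichment = proximity_enrichment,
    proximity_cutoff_um = proximity_cutoff_um,
    nb_mean_baseline = nb_mean_baseline,
    baseline_sdlog = baseline_sdlog,
    nb_dispersion = nb_dispersion,
    effect_log2fc = effect_log2fc,
    volume_lognormal = volume_lognormal,
    intensity_mixture = as.data.frame(intensity_mixture),
    intensity_link = intensity_link,
    sample_ids = sample_ids, sample_depth = sample_depth,
    program_genes = program_genes,
    dropout_cells = dropout_cells
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_intensity_mixture <- function(fold_change = 1.25, centre = 100,
                                      sdlog = 0.08,
                                      weights = c(0.2, 0.6, 0.2)) {
  data.frame(
    component = c("low", "medium", "high"),
    mean = centre * c(1 / fold_change^2, 1, fold_change^2),
    sdlog = sdlog,
    weight = weights
  )
}

validate_simulation_config <- function(cfg) {
  r <- cfg$region
  if (length(r) != 4 || r["xmax"] <= r["xmin"] || r["ymax"] <= r["ymin"]) {
    abort("Invalid region extents: need xmin < xmax and ymin < ymax.")
  }
  if (abs(sum(cfg$frac_states) - 1) > 1e-8 || any(cfg$frac_states < 0)) {
    abort("`frac_states` must be non-negative and sum to 1.")
  }
  if (cfg$nb_dispersion <= 0) abort("`nb_dispersion` must be positive.")
  if (cfg$baseline_sdlog < 0) abort("`baseline_sdlog` must be >= 0.")
  if (cfg$proximity_enrichment < 1) {
    abort("`proximity_enrichment` must be >= 1.")
  }
  if (cfg$n_genes < length(unlist(panel_program_genes()))) {
    abort("`n_genes` must cover the bundled program gene sets (>= 35).")
  }
  mix <- cfg$intensity_mixture
  if (nrow(mix) != 3 || any(mix$sdlog <= 0) || any(mix$mean <= 0)) {
    abort("`intensity_mixture` needs three components with positive mean and sdlog.")
  }
  if (abs(sum(mix$weight) - 1) > 1e-8) {
    abort("`intensity_mixture` weights must sum to 1.")
  }
  if (length(cfg$sample_depth) != length(cfg$sample_ids)) {
    abort("`sample_depth` must match `sample_ids` in length.")
  }
  bad <- setdiff(names(cfg$dropout_cells),
                 c("low_transcripts", "low_volume", "low_genes"))
  if (length(bad)) abort(paste0("Unknown dropout class: ", bad[1]))
  pg <- cfg$program_genes
  if (!is.null(pg)) {
    if (is.null(names(pg)) ||
        !all(names(pg) %in% c("homeostatic", "dam", "lymphoid"))) {
      abort("`program_genes` names must be among homeostatic, dam, lymphoid.")
    }
    all_genes <- unlist(pg, use.names = FALSE)
    if (anyDuplicated(all_genes)) {
      abort("`program_genes` sets must be disjoint.")
    }
    missing <- setdiff(all_genes, panel_genes(cfg$n_genes))
    if (length(missing)) {
      abort(paste0("`program_genes` ids absent from the panel: ",
                   paste(missing, collapse = ", ")))
    }
  }
  invisible(cfg)
}

# marker panel: bundled signature genes, in fixed order
panel_program_genes <- function() {
  sets <- microglia_gene_sets()
  list(homeostatic = sets$homeostatic, dam = sets$dam,
       lymphoid = sets$lymphoid, interferon = sets$interferon)
}

panel_genes <- function(n_genes) {
  named <- unlist(panel_program_genes(), use.names = FALSE)
  if (n_genes < length(named)) abort("Panel too small for bundled gene sets.")
  c(named, sprintf("Gene%03d", seq_len(n_genes - length(named))))
}

active_program_genes <- function(config) {
  config$program_genes %||%
    panel_program_genes()[c("homeostatic", "dam", "lymphoid")]
}

# programs elevated by each cell state
state_programs <- function() {
  list(homeostatic = "homeostatic", DAM = "dam",
       lymphoid_DAM = c("dam", "lymphoid"))
}

# derive independent stage seeds from the master seed
stage_seeds <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max, 6),
           c("plaques", "cells", "states", "counts", "intensities", "scoring"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate plaque outlines
#'
#' Each plaque is four perimeter points at jittered right angles around a
#' uniformly placed centre, ordered counter-clockwise, which guarantees a
#' simple quadrilateral fully inside the region.
#'
#' @param config A [simulation_config()].
#' @param seed Stage seed (defaults to a seed derived from the config).
#' @return Tibble `plaque_id`, `x1`, `y1`, ..., `x4`, `y4`.
#' @export
generate_plaques <- function(config, seed = stage_seeds(config$seed)["plaques"]) {
  r <- config$region
  rr <- config$plaque_radius_range
  n <- config$n_plaques
  if (n == 0) {
    return(tibble::tibble(plaque_id = integer(),
                          x1 = numeric(), y1 = numeric(),
                          x2 = numeric(), y2 = numeric(),
                          x3 = numeric(), y3 = numeric(),
                          x4 = numeric(), y4 = numeric()))
  }
  with_seed(seed, {
    cx <- runif(n, r["xmin"] + rr[2], r["xmax"] - rr[2])
    cy <- runif(n, r["ymin"] + rr[2], r["ymax"] - rr[2])
    rows <- lapply(seq_len(n), function(i) {
      ang <- (c(0, 90, 180, 270) + runif(4, -30, 30)) * pi / 180
      rad <- runif(4, rr[1], rr[2])
      quad <- canonical_quadrilateral(
        cbind(cx[i] + rad * cos(ang), cy[i] + rad * sin(ang))
      )
      setNames(as.numeric(t(quad)),
               paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)))
    })
    out <- tibble::as_tibble(do.call(rbind, rows))
    dplyr::bind_cols(tibble::tibble(plaque_id = seq_len(n)), out)
  })
}

generate_cell_positions <- function(config, seed) {
  r <- config$region
  n_drop <- sum(config$dropout_cells)
  n_total <- config$n_cells + n_drop
  with_seed(seed, {
    cells <- tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_total)),
      x_um = runif(n_total, r["xmin"], r["xmax"]),
      y_um = runif(n_total, r["ymin"], r["ymax"]),
      volume_um3 = rlnorm(n_total, config$volume_lognormal["meanlog"],
                          config$volume_lognormal["sdlog"]),
      sample_id = rep_len(config$sample_ids, n_total)
    )
    qc_fail <- rep(NA_character_, n_total)
    if (n_drop > 0) {
      idx <- config$n_cells + seq_len(n_drop)
      qc_fail[idx] <- rep(names(config$dropout_cells), config$dropout_cells)
      lv <- idx[qc_fail[idx] == "low_volume"]
      cells$volume_um3[lv] <- runif(length(lv), 20, 99)
    }
    cells$qc_fail <- qc_fail
    cells
  })
}

#' Assign ground-truth cell states with plaque-proximity enrichment
#'
#' Cells within the generative cutoff of a plaque edge draw the DAM and
#' lymphoid-DAM states with odds multiplied by `proximity_enrichment`,
#' emulating the accumulation of disease-associated states around plaques.
#'
#' @param cells Cell table with centroids.
#' @param plaques Plaque table (may be empty: all cells distal).
#' @param config A [simulation_config()].
#' @param seed Stage seed.
#' @return Tibble `cell_id`, `cell_state`, `true_proximity_label`,
#'   `distance_um`, with the marginal state fractions as an attribute.
#' @export
assign_states <- function(cells, plaques, config,
                          seed = stage_seeds(config$seed)["states"]) {
  if (nrow(plaques) > 0) {
    np <- nearest_plaque(cells, plaques)
    dist <- np$distance_um
  } else {
    dist <- rep(Inf, nrow(cells))
  }
  near <- dist <= config$proximity_cutoff_um
  states <- c("homeostatic", "DAM", "lymphoid_DAM")
  base <- unname(config$frac_states)
  enr <- base * c(1, config$proximity_enrichment, config$proximity_enrichment)
  enr <- enr / sum(enr)
  with_seed(seed, {
    state <- character(nrow(cells))
    state[!near] <- sample(states, sum(!near), replace = TRUE, prob = base)
    if (any(near)) {
      state[near] <- sample(states, sum(near), replace = TRUE, prob = enr)
    }
    out <- tibble::tibble(
      cell_id = cells$cell_id,
      cell_state = state,
      true_proximity_label = ifelse(near, "plaque_associated", "distal"),
      distance_um = dist
    )
    attr(out, "state_fractions") <- table(factor(state, states)) / nrow(cells)
    out
  })
}

#' Generate negative-binomial panel counts
#'
#' Gamma-Poisson counts with a shared dispersion: gene means are the
#' baseline times the sample depth factor, times `2^effect` for genes in a
#' program expressed by the cell's state. Deliberately QC-failing cells are
#' overwritten with draws guaranteed to violate exactly one filter.
#'
#' @param cells Cell table (with `sample_id` and `qc_fail`).
#' @param truth State assignment from [assign_states()].
#' @param config A [simulation_config()].
#' @param seed Stage seed.
#' @return An [expr_matrix()] (raw layer), cells x genes.
#' @export
generate_counts <- function(cells, truth, config,
                            seed = stage_seeds(config$seed)["counts"]) {
  genes <- panel_genes(config$n_genes)
  progs <- active_program_genes(config)
  sp <- state_programs()
  n <- nrow(cells)
  g <- length(genes)
  depth <- setNames(config$sample_depth, config$sample_ids)[cells$sample_id]
  gene_baseline <- with_seed(seed, {
    config$nb_mean_baseline *
      exp(rnorm(g, 0, config$baseline_sdlog))
  })
  names(gene_baseline) <- genes
  mu <- matrix(gene_baseline, n, g, byrow = TRUE,
               dimnames = list(cells$cell_id, genes))
  for (st in names(sp)) {
    rows <- truth$cell_state == st
    if (!any(rows)) next
    for (p in sp[[st]]) {
      eff <- config$effect_log2fc[[p]]
      if (is.null(eff) || eff == 0 || is.null(progs[[p]])) next
      mu[rows, progs[[p]]] <- mu[rows, progs[[p]]] * 2^eff
    }
  }
  mu <- mu * as.numeric(depth)
  with_seed(seed + 1L, {
    counts <- matrix(rnbinom(n * g, mu = mu, size = config$nb_dispersion),
                     n, g, dimnames = dimnames(mu))
    fail <- cells$qc_fail
    for (i in which(!is.na(fail) & fail == "low_transcripts")) {
      total <- sample(15:39, 1)
      counts[i, ] <- as.integer(rmultinom(1, total, prob = mu[i, ]))
    }
    for (i in which(!is.na(fail) & fail == "low_genes")) {
      picked <- sample(g, 10)
      row <- integer(g)
      row[picked] <- 1L + as.integer(rmultinom(1, 90, prob = mu[i, picked]))
      counts[i, ] <- row
    }
    out <- expr_matrix(counts, layer = "raw")
    attr(out, "gene_baseline") <- gene_baseline
    out
  })
}

#' Generate nuclear PU.1-like intensities
#'
#' Draws each nucleus's mean intensity from a three-component lognormal
#' mixture. Under the default `"state"` link, lymphoid-DAM nuclei draw from
#' the low component, homeostatic from the medium and DAM from the high
#' component; under `"mixture"`, components are drawn from the mixture
#' weights.
#'
#' @param cells Cell table.
#' @param truth State assignment.
#' @param config A [simulation_config()].
#' @param seed Stage seed.
#' @return Tibble `nucleus_id`, `mean_intensity`, `sample_id`, `component`.
#' @export
generate_intensities <- function(cells, truth, config,
                                 seed = stage_seeds(config$seed)["intensities"]) {
  mix <- config$intensity_mixture
  with_seed(seed, {
    comp <- if (config$intensity_link == "state") {
      c(homeostatic = "medium", DAM = "high",
        lymphoid_DAM = "low")[truth$cell_state]
    } else {
      sample(mix$component, nrow(cells), replace = TRUE, prob = mix$weight)
    }
    idx <- match(comp, mix$component)
    # arithmetic component mean `mean` => meanlog = log(mean) - sdlog^2/2
    meanlog <- log(mix$mean[idx]) - mix$sdlog[idx]^2 / 2
    tibble::tibble(
      nucleus_id = cells$cell_id,
      mean_intensity = rlnorm(nrow(cells), meanlog, mix$sdlog[idx]),
      sample_id = cells$sample_id,
      component = unname(comp)
    )
  })
}

#' Simulate a complete MERFISH-like dataset with ground truth
#'
#' Runs all generation stages (plaques, cell placement, state assignment,
#' counts, intensities) from one seeded configuration. The `cluster` column
#' of the cell table is set to the true cell state, standing in for an
#' upstream clustering.
#'
#' @param config A [simulation_config()].
#' @return A `plaquemap_sim` list: `cells`, `counts` (raw [expr_matrix()]),
#'   `plaques`, `region` (polygon vertex matrix), `intensities`, `truth`
#'   (list with per-cell labels, program gene sets and true effects) and
#'   the `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(seed = 7, n_cells = 200,
#'                                           n_plaques = 4))
#' dim(sim$counts)
simulate_dataset <- function(config = simulation_config()) {
  validate_simulation_config(config)
  seeds <- stage_seeds(config$seed)
  plaques <- generate_plaques(config, seeds["plaques"])
  cells <- generate_cell_positions(config, seeds["cells"])
  states <- assign_states(cells, plaques, config, seeds["states"])
  counts <- generate_counts(cells, states, config, seeds["counts"])
  intens <- generate_intensities(cells, states, config, seeds["intensities"])
  r <- config$region
  region <- cbind(x = c(r["xmin"], r["xmax"], r["xmax"], r["xmin"]),
                  y = c(r["ymin"], r["ymin"], r["ymax"], r["ymax"]))
  rownames(region) <- NULL
  progs <- active_program_genes(config)
  effects <- dplyr::bind_rows(lapply(names(progs), function(p) {
    tibble::tibble(program = p, gene = progs[[p]],
                   true_log2fc = unname(config$effect_log2fc[p]))
  }))
  truth_cells <- dplyr::left_join(
    states,
    dplyr::select(intens, cell_id = "nucleus_id",
                  intensity_component = "component"),
    by = "cell_id"
  )
  truth_cells$qc_fail <- cells$qc_fail
  cells_out <- dplyr::mutate(
    dplyr::select(cells, -"qc_fail"),
    cluster = states$cell_state
  )
  structure(list(
    cells = cells_out,
    counts = counts,
    plaques = plaques,
    region = region,
    intensities = dplyr::select(intens, -"component"),
    truth = list(
      cells = truth_cells,
      program_genes = progs,
      effects = effects,
      gene_baseline = attr(counts, "gene_baseline"),
      state_fractions = attr(states, "state_fractions")
    ),
    config = config
  ), class = "plaquemap_sim")
}

#' @export
print.plaquemap_sim <- function(x, ...) {
  cat(sprintf(
    "<plaquemap_sim> %d cells x %d genes, %d plaques, seed %d\n",
    nrow(x$cells), ncol(x$counts), nrow(x$plaques), x$config$seed))
  invisible(x)
}
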