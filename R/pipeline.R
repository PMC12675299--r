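#' Pipeline configuration
#'
#' Bundles a simulation block (or a dataset directory) with the thresholds
#' of every analysis stage. Defaults are the study values: 40 transcripts,
#' 100 cubic micrometres, 11 unique genes, 15 micrometre proximity cutoff,
#' min.pct 0.01, log2 fold-change threshold 0.25, intensity fold change
#' 1.25.
#'
#' @param simulate A [simulation_config()], or `NULL` when `dataset_dir`
#'   points at an existing dataset.
#' @param dataset_dir Directory holding a dataset written by
#'   [write_dataset()]; ignored when `simulate` is given.
#' @param min_transcripts,min_volume,min_genes QC thresholds.
#' @param cutoff_um Plaque-proximity cutoff, micrometres.
#' @param min_pct,logfc_threshold,adjust Marker-detection parameters.
#' @param fold_change Intensity-state calibration factor.
#' @param score_seed Seed for module-score control draws.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            dataset_dir = NULL,
                            min_transcripts = 40, min_volume = 100,
                            min_genes = 11, cutoff_um = 15,
                            min_pct = 0.01, logfc_threshold = 0.25,
                            adjust = "BH", fold_change = 1.25,
                            score_seed = 0L) {
  if (is.null(simulate) && is.null(dataset_dir)) {
    abort("Either a simulate block or a dataset directory is required.")
  }
  structure(list(
    simulate = simulate, dataset_dir = dataset_dir,
    min_transcripts = min_transcripts, min_volume = min_volume,
    min_genes = min_genes, cutoff_um = cutoff_um, min_pct = min_pct,
    logfc_threshold = logfc_threshold, adjust = adjust,
    fold_change = fold_change, score_seed = as.integer(score_seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` mapping is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    for (nm in c("region", "plaque_radius_range", "frac_states",
                 "effect_log2fc", "volume_lognormal", "sample_depth",
                 "dropout_cells")) {
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    }
    sim <- do.call(simulation_config, sim_args)
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipeline_config, c(list(simulate = sim), args))
}

#' Validate the files of a dataset directory
#'
#' Schema checks for every input format: missing required columns and
#' malformed records are fatal diagnostics; unknown columns and cells
#' outside the region bounding box are warnings.
#'
#' @param dir Dataset directory.
#' @return Tibble `level` (`"fatal"`/`"warning"`), `file`, `message`;
#'   zero rows when everything is clean.
#' @export
validate_inputs <- function(dir) {
  diags <- list()
  note <- function(level, file, message) {
    diags[[length(diags) + 1]] <<- tibble::tibble(
      level = level, file = file, message = message)
  }
  p <- function(f) file.path(dir, f)
  for (f in c("cells.csv", "plaques.csv", "region.geojson")) {
    if (!file.exists(p(f))) note("fatal", f, "file missing")
  }
  cells <- NULL
  if (file.exists(p("cells.csv"))) {
    cells <- tryCatch(utils::read.csv(p("cells.csv")),
                      error = function(e) {
                        note("fatal", "cells.csv", conditionMessage(e))
                        NULL
                      })
    if (!is.null(cells)) {
      need <- c("cell_id", "x_um", "y_um", "volume_um3", "sample_id")
      miss <- setdiff(need, names(cells))
      if (length(miss)) {
        note("fatal", "cells.csv",
             paste0("missing required columns: ", paste(miss, collapse = ", ")))
        cells <- NULL
      }
      extra <- setdiff(names(cells), c(need, "cluster"))
      if (length(extra)) {
        note("warning", "cells.csv",
             paste0("unknown columns: ", paste(extra, collapse = ", ")))
      }
    }
  }
  if (file.exists(p("plaques.csv"))) {
    pl <- tryCatch(utils::read.csv(p("plaques.csv")),
                   error = function(e) {
                     note("fatal", "plaques.csv", conditionMessage(e))
                     NULL
                   })
    if (!is.null(pl)) {
      need <- c("plaque_id", paste0(rep(c("x", "y"), 4), rep(1:4, each = 2)))
      miss <- setdiff(need, names(pl))
      if (length(miss)) {
        note("fatal", "plaques.csv",
             paste0("each plaque needs an id and 8 coordinates; missing: ",
                    paste(miss, collapse = ", ")))
      } else if (nrow(pl) > 0) {
        coords <- as.matrix(pl[, need[-1]])
        if (anyNA(coords) || any(!is.finite(coords))) {
          note("fatal", "plaques.csv", "non-numeric or missing coordinates")
        }
        if (anyDuplicated(pl$plaque_id)) {
          note("fatal", "plaques.csv", "duplicated plaque_id")
        }
      }
    }
  }
  region <- NULL
  if (file.exists(p("region.geojson"))) {
    region <- tryCatch(read_region_geojson(p("region.geojson")),
                       error = function(e) {
                         note("fatal", "region.geojson", conditionMessage(e))
                         NULL
                       })
  }
  if (!is.null(cells) && !is.null(region)) {
    out <- cells$x_um < min(region[, 1]) | cells$x_um > max(region[, 1]) |
      cells$y_um < min(region[, 2]) | cells$y_um > max(region[, 2])
    if (any(out)) {
      note("warning", "cells.csv",
           paste0("cells outside the region bounding box: ",
                  paste(head(cells$cell_id[out], 10), collapse = ", "),
                  if (sum(out) > 10) " ..." else ""))
    }
  }
  if (length(diags) == 0) {
    tibble::tibble(level = character(), file = character(),
                   message = character())
  } else {
    dplyr::bind_rows(diags)
  }
}

log_stage <- function(con, stage, t0, ...) {
  rec <- c(list(stage = stage,
                elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Fixed stage order: simulate (or load) -> validate -> QC/normalize ->
#' proximity classification -> rank-sum markers (plaque-associated vs
#' distal) -> module scoring and cluster categorization -> intensity-state
#' classification. Every intermediate table is written under `out_dir`,
#' and `report.json` records counts, parameters and file checksums.
#' Identical configuration and seed give byte-identical tables and
#' report; wall-clock timings go to `pipeline.log` only.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con))
  t0 <- as.numeric(Sys.time())
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      ds_dir <- file.path(out_dir, "dataset")
      write_dataset(sim, ds_dir)
    } else {
      ds_dir <- config$dataset_dir
      sim <- read_dataset(ds_dir)
    }
    log_stage(log_con, "simulate", t0, n_cells = nrow(sim$cells))

    stage <- "validate"
    diags <- validate_inputs(ds_dir)
    if (any(diags$level == "fatal")) {
      abort(paste0("Input validation failed: ",
                   paste(diags$message[diags$level == "fatal"],
                         collapse = "; ")))
    }
    log_stage(log_con, "validate", t0, n_warnings = nrow(diags))

    stage <- "qc"
    qc <- run_qc(sim$counts, sim$cells, config$min_transcripts,
                 config$min_volume, config$min_genes)
    log_stage(log_con, "qc", t0, n_retained = nrow(qc$cells))

    stage <- "proximity"
    prox <- compute_proximity(qc$cells, sim$plaques, sim$region,
                              config$cutoff_um)
    prox_sum <- summarize_proximity(prox, sim$plaques, sim$region)
    log_stage(log_con, "proximity", t0,
              n_associated = sum(prox$label == "plaque_associated",
                                 na.rm = TRUE))

    stage <- "de"
    de <- find_markers(qc$lognorm, prox$label,
                       group1 = "plaque_associated",
                       min_pct = config$min_pct,
                       logfc_threshold = config$logfc_threshold,
                       adjust = config$adjust)
    log_stage(log_con, "de", t0, n_tested = attr(de, "n_tested"))

    stage <- "scoring"
    sets <- microglia_gene_sets()
    scores <- score_modules(qc$lognorm, sets, seed = config$score_seed)
    scores$cluster <- qc$cells$cluster
    categories <- categorize_clusters(scores)
    log_stage(log_con, "scoring", t0, n_clusters = nrow(categories))

    stage <- "intensity"
    intens <- dplyr::inner_join(
      sim$intensities,
      dplyr::select(prox, nucleus_id = "cell_id", "label"),
      by = "nucleus_id"
    )
    pu1 <- classify_nuclei(intens, fold_change = config$fold_change)
    props <- state_proportions(pu1)
    props_by_label <- state_proportions(
      dplyr::filter(pu1, !is.na(.data$label)), group_by = "label")
    log_stage(log_con, "intensity", t0, n_nuclei = nrow(pu1))

    list(sim = sim, ds_dir = ds_dir, qc = qc, prox = prox,
         prox_sum = prox_sum, de = de, scores = scores,
         categories = categories, pu1 = pu1, props = props,
         props_by_label = props_by_label)
  }, error = function(e) {
    abort(paste0("Pipeline failed at stage `", stage, "`: ",
                 conditionMessage(e)))
  })

  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(tidy(res$qc), "qc_report.tsv")
  wt(res$prox, "proximity.tsv")
  wt(res$prox_sum$per_plaque, "proximity_per_plaque.tsv")
  wt(res$prox_sum$distal, "proximity_distal_density.tsv")
  wt(tidy(res$de), "de.tsv")
  wt(res$scores, "module_scores.tsv")
  wt(res$categories, "cluster_categories.tsv")
  wt(tibble::as_tibble(res$pu1), "pu1_states.tsv")
  wt(res$props_by_label, "pu1_proportions_by_label.tsv")

  tables <- c("qc_report.tsv", "proximity.tsv", "proximity_per_plaque.tsv",
              "proximity_distal_density.tsv", "de.tsv", "module_scores.tsv",
              "cluster_categories.tsv", "pu1_states.tsv",
              "pu1_proportions_by_label.tsv")
  checksums <- as.list(tools::md5sum(file.path(out_dir, tables)))
  names(checksums) <- tables

  cfg_out <- unclass(config)
  if (!is.null(cfg_out$simulate)) cfg_out$simulate <- unclass(cfg_out$simulate)
  report <- list(
    tool = "plaquemap",
    config = cfg_out,
    stages = list(
      input = list(n_cells = nrow(res$sim$cells),
                   n_genes = ncol(res$sim$counts),
                   n_plaques = nrow(res$sim$plaques)),
      qc = list(n_retained = nrow(res$qc$cells),
                reports = lapply(res$qc$reports, function(r) {
                  r$params <- NULL
                  unclass(r)
                })),
      proximity = list(
        n_in_region = sum(res$prox$in_region),
        n_plaque_associated = sum(res$prox$label == "plaque_associated",
                                  na.rm = TRUE),
        n_distal = sum(res$prox$label == "distal", na.rm = TRUE),
        distal_density_per_um2 = res$prox_sum$distal$density_per_um2
      ),
      de = as.list(glance(res$de)),
      scoring = list(categories = as.list(table(res$categories$category))),
      intensity = list(
        prop_low = res$props$prop_low,
        prop_medium = res$props$prop_medium,
        prop_high = res$props$prop_high
      )
    ),
    checksums = checksums
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
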