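#' Write a simulated dataset to plain-text files
#'
#' Emits the cell-by-gene counts as MatrixMarket MTX (genes x cells, with
#' `features.tsv` / `barcodes.tsv` companions) and as a dense CSV, plus the
#' cell metadata, plaque outlines, region polygon (GeoJSON), nuclear
#' intensities and ground truth, and a JSON manifest carrying a hash of the
#' generating configuration and per-file checksums.
#'
#' @param sim A `plaquemap_sim` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create directory: ", dir))
  p <- function(f) file.path(dir, f)

  m <- Matrix::Matrix(t(unclass(sim$counts)), sparse = TRUE)
  Matrix::writeMM(m, p("counts.mtx"))
  writeLines(colnames(sim$counts), p("features.tsv"))
  writeLines(rownames(sim$counts), p("barcodes.tsv"))
  counts_df <- data.frame(cell_id = rownames(sim$counts),
                          unclass(sim$counts)[, , drop = FALSE],
                          check.names = FALSE)
  utils::write.csv(counts_df, p("counts.csv"), row.names = FALSE)

  utils::write.csv(sim$cells, p("cells.csv"), row.names = FALSE)
  utils::write.csv(sim$plaques, p("plaques.csv"), row.names = FALSE)
  utils::write.csv(sim$intensities, p("intensities.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$cells, p("truth_cells.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$effects, p("truth_effects.csv"),
                   row.names = FALSE)
  progs <- sim$truth$program_genes
  utils::write.csv(
    data.frame(set = rep(names(progs), lengths(progs)),
               gene = unlist(progs, use.names = FALSE)),
    p("program_genes.csv"), row.names = FALSE)

  write_region_geojson(sim$region, p("region.geojson"))

  files <- c("counts.mtx", "features.tsv", "barcodes.tsv", "counts.csv",
             "cells.csv", "plaques.csv", "intensities.csv",
             "truth_cells.csv", "truth_effects.csv", "program_genes.csv",
             "region.geojson")
  manifest <- list(
    format = "plaquemap_dataset",
    config_hash = config_hash(sim$config),
    n_cells = nrow(sim$cells),
    n_genes = ncol(sim$counts),
    n_plaques = nrow(sim$plaques),
    files = as.list(tools::md5sum(file.path(dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Hash of a simulation configuration
#'
#' MD5 of the canonical JSON serialization; changes iff the configuration
#' changes.
#'
#' @param config A [simulation_config()].
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  unname(tools::md5sum(tmp))
}

write_region_geojson <- function(region, path) {
  ring <- rbind(region, region[1, , drop = FALSE])
  gj <- list(
    type = "Feature",
    properties = list(name = "cortex"),
    geometry = list(
      type = "Polygon",
      coordinates = list(lapply(seq_len(nrow(ring)),
                                function(i) as.numeric(ring[i, ])))
    )
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a region polygon from GeoJSON
#'
#' Accepts a GeoJSON `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature is a polygon. Only the outer
#' ring is used.
#'
#' @param path GeoJSON file path.
#' @return An n x 2 vertex matrix (closing vertex dropped).
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- switch(gj$type %||% "",
                 Polygon = gj,
                 Feature = gj$geometry,
                 FeatureCollection = gj$features[[1]]$geometry,
                 abort("Unsupported GeoJSON: expected Polygon/Feature/FeatureCollection."))
  if (!identical(geom$type, "Polygon")) {
    abort("Region geometry must be a GeoJSON Polygon.")
  }
  ring <- do.call(rbind, lapply(geom$coordinates[[1]], as.numeric))
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  if (nrow(ring) < 3) abort("Region polygon needs at least 3 vertices.")
  colnames(ring) <- c("x", "y")
  ring
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @param counts_from `"mtx"` (default) or `"csv"`.
#' @return A `plaquemap_sim`-shaped list (without the config, which is
#'   summarized by its hash in the manifest).
#' @export
read_dataset <- function(dir, counts_from = c("mtx", "csv")) {
  counts_from <- match.arg(counts_from)
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("manifest.json"))) {
    abort(paste0("Not a dataset directory (no manifest.json): ", dir))
  }
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  counts <- if (counts_from == "mtx") {
    read_counts_mtx(p("counts.mtx"), p("features.tsv"), p("barcodes.tsv"))
  } else {
    read_counts_csv(p("counts.csv"))
  }
  truth_cells <- tibble::as_tibble(utils::read.csv(p("truth_cells.csv")))
  progs_df <- utils::read.csv(p("program_genes.csv"))
  list(
    cells = tibble::as_tibble(utils::read.csv(p("cells.csv"))),
    counts = counts,
    plaques = tibble::as_tibble(utils::read.csv(p("plaques.csv"))),
    region = read_region_geojson(p("region.geojson")),
    intensities = tibble::as_tibble(utils::read.csv(p("intensities.csv"))),
    truth = list(
      cells = truth_cells,
      program_genes = split(progs_df$gene, progs_df$set),
      effects = tibble::as_tibble(utils::read.csv(p("truth_effects.csv")))
    ),
    manifest = manifest
  )
}

#' Read raw counts from MatrixMarket companions
#'
#' @param mtx,features,barcodes File paths; the MTX stores genes as rows
#'   and cells as columns, as is conventional for panel outputs.
#' @return A raw [expr_matrix()], cells x genes.
#' @export
read_counts_mtx <- function(mtx, features, barcodes) {
  m <- Matrix::readMM(mtx)
  genes <- readLines(features)
  cells <- readLines(barcodes)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort("MTX dimensions do not match features/barcodes lengths.")
  }
  dense <- t(as.matrix(m))
  dimnames(dense) <- list(cells, genes)
  expr_matrix(dense, layer = "raw")
}

#' Read raw counts from a dense CSV (cell_id column plus one column per gene)
#' @param path CSV path.
#' @return A raw [expr_matrix()].
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "cell_id") abort("Counts CSV must start with a `cell_id` column.")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cell_id
  storage.mode(m) <- "double"
  expr_matrix(m, layer = "raw")
}
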