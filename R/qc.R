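#' Cell quality filters on transcript count and volume
#'
#' Removes cells with fewer than `min_transcripts` total molecules or a
#' segmented volume below `min_volume` cubic micrometres. Both thresholds
#' are strict: a cell at exactly the threshold is retained.
#'
#' @param counts Raw [expr_matrix()] (cells x genes).
#' @param cells Cell table aligned to `counts` rows.
#' @param min_transcripts Minimum total molecules per cell (default 40).
#' @param min_volume Minimum cell volume in cubic micrometres (default 100).
#' @return List `counts`, `cells`, `report` (a `qc_report`).
#' @export
filter_cells <- function(counts, cells, min_transcripts = 40,
                         min_volume = 100) {
  if (expr_layer(counts) != "raw") {
    abort("Transcript/volume filtering applies to the raw layer.")
  }
  check_cells_match(counts, cells)
  totals <- rowSums(counts)
  fail_t <- totals < min_transcripts
  fail_v <- cells$volume_um3 < min_volume
  keep <- !(fail_t | fail_v)
  report <- qc_report(
    stage = "filter_cells",
    n_input = nrow(counts),
    n_fail_transcripts = sum(fail_t),
    n_fail_volume = sum(fail_v),
    n_retained = sum(keep),
    params = list(min_transcripts = min_transcripts, min_volume = min_volume)
  )
  list(counts = counts[keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE],
       report = report)
}

#' Equalize sequencing depth between samples
#'
#' Removes global differences in molecule counts between samples by
#' rescaling every cell of a sample by (grand mean of per-cell totals over
#' all cells) / (mean per-cell total of that sample). After scaling, the
#' per-sample mean totals are identical.
#'
#' @param counts Raw [expr_matrix()].
#' @param cells Cell table with `sample_id`.
#' @return List `counts` (layer `"scaled"`), `scale_factors` (tibble).
#' @export
sample_scale <- function(counts, cells) {
  if (!expr_layer(counts) %in% c("raw", "scaled")) {
    abort("Sample scaling applies to counts, before volume normalization.")
  }
  check_cells_match(counts, cells)
  totals <- rowSums(counts)
  sample_means <- tapply(totals, cells$sample_id, mean)
  if (any(sample_means == 0)) {
    abort(paste0("Sample with zero total transcripts: ",
                 names(sample_means)[sample_means == 0][1]))
  }
  grand <- mean(totals)
  factors <- grand / sample_means
  scaled <- unclass(counts) * as.numeric(factors[cells$sample_id])
  list(
    counts = expr_matrix(scaled, layer = "scaled"),
    scale_factors = tibble::tibble(sample_id = names(factors),
                                   scale_factor = as.numeric(factors))
  )
}

#' Normalize expression by cell volume
#'
#' Divides each cell's values by its segmented volume, yielding counts per
#' cubic micrometre.
#'
#' @param counts [expr_matrix()] (raw or scaled).
#' @param cells Cell table with positive `volume_um3`.
#' @return [expr_matrix()] with layer `"per_um3"`.
#' @export
volume_normalize <- function(counts, cells) {
  if (!expr_layer(counts) %in% c("raw", "scaled")) {
    abort("Volume normalization applies to (scaled) counts.")
  }
  check_cells_match(counts, cells)
  if (any(!is.finite(cells$volume_um3)) || any(cells$volume_um3 <= 0)) {
    abort("All retained cells must have a positive finite volume.")
  }
  expr_matrix(unclass(counts) / cells$volume_um3, layer = "per_um3")
}

#' Filter cells detecting too few unique genes
#'
#' Removes cells with fewer than `min_genes` genes at a value above zero.
#' Positivity is preserved by the scaling and volume normalizations, so the
#' result is identical whichever layer it runs on.
#'
#' @param counts [expr_matrix()] (any layer).
#' @param cells Cell table.
#' @param min_genes Minimum number of detected genes (default 11; strict).
#' @return List `counts`, `cells`, `report`.
#' @export
filter_min_genes <- function(counts, cells, min_genes = 11) {
  check_cells_match(counts, cells)
  n_genes_detected <- rowSums(unclass(counts) > 0)
  keep <- n_genes_detected >= min_genes
  report <- qc_report(
    stage = "filter_min_genes",
    n_input = nrow(counts),
    n_fail_genes = sum(!keep),
    n_retained = sum(keep),
    params = list(min_genes = min_genes)
  )
  list(counts = counts[keep, , drop = FALSE],
       cells = cells[keep, , drop = FALSE],
       report = report)
}

#' Log-normalize volume-normalized expression
#'
#' For each cell, divides the per-cubic-micrometre values by the cell's
#' total, multiplies by 10,000 and applies log1p (natural log). After the
#' transform, `sum(exp(x) - 1)` is exactly 10,000 for every cell.
#'
#' @param counts [expr_matrix()] with layer `"per_um3"`.
#' @return [expr_matrix()] with layer `"lognorm"`.
#' @export
log_normalize <- function(counts) {
  if (expr_layer(counts) != "per_um3") {
    abort("Log normalization applies to the per-cubic-micrometre layer.")
  }
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    abort("Cells with zero total expression must be filtered before log normalization.")
  }
  expr_matrix(log1p(10000 * unclass(counts) / totals), layer = "lognorm")
}

qc_report <- function(stage, n_input, n_retained,
                      n_fail_transcripts = NA_integer_,
                      n_fail_volume = NA_integer_,
                      n_fail_genes = NA_integer_,
                      params = list()) {
  structure(list(stage = stage, n_input = n_input,
                 n_fail_transcripts = n_fail_transcripts,
                 n_fail_volume = n_fail_volume,
                 n_fail_genes = n_fail_genes,
                 n_retained = n_retained, params = params),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report:%s> %d -> %d cells", x$stage, x$n_input,
              x$n_retained))
  if (!is.na(x$n_fail_transcripts)) {
    cat(sprintf(" (%d low-transcript, %d low-volume)",
                x$n_fail_transcripts, x$n_fail_volume))
  }
  if (!is.na(x$n_fail_genes)) cat(sprintf(" (%d low-gene)", x$n_fail_genes))
  cat("\n")
  invisible(x)
}

#' @rdname run_qc
#' @exportS3Method generics::tidy
tidy.plaquemap_qc <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, function(r) {
    tibble::tibble(stage = r$stage, n_input = r$n_input,
                   n_fail_transcripts = r$n_fail_transcripts,
                   n_fail_volume = r$n_fail_volume,
                   n_fail_genes = r$n_fail_genes,
                   n_retained = r$n_retained)
  }))
}

#' @rdname run_qc
#' @exportS3Method generics::glance
glance.plaquemap_qc <- function(x, ...) {
  tibble::tibble(
    n_input = x$reports[[1]]$n_input,
    n_retained = nrow(x$lognorm),
    n_samples = length(unique(x$cells$sample_id))
  )
}

#' Full quality-control and normalization cascade
#'
#' Applies, in fixed order: the transcript/volume filter, per-sample depth
#' equalization, volume normalization to counts per cubic micrometre, the
#' minimum-unique-genes filter, and 10,000-scaled log normalization.
#'
#' @param counts Raw [expr_matrix()].
#' @param cells Cell table aligned to `counts`.
#' @param min_transcripts,min_volume,min_genes Filter thresholds
#'   (defaults 40 molecules, 100 cubic micrometres, 11 genes).
#' @return A `plaquemap_qc` list: `lognorm` and `per_um3` matrices, the
#'   retained `cells`, `scale_factors` and the per-stage `reports`.
#'   `tidy()` returns the per-stage report table; `glance()` a one-row
#'   summary.
#' @export
run_qc <- function(counts, cells, min_transcripts = 40, min_volume = 100,
                   min_genes = 11) {
  s1 <- filter_cells(counts, cells, min_transcripts, min_volume)
  if (nrow(s1$counts) == 0) {
    abort("Empty cohort: no cells pass the transcript/volume filters.")
  }
  s2 <- sample_scale(s1$counts, s1$cells)
  s3 <- volume_normalize(s2$counts, s1$cells)
  s4 <- filter_min_genes(s3, s1$cells, min_genes)
  if (nrow(s4$counts) == 0) {
    abort("Empty cohort: no cells detect enough unique genes.")
  }
  lognorm <- log_normalize(s4$counts)
  structure(list(
    lognorm = lognorm,
    per_um3 = s4$counts,
    cells = s4$cells,
    scale_factors = s2$scale_factors,
    reports = list(filter_cells = s1$report, filter_min_genes = s4$report)
  ), class = "plaquemap_qc")
}
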