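#' Control-gene-matched module score for one gene set
#'
#' The classic expression-bin control scheme: genes are placed into
#' `n_bins` equal-frequency bins by their mean expression across cells;
#' for each signature gene, `n_ctrl` control genes are drawn from the
#' non-signature genes of its bin (without replacement when the bin is
#' large enough, otherwise with replacement; a bin containing only
#' signature genes falls back to the nearest non-signature genes by
#' expression rank -- on panel-sized matrices a signature can otherwise
#' fill its own bins and cancel itself); the per-cell score is the mean
#' expression of the
#' signature genes minus the mean expression of the pooled control draws.
#' Scores can be negative; the expected score of a random gene set is 0.
#'
#' @param counts Log-normalized [expr_matrix()].
#' @param genes Character vector of signature gene ids. Ids missing from
#'   the matrix raise an error listing them.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Seed for the control draws.
#' @return Tibble `cell_id`, `score`, with the binning parameters and
#'   whether any bin needed replacement sampling as attributes.
#' @export
module_score <- function(counts, genes, n_bins = 24, n_ctrl = 100,
                         seed = 0L) {
  if (expr_layer(counts) != "lognorm") {
    abort("Module scores are computed on the log-normalized layer.")
  }
  if (length(genes) == 0) abort("Empty gene set.")
  missing <- setdiff(genes, colnames(counts))
  if (length(missing)) {
    abort(paste0("Gene set ids absent from the matrix: ",
                 paste(missing, collapse = ", ")))
  }
  if (ncol(counts) < n_bins) {
    abort("Matrix has fewer genes than `n_bins`.")
  }
  m <- unclass(counts)
  avg <- colMeans(m)
  rnk <- rank(avg, ties.method = "first")
  bin <- ceiling(n_bins * rnk / length(avg))
  bin_size <- ceiling(length(avg) / n_bins)
  # controls are never signature genes; when a bin holds only signature
  # genes, fall back to the nearest non-signature genes by expression rank
  nonset <- setdiff(names(avg), genes)
  if (length(nonset) == 0) abort("No non-signature genes left for controls.")
  with_replacement <- FALSE
  ctrl <- with_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- nonset[bin[nonset] == bin[[g]]]
      if (length(pool) == 0) {
        pool <- nonset[order(abs(rnk[nonset] - rnk[[g]]))][seq_len(
          min(bin_size, length(nonset)))]
      }
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl)
      } else {
        with_replacement <<- TRUE
        sample(pool, n_ctrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })
  score <- rowMeans(m[, genes, drop = FALSE]) -
    rowMeans(m[, ctrl, drop = FALSE])
  out <- tibble::tibble(cell_id = rownames(m), score = unname(score))
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                              with_replacement = with_replacement)
  out
}

#' Module scores for several gene sets
#'
#' @param counts Log-normalized [expr_matrix()].
#' @param sets Named list of gene-id vectors (default: the bundled
#'   signatures restricted to none -- pass explicitly).
#' @param n_bins,n_ctrl,seed Passed to [module_score()]; the seed is
#'   offset per set so control draws differ between sets but are
#'   reproducible.
#' @return Wide tibble: `cell_id` plus one `<set>_score` column per set.
#' @export
score_modules <- function(counts, sets, n_bins = 24, n_ctrl = 100,
                          seed = 0L) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list.")
  }
  out <- tibble::tibble(cell_id = rownames(counts))
  for (i in seq_along(sets)) {
    s <- module_score(counts, sets[[i]], n_bins, n_ctrl,
                      seed = seed + i - 1L)
    out[[paste0(names(sets)[i], "_score")]] <- s$score
  }
  out
}

#' Categorize clusters by DAM/homeostatic balance and lymphoid signature
#'
#' A cluster is DAM when its mean DAM module score exceeds its mean
#' homeostatic score (ties go to homeostatic); DAM clusters are split into
#' lymphoid-positive (mean lymphoid score > 0) and lymphoid-negative. The
#' mean-score difference is used as the decision statistic because module
#' scores can be negative, which makes a literal score ratio ill-defined;
#' the ratio is still reported for inspection.
#'
#' @param scores Data frame with `cell_id`, `cluster`, `dam_score`,
#'   `homeostatic_score`, `lymphoid_score` (as produced by
#'   [score_modules()] joined to cluster labels).
#' @return Tibble per cluster: mean scores, `dam_homeostatic_ratio`, and
#'   `category` in `homeostatic` / `DAM_lymphoid_pos` / `DAM_lymphoid_neg`.
#' @export
categorize_clusters <- function(scores) {
  need <- c("cluster", "dam_score", "homeostatic_score", "lymphoid_score")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    abort(paste0("`scores` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(scores[need])) abort("Scores and cluster labels must be complete.")
  out <- scores |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_dam = mean(.data$dam_score),
      mean_homeostatic = mean(.data$homeostatic_score),
      mean_lymphoid = mean(.data$lymphoid_score),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dam_homeostatic_ratio = .data$mean_dam / .data$mean_homeostatic,
      category = dplyr::case_when(
        .data$mean_dam <= .data$mean_homeostatic ~ "homeostatic",
        .data$mean_lymphoid > 0 ~ "DAM_lymphoid_pos",
        TRUE ~ "DAM_lymphoid_neg"
      )
    )
  out
}

#' Dot-count positivity call for in situ hybridization signal
#'
#' A cell is positive when its nuclear dot count reaches the probe's
#' threshold: at least 5 dots for *Cd28*, at least 3 for *Mx1* (see
#' [spot_thresholds]); any other probe needs an explicit threshold.
#'
#' @param spot_counts Non-negative integer dot counts.
#' @param threshold Minimum dots for positivity, or a probe name found in
#'   [spot_thresholds].
#' @return Logical vector.
#' @export
#' @examples
#' classify_spot_positive(c(4, 5), "Cd28")  # FALSE TRUE
classify_spot_positive <- function(spot_counts, threshold) {
  if (is.character(threshold)) {
    if (!threshold %in% names(spot_thresholds)) {
      abort(paste0("No preset threshold for probe ", threshold, "."))
    }
    threshold <- spot_thresholds[[threshold]]
  }
  if (anyNA(spot_counts) || any(spot_counts < 0) ||
      any(spot_counts != round(spot_counts))) {
    abort("Dot counts must be non-negative integers.")
  }
  spot_counts >= threshold
}
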