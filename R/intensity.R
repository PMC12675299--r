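#' Fold change between reference nuclear-intensity populations
#'
#' The calibration factor: mean intensity of the high-reference nuclei
#' divided by mean intensity of the low-reference nuclei. With the
#' reference populations used for PU.1 this factor is 1.25, which is the
#' packaged default wherever a fold change is needed.
#'
#' @param high_ref,low_ref Positive intensity vectors.
#' @return The fold change (a single number).
#' @export
reference_fold_change <- function(high_ref, low_ref) {
  if (length(high_ref) == 0 || length(low_ref) == 0) {
    abort("Both reference populations must be non-empty.")
  }
  mh <- mean(high_ref)
  ml <- mean(low_ref)
  if (!is.finite(mh) || !is.finite(ml) || mh <= 0 || ml <= 0) {
    abort("Reference means must be positive and finite.")
  }
  mh / ml
}

#' Intensity cutoffs from a population mean and fold change
#'
#' The low cutoff divides and the high cutoff multiplies the mean
#' intensity of the full population by the fold change.
#'
#' @param intensities Positive intensities of the whole population.
#' @param fold_change Calibration factor, >= 1 (default 1.25).
#' @return A `pu1_cutoffs` list: `population_mean`, `fold_change`,
#'   `low_cut`, `high_cut`.
#' @export
#' @examples
#' compute_cutoffs(rep(100, 5), 1.25)  # cutoffs 80 and 125
compute_cutoffs <- function(intensities, fold_change = 1.25) {
  if (length(intensities) == 0) abort("Empty intensity population.")
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    abort("Intensities must be finite.")
  }
  if (fold_change < 1) abort("`fold_change` must be >= 1.")
  m <- mean(intensities)
  if (m <= 0) abort("Population mean intensity must be positive.")
  structure(list(population_mean = m, fold_change = fold_change,
                 low_cut = m / fold_change, high_cut = m * fold_change),
            class = "pu1_cutoffs")
}

#' @export
print.pu1_cutoffs <- function(x, ...) {
  cat(sprintf("<pu1_cutoffs> mean %.4g, fold change %.4g -> low < %.4g <= medium <= %.4g < high\n",
              x$population_mean, x$fold_change, x$low_cut, x$high_cut))
  invisible(x)
}

#' Classify nuclei into low/medium/high intensity states
#'
#' Values strictly below the low cutoff are `low`, strictly above the high
#' cutoff are `high`; values between the cutoffs -- including exactly at a
#' cutoff -- are `medium`.
#'
#' @param intensities Data frame with `nucleus_id`, `mean_intensity` (and
#'   optionally `sample_id`), or a bare numeric vector.
#' @param cutoffs A `pu1_cutoffs` object, or `NULL` to compute cutoffs
#'   from the data (per `sample_id` when present and `by_sample = TRUE`,
#'   mirroring per-experiment calibration).
#' @param fold_change Used when computing cutoffs from the data.
#' @param by_sample Compute cutoffs within each `sample_id` (default
#'   `TRUE`).
#' @return The input tibble with `state` (`low`/`medium`/`high`) added;
#'   cutoffs used are attached as the `cutoffs` attribute.
#' @export
classify_nuclei <- function(intensities, cutoffs = NULL, fold_change = 1.25,
                            by_sample = TRUE) {
  if (is.numeric(intensities)) {
    intensities <- tibble::tibble(
      nucleus_id = as.character(seq_along(intensities)),
      mean_intensity = intensities
    )
  }
  if (!all(c("nucleus_id", "mean_intensity") %in% names(intensities))) {
    abort("Need columns `nucleus_id` and `mean_intensity`.")
  }
  v <- intensities$mean_intensity
  if (anyNA(v) || any(!is.finite(v))) abort("Intensities must be finite.")
  if (any(v <= 0)) abort("Intensities must be positive.")
  classify_one <- function(v, cut) {
    ifelse(v < cut$low_cut, "low",
           ifelse(v > cut$high_cut, "high", "medium"))
  }
  out <- tibble::as_tibble(intensities)
  if (!is.null(cutoffs)) {
    if (!inherits(cutoffs, "pu1_cutoffs")) abort("`cutoffs` must be a `pu1_cutoffs`.")
    out$state <- classify_one(v, cutoffs)
    used <- list(all = cutoffs)
  } else if (by_sample && "sample_id" %in% names(out)) {
    used <- lapply(split(v, out$sample_id), compute_cutoffs,
                   fold_change = fold_change)
    out$state <- NA_character_
    for (s in names(used)) {
      rows <- out$sample_id == s
      out$state[rows] <- classify_one(v[rows], used[[s]])
    }
  } else {
    cut <- compute_cutoffs(v, fold_change)
    out$state <- classify_one(v, cut)
    used <- list(all = cut)
  }
  attr(out, "cutoffs") <- used
  class(out) <- c("plaquemap_pu1", class(out))
  out
}

#' Proportions of intensity states
#'
#' @param labeled Output of [classify_nuclei()] (or any data frame with a
#'   `state` column).
#' @param group_by Optional column name to group by (e.g. `"sample_id"` or
#'   a plaque-association label).
#' @return Tibble with one row per group: `n`, `prop_low`, `prop_medium`,
#'   `prop_high` (summing to 1 per group).
#' @export
state_proportions <- function(labeled, group_by = NULL) {
  if (!"state" %in% names(labeled)) abort("`labeled` needs a `state` column.")
  grp <- if (is.null(group_by)) rep("all", nrow(labeled)) else {
    if (!group_by %in% names(labeled)) {
      abort(paste0("No such column: ", group_by))
    }
    labeled[[group_by]]
  }
  if (nrow(labeled) == 0) abort("No labeled nuclei.")
  tab <- table(grp, factor(labeled$state, c("low", "medium", "high")))
  prop <- prop.table(tab, margin = 1)
  out <- tibble::tibble(
    group = rownames(tab),
    n = as.integer(rowSums(tab)),
    prop_low = as.numeric(prop[, "low"]),
    prop_medium = as.numeric(prop[, "medium"]),
    prop_high = as.numeric(prop[, "high"])
  )
  if (is.null(group_by)) out$group <- NULL
  out
}

#' @rdname classify_nuclei
#' @param x A `plaquemap_pu1` classification.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.plaquemap_pu1 <- function(x, ...) {
  props <- state_proportions(x)
  cuts <- attr(x, "cutoffs")
  tibble::tibble(
    n = nrow(x),
    n_batches = length(cuts),
    fold_change = cuts[[1]]$fold_change,
    prop_low = props$prop_low,
    prop_medium = props$prop_medium,
    prop_high = props$prop_high
  )
}
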