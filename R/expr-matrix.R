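#' Expression matrix with a layer tag
#'
#' A cells-by-genes numeric matrix carrying a `layer` attribute that records
#' which normalization stage produced it: `"raw"` (integer molecule counts),
#' `"scaled"` (sample-depth equalized counts), `"per_um3"` (counts per cubic
#' micrometre of cell volume) or `"lognorm"` (log1p of 10,000-scaled
#' per-cell fractions). Row names are cell ids, column names gene ids.
#'
#' @param x Numeric matrix, cells in rows, genes in columns. Row and column
#'   names are required.
#' @param layer One of `"raw"`, `"scaled"`, `"per_um3"`, `"lognorm"`.
#' @return `x` with class `expr_matrix` and the layer recorded.
#' @export
expr_matrix <- function(x, layer = c("raw", "scaled", "per_um3", "lognorm")) {
  layer <- match.arg(layer)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix (cells x genes).")
  }
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    abort("`x` must have cell ids as row names and gene ids as column names.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("Expression values must be finite; found NA/NaN/Inf.")
  }
  if (any(x < 0)) abort("Expression values must be non-negative.")
  if (layer == "raw" && any(x != round(x))) {
    abort("The raw layer must contain integer molecule counts.")
  }
  structure(x, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @export
expr_layer <- function(x) {
  attr(x, "layer") %||% abort("`x` carries no layer tag; see `expr_matrix()`.")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, layer \"%s\"\n",
              nrow(x), ncol(x), expr_layer(x)))
  invisible(x)
}

# subsetting keeps the layer tag
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out, layer = attr(x, "layer"),
              class = c("expr_matrix", "matrix", "array"))
  } else {
    out
  }
}

check_cells_match <- function(counts, cells) {
  if (nrow(counts) == 0 && nrow(cells) == 0) return(invisible(TRUE))
  if (!identical(rownames(counts), cells$cell_id)) {
    if (setequal(rownames(counts), cells$cell_id)) {
      abort("`counts` rows and `cells$cell_id` are the same set but ordered differently; align them first.")
    }
    abort("Cell ids of `counts` (row names) and `cells` do not match.")
  }
  invisible(TRUE)
}
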