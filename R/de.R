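#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks are used for ties. When the two samples are tie-free and the
#' combined size is at most `exact_max_n`, the two-sided p-value comes from
#' the exact Mann-Whitney null distribution; otherwise a normal
#' approximation with tie-corrected variance and (by default) a continuity
#' correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_max_n Largest combined sample size for the exact path
#'   (default 12).
#' @param correct Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param alternative `"two.sided"` (default) or `"greater"` (`x` tends
#'   larger than `y`).
#' @return List with `statistic` (the Mann-Whitney U of `x`), `p_value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12, correct = TRUE,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("Both groups must be non-empty.")
  if (anyNA(x) || anyNA(y)) abort("Missing values are not allowed.")
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- tabulate(match(r, unique(r)))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= exact_max_n) {
    upper <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- if (alternative == "greater") upper else {
      min(1, 2 * min(pwilcox(u, n1, n2), upper))
    }
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(statistic = u, p_value = 1, method = "normal"))
  }
  diff <- u - mu
  if (alternative == "greater") {
    z <- (diff - if (correct) 0.5 else 0) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    cc <- if (correct) sign(diff) * 0.5 else 0
    z <- (diff - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = u, p_value = p, method = "normal")
}

#' Log2 fold change between two groups on the log-normalized layer
#'
#' Values are de-logged (`expm1`), averaged per group, and the ratio of the
#' pseudocount-shifted means is log2-transformed.
#'
#' @param x1,x2 Log-normalized values for the two groups.
#' @param pseudocount Added to both de-logged means (default 1).
#' @return A single log2 fold change (positive when `x1` is higher).
#' @export
log2_fold_change <- function(x1, x2, pseudocount = 1) {
  if (length(x1) == 0 || length(x2) == 0) abort("Both groups must be non-empty.")
  log2((mean(expm1(x1)) + pseudocount) / (mean(expm1(x2)) + pseudocount))
}

#' Fraction of cells expressing (value > 0)
#' @param v Numeric vector, non-empty.
#' @return Fraction in \[0, 1\].
#' @export
pct_expressing <- function(v) {
  if (length(v) == 0) abort("Empty group.")
  mean(v > 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' capped at 1.
#'
#' @param p P-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("P-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Rank-sum marker detection between two cell groups
#'
#' The marker cascade: per gene, compute the expressing fraction in each
#' group and the log2 fold change of de-logged means; keep genes with
#' `max(pct1, pct2) >= min_pct` and `|log2fc| >= logfc_threshold`; test the
#' kept genes with the Wilcoxon rank-sum test; adjust p-values over the
#' kept set; sort by p-value.
#'
#' @param counts Log-normalized [expr_matrix()].
#' @param groups Character/factor vector aligned to the rows of `counts`
#'   with exactly two non-`NA` levels; `NA` cells are excluded.
#' @param group1 Optional level to treat as group 1 (fold changes are
#'   group1 over group2); defaults to the first level encountered.
#' @param min_pct Minimum expressing fraction in the better group
#'   (default 0.01).
#' @param logfc_threshold Minimum absolute log2 fold change (default 0.25).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return A `plaquemap_de` tibble: `gene`, `log2fc`, `p_value`,
#'   `p_adjusted`, `pct_group1`, `pct_group2`, with group sizes and
#'   parameters as attributes. `tidy()` returns the table; `glance()` a
#'   one-row summary.
#' @export
find_markers <- function(counts, groups, group1 = NULL,
                         min_pct = 0.01, logfc_threshold = 0.25,
                         adjust = c("BH", "bonferroni"), pseudocount = 1) {
  adjust <- match.arg(adjust)
  if (expr_layer(counts) != "lognorm") {
    abort("Marker detection runs on the log-normalized layer.")
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(counts)) {
    abort("`groups` must align with the rows of `counts`.")
  }
  keep <- !is.na(groups)
  counts <- counts[keep, , drop = FALSE]
  groups <- groups[keep]
  levs <- unique(groups)
  if (length(levs) != 2) {
    abort(paste0("Exactly two groups are required; got ", length(levs), "."))
  }
  if (!is.null(group1)) {
    if (!group1 %in% levs) abort("`group1` is not a level of `groups`.")
    levs <- c(group1, setdiff(levs, group1))
  }
  in1 <- groups == levs[1]
  m1 <- unclass(counts)[in1, , drop = FALSE]
  m2 <- unclass(counts)[!in1, , drop = FALSE]
  pct1 <- colMeans(m1 > 0)
  pct2 <- colMeans(m2 > 0)
  lfc <- log2((colMeans(expm1(m1)) + pseudocount) /
                (colMeans(expm1(m2)) + pseudocount))
  tested <- which(pmax(pct1, pct2) >= min_pct & abs(lfc) >= logfc_threshold)
  pvals <- vapply(tested, function(j) {
    wilcoxon_rank_sum(m1[, j], m2[, j])$p_value
  }, 0)
  res <- tibble::tibble(
    gene = colnames(counts)[tested],
    log2fc = unname(lfc[tested]),
    p_value = unname(pvals),
    p_adjusted = if (length(pvals)) {
      if (adjust == "BH") bh_adjust(pvals) else p.adjust(pvals, "bonferroni")
    } else numeric(),
    pct_group1 = unname(pct1[tested]),
    pct_group2 = unname(pct2[tested])
  )
  res <- dplyr::arrange(res, .data$p_value)
  attr(res, "group1") <- levs[1]
  attr(res, "group2") <- levs[2]
  attr(res, "n1") <- sum(in1)
  attr(res, "n2") <- sum(!in1)
  attr(res, "n_tested") <- length(tested)
  attr(res, "params") <- list(min_pct = min_pct,
                              logfc_threshold = logfc_threshold,
                              adjust = adjust, pseudocount = pseudocount)
  class(res) <- c("plaquemap_de", class(res))
  res
}

#' @rdname find_markers
#' @param x A `plaquemap_de` result.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.plaquemap_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "plaquemap_de")
  out
}

#' @rdname find_markers
#' @exportS3Method generics::glance
glance.plaquemap_de <- function(x, ...) {
  tibble::tibble(
    group1 = attr(x, "group1"), group2 = attr(x, "group2"),
    n1 = attr(x, "n1"), n2 = attr(x, "n2"),
    n_tested = attr(x, "n_tested"),
    n_significant = sum(x$p_adjusted < 0.05),
    adjust = attr(x, "params")$adjust
  )
}
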