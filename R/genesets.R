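#' Bundled microglial gene signatures
#'
#' Marker sets used throughout the package: the lymphoid immunoregulatory
#' signature expressed by the PU.1-low microglial subset, an interferon
#' response signature (unique gene ids; the source list repeats *Isg15*,
#' which is stored once), the disease-associated microglia (DAM) markers
#' that drive DAM cluster identity, and canonical homeostatic microglia
#' markers. All sets are user-overridable wherever they are consumed.
#'
#' @return A named list of character vectors of mouse gene symbols.
#' @export
#' @examples
#' names(microglia_gene_sets())
#' microglia_gene_sets()$lymphoid
microglia_gene_sets <- function() {
  list(
    lymphoid = c("Cd28", "Cd274", "Pdcd1", "Ctla2a", "Cd5", "Sox5",
                 "Cd48", "Cd52", "Cd72"),
    interferon = c("Ifitm3", "Ifit3", "Isg15", "Ifit2", "Ifi27l2a",
                   "Ifi204", "Irf7", "Usp18", "Stat2", "Ifitm2", "Rsad2",
                   "Ifit1", "Bst2", "Isg20", "Xaf1"),
    dam = c("Cst7", "Apoe", "Lpl", "Itgax"),
    homeostatic = c("Cx3cr1", "Tmem119", "P2ry12", "Csf1r", "Hexb",
                    "Sall1", "Selplg")
  )
}

#' In situ hybridization dot-count positivity thresholds
#'
#' Minimum in situ signal dots within a nucleus for a cell to be called
#' positive: at least 5 dots for *Cd28*, at least 3 for *Mx1*.
#'
#' @format Named integer vector.
#' @export
spot_thresholds <- c(Cd28 = 5L, Mx1 = 3L)

#' Read gene sets from GMT or two-column CSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' CSV: columns `set` (or `name`) and `gene`.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("Gene-set file not found: ", path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 0L) < 3
    if (any(bad)) abort("Malformed GMT: every line needs name, description and >= 1 gene.")
    setNames(lapply(parts, function(p) unique(p[-(1:2)])),
             vapply(parts, `[[`, "", 1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df)[names(df) == "name"] <- "set"
    if (!all(c("set", "gene") %in% names(df))) {
      abort("Gene-set CSV needs columns `set` (or `name`) and `gene`.")
    }
    lapply(split(df$gene, df$set), unique)
  }
}
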