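# Hand-built 12-cell / 2-plaque scene exercising every QC and proximity
# boundary: transcript totals 39 vs 40, volumes 99.99 vs 100, 10 vs 11
# detected genes, edge distances 15.0 vs 15.01, a cell inside a plaque and
# a cell outside the traced region.
boundary_fixture <- function() {
  genes <- sprintf("g%02d", 1:12)
  base_row <- rep(4L, 12)                       # total 48, 12 genes
  counts <- rbind(
    c01 = base_row,
    c02 = base_row,
    c03 = base_row,
    c04 = base_row,
    c05 = base_row,
    c06 = base_row,
    c07 = c(6L, rep(3L, 11)),                   # total 39 -> fails
    c08 = c(7L, rep(3L, 11)),                   # total 40 -> passes
    c09 = base_row,                             # volume 99.99 -> fails
    c10 = base_row,                             # volume 100 -> passes
    c11 = c(rep(5L, 10), 0L, 0L),               # 10 genes -> fails
    c12 = c(rep(4L, 11), 0L)                    # 11 genes -> passes
  )
  colnames(counts) <- genes
  cells <- tibble::tibble(
    cell_id = rownames(counts),
    x_um = c(40, 45, 45.01, 5, 20, 95, 50, 50, 50, 50, 50, 50),
    y_um = c(20, 20, 20, 5, 20, 95, 10, 10, 20, 20, 30, 30),
    volume_um3 = c(150, 150, 150, 150, 150, 150, 150, 150, 99.99, 100,
                   150, 150),
    sample_id = "s1"
  )
  plaques <- tibble::tibble(
    plaque_id = 1:2,
    x1 = c(10, 60), y1 = c(10, 60),
    x2 = c(30, 80), y2 = c(10, 60),
    x3 = c(30, 80), y3 = c(30, 80),
    x4 = c(10, 60), y4 = c(30, 80)
  )
  # region excludes c06 at (95, 95) but contains both plaques
  region <- cbind(x = c(0, 90, 90, 0), y = c(0, 0, 100, 100))
  list(counts = expr_matrix(counts, "raw"), cells = cells,
       plaques = plaques, region = region)
}

# independent even-odd crossing test (oracle for boundary-free interior
# checks; boundary points are not used with it)
crossing_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force minimum distance to densely sampled boundary points
brute_edge_distance <- function(px, py, quad, n_samples = 1e5) {
  per_seg <- ceiling(n_samples / 4)
  t <- seq(0, 1, length.out = per_seg)
  best <- Inf
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    sx <- quad[i, 1] + t * (quad[j, 1] - quad[i, 1])
    sy <- quad[i, 2] + t * (quad[j, 2] - quad[i, 2])
    best <- min(best, min((sx - px)^2 + (sy - py)^2))
  }
  sqrt(best)
}

# exhaustive-enumeration two-sided rank-sum p-value (tie-free samples):
# probability over all reassignments of a U at least as far from its mean
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# small, fast simulation configuration for unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_cells = 400L, n_genes = 50L,
                   n_plaques = 8L,
                   dropout_cells = c(low_transcripts = 5L, low_volume = 5L,
                                     low_genes = 5L))
  do.call(simulation_config, utils::modifyList(defaults, args))
}
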