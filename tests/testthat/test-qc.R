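test_that("transcript and volume filters are strict at the printed thresholds", {
  fx <- boundary_fixture()
  out <- filter_cells(fx$counts, fx$cells)
  expect_false("c07" %in% out$cells$cell_id)  # 39 transcripts
  expect_true("c08" %in% out$cells$cell_id)   # exactly 40
  expect_false("c09" %in% out$cells$cell_id)  # 99.99 um3
  expect_true("c10" %in% out$cells$cell_id)   # exactly 100
  expect_equal(out$report$n_fail_transcripts, 1)
  expect_equal(out$report$n_fail_volume, 1)
  expect_equal(out$report$n_retained, 10)
  expect_equal(out$report$n_input - out$report$n_retained, 2)
})

test_that("filter_cells on an empty matrix returns empty output and zero counts", {
  m <- expr_matrix(matrix(integer(), 0, 3,
                          dimnames = list(character(), c("a", "b", "c"))),
                   "raw")
  cells <- tibble::tibble(cell_id = character(), x_um = numeric(),
                          y_um = numeric(), volume_um3 = numeric(),
                          sample_id = character())
  out <- filter_cells(m, cells)
  expect_equal(nrow(out$counts), 0)
  expect_equal(out$report$n_retained, 0)
  expect_equal(out$report$n_fail_transcripts, 0)
})

test_that("filter_cells rejects misaligned cell tables", {
  fx <- boundary_fixture()
  shuffled <- fx$cells[rev(seq_len(nrow(fx$cells))), ]
  expect_error(filter_cells(fx$counts, shuffled), "ordered differently")
})

test_that("sample_scale equalizes per-sample mean totals against the grand mean", {
  # two cells per sample with mean totals 100 and 300 -> factors 2 and 2/3
  counts <- expr_matrix(
    matrix(c(50, 50, 150, 150), 4, 1,
           dimnames = list(c("a", "b", "c", "d"), "g1")), "raw")
  cells <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                          volume_um3 = 1, sample_id = c("u", "u", "v", "v"))
  out <- sample_scale(counts, cells)
  f <- setNames(out$scale_factors$scale_factor, out$scale_factors$sample_id)
  expect_equal(unname(f["u"]), 2)
  expect_equal(unname(f["v"]), 2 / 3)
  totals <- rowSums(out$counts)
  expect_equal(mean(totals[1:2]), mean(totals[3:4]), tolerance = 1e-9)
  # single sample: scale factor 1, matrix unchanged
  one <- sample_scale(counts, dplyr::mutate(cells, sample_id = "w"))
  expect_equal(unclass(one$counts), unclass(counts), ignore_attr = TRUE)
})

test_that("sample_scale is invariant to cell order and errors on empty samples", {
  set.seed(5)
  m <- matrix(rpois(60, 5), 10, 6,
              dimnames = list(sprintf("c%d", 1:10), sprintf("g%d", 1:6)))
  cells <- tibble::tibble(cell_id = rownames(m), volume_um3 = 1,
                          sample_id = rep(c("p", "q"), 5))
  a <- sample_scale(expr_matrix(m, "raw"), cells)
  perm <- sample(10)
  b <- sample_scale(expr_matrix(m[perm, ], "raw"), cells[perm, ])
  expect_equal(unclass(b$counts)[rownames(m), ], unclass(a$counts),
               ignore_attr = TRUE)
  zero <- expr_matrix(matrix(c(0L, 5L), 2, 1,
                             dimnames = list(c("z1", "z2"), "g")), "raw")
  zcells <- tibble::tibble(cell_id = c("z1", "z2"), volume_um3 = 1,
                           sample_id = c("empty", "ok"))
  expect_error(sample_scale(zero, zcells), "empty")
})

test_that("volume_normalize divides by volume and is linear in volume", {
  m <- expr_matrix(matrix(c(5L, 5L), 1, 2,
                          dimnames = list("c1", c("g1", "g2"))), "raw")
  cells <- tibble::tibble(cell_id = "c1", volume_um3 = 2, sample_id = "s")
  out <- volume_normalize(m, cells)
  expect_equal(as.numeric(out), c(2.5, 2.5))
  expect_equal(plaquemap::expr_layer(out), "per_um3")
  ident <- volume_normalize(m, dplyr::mutate(cells, volume_um3 = 1))
  expect_equal(as.numeric(ident), c(5, 5))
  halved <- volume_normalize(m, dplyr::mutate(cells, volume_um3 = 4))
  expect_equal(as.numeric(halved), as.numeric(out) / 2)
  expect_error(volume_normalize(m, dplyr::mutate(cells, volume_um3 = 0)),
               "positive")
})

test_that("minimum-unique-genes filter is strict at 11 and layer-independent", {
  fx <- boundary_fixture()
  s1 <- filter_cells(fx$counts, fx$cells)
  raw_out <- filter_min_genes(s1$counts, s1$cells)
  expect_false("c11" %in% raw_out$cells$cell_id)  # 10 genes
  expect_true("c12" %in% raw_out$cells$cell_id)   # 11 genes
  expect_equal(raw_out$report$n_fail_genes, 1)
  # same outcome after scaling + volume normalization (positivity preserved)
  pv <- volume_normalize(sample_scale(s1$counts, s1$cells)$counts, s1$cells)
  norm_out <- filter_min_genes(pv, s1$cells)
  expect_equal(norm_out$cells$cell_id, raw_out$cells$cell_id)
  # min_genes = 0 removes nothing; an all-zero cell fails any threshold >= 1
  expect_equal(filter_min_genes(fx$counts, fx$cells, 0)$report$n_retained, 12)
  zero <- expr_matrix(matrix(0L, 1, 3, dimnames = list("z", c("a", "b", "c"))),
                      "raw")
  zc <- tibble::tibble(cell_id = "z", volume_um3 = 150, sample_id = "s")
  expect_equal(filter_min_genes(zero, zc, 1)$report$n_retained, 0)
})

test_that("log_normalize matches the 10,000-scaling arithmetic and conserves totals", {
  m <- expr_matrix(matrix(c(2.5, 2.5), 1, 2,
                          dimnames = list("c1", c("g1", "g2"))), "per_um3")
  out <- log_normalize(m)
  expect_equal(as.numeric(out), c(log(5001), log(5001)))
  single <- expr_matrix(matrix(3, 1, 1, dimnames = list("c", "g")),
                        "per_um3")
  expect_equal(as.numeric(log_normalize(single)), log(10001))
  # scaling a cell's row by any k > 0 leaves its log-normalized row unchanged
  k <- 7.3
  out_k <- log_normalize(expr_matrix(unclass(m) * k, "per_um3"))
  expect_equal(as.numeric(out_k), as.numeric(out))
  # conservation: sum(exp(x) - 1) = 10,000 per cell
  set.seed(9)
  big <- expr_matrix(matrix(runif(200, 0.01, 5), 20, 10,
                            dimnames = list(sprintf("c%d", 1:20),
                                            sprintf("g%d", 1:10))),
                     "per_um3")
  ln <- log_normalize(big)
  expect_equal(rowSums(expm1(ln)), rep(10000, 20), tolerance = 1e-6,
               ignore_attr = TRUE)
  zero <- expr_matrix(matrix(0, 1, 2, dimnames = list("z", c("a", "b"))),
                      "per_um3")
  expect_error(log_normalize(zero), "filtered")
})

test_that("the QC cascade reconciles counts and is idempotent for filters", {
  sim <- simulate_dataset(small_config(seed = 2))
  qc <- run_qc(sim$counts, sim$cells)
  rep1 <- qc$reports$filter_cells
  rep2 <- qc$reports$filter_min_genes
  expect_equal(rep1$n_input, nrow(sim$cells))
  expect_equal(rep2$n_input, rep1$n_retained)
  expect_equal(rep2$n_retained, nrow(qc$lognorm))
  expect_equal(nrow(qc$cells), nrow(qc$lognorm))
  # injected QC failures are all removed
  failed <- sim$truth$cells$cell_id[!is.na(sim$truth$cells$qc_fail)]
  expect_length(intersect(failed, qc$cells$cell_id), 0)
  # re-filtering already-filtered cells removes nothing
  s1 <- filter_cells(sim$counts, sim$cells)
  s1b <- filter_cells(s1$counts, s1$cells)
  expect_equal(s1b$report$n_retained, s1$report$n_retained)
  expect_equal(filter_min_genes(qc$per_um3, qc$cells)$report$n_fail_genes, 0)
})

test_that("raising any QC threshold never increases the retained count", {
  sim <- simulate_dataset(small_config(seed = 3))
  base <- run_qc(sim$counts, sim$cells)
  stricter_t <- run_qc(sim$counts, sim$cells, min_transcripts = 80)
  stricter_v <- run_qc(sim$counts, sim$cells, min_volume = 200)
  stricter_g <- run_qc(sim$counts, sim$cells, min_genes = 25)
  expect_lte(nrow(stricter_t$cells), nrow(base$cells))
  expect_lte(nrow(stricter_v$cells), nrow(base$cells))
  expect_lte(nrow(stricter_g$cells), nrow(base$cells))
})
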