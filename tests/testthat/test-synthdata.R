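test_that("plaque generation respects counts, radii and the region", {
  cfg <- small_config(seed = 4)
  expect_equal(nrow(generate_plaques(small_config(seed = 4, n_plaques = 0L))),
               0)
  cfg5 <- small_config(seed = 4, n_plaques = 5L,
                       plaque_radius_range = c(10, 20))
  pl <- generate_plaques(cfg5)
  expect_equal(pl$plaque_id, 1:5)
  quads <- plaquemap:::plaque_vertex_list(pl)
  for (i in 1:5) {
    ctr <- colMeans(quads[[i]])
    # vertex radii were drawn around the generating centre, not the
    # centroid; allow the centroid offset but enforce the design bound
    vr <- sqrt(rowSums(sweep(quads[[i]], 2, ctr)^2))
    expect_true(all(vr < 2 * 20))
    expect_true(all(quads[[i]] >= 0 & quads[[i]] <= 1000))
    expect_gt(abs(plaquemap:::shoelace_area(quads[[i]])), 0)
  }
  # determinism: same config and seed give identical vertices
  expect_identical(generate_plaques(cfg5), generate_plaques(cfg5))
})

test_that("identical config and seed reproduce the whole dataset", {
  a <- simulate_dataset(small_config(seed = 8))
  b <- simulate_dataset(small_config(seed = 8))
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$plaques, b$plaques)
  expect_identical(a$intensities, b$intensities)
  c <- simulate_dataset(small_config(seed = 9))
  expect_false(identical(unclass(a$counts), unclass(c$counts)))
})

test_that("state fractions converge to the configured mixture", {
  cfg <- small_config(seed = 12, n_cells = 3000L, n_plaques = 0L,
                      dropout_cells = c(low_transcripts = 0L,
                                        low_volume = 0L, low_genes = 0L))
  sim <- simulate_dataset(cfg)
  frac <- table(sim$truth$cells$cell_state) / nrow(sim$cells)
  for (st in names(cfg$frac_states)) {
    p <- cfg$frac_states[[st]]
    se <- sqrt(p * (1 - p) / nrow(sim$cells))
    expect_lt(abs(frac[[st]] - p), 3 * se)
  }
  # degenerate mixture: every cell homeostatic
  pure <- simulate_dataset(small_config(
    seed = 13, n_cells = 200L,
    frac_states = c(homeostatic = 1, DAM = 0, lymphoid_DAM = 0),
    dropout_cells = c(low_transcripts = 0L, low_volume = 0L,
                      low_genes = 0L)))
  expect_true(all(pure$truth$cells$cell_state == "homeostatic"))
})

test_that("state labels are independent of plaque distance when enrichment is 1", {
  tab <- matrix(0, 2, 3)
  for (s in 1:10) {
    sim <- simulate_dataset(small_config(
      seed = 60 + s, n_cells = 800L, proximity_enrichment = 1,
      dropout_cells = c(low_transcripts = 0L, low_volume = 0L,
                        low_genes = 0L)))
    t1 <- table(sim$truth$cells$true_proximity_label,
                factor(sim$truth$cells$cell_state,
                       c("homeostatic", "DAM", "lymphoid_DAM")))
    tab <- tab + as.matrix(t1)
  }
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("proximity enrichment raises disease-state odds near plaque edges", {
  sim <- simulate_dataset(small_config(seed = 71, n_cells = 3000L,
                                       proximity_enrichment = 10))
  tc <- sim$truth$cells
  near <- tc$true_proximity_label == "plaque_associated"
  frac_near <- mean(tc$cell_state[near] == "lymphoid_DAM")
  frac_far <- mean(tc$cell_state[!near] == "lymphoid_DAM")
  expect_gt(frac_near, frac_far)
})

test_that("counts follow the configured negative-binomial program model", {
  # no effects: pooled per-gene means match the drawn baselines
  cfg0 <- small_config(seed = 30, n_cells = 2000L, n_plaques = 0L,
                       effect_log2fc = c(homeostatic = 0, dam = 0,
                                         lymphoid = 0),
                       sample_depth = c(1, 1),
                       dropout_cells = c(low_transcripts = 0L,
                                         low_volume = 0L, low_genes = 0L))
  sim0 <- simulate_dataset(cfg0)
  mu <- sim0$truth$gene_baseline
  disp <- cfg0$nb_dispersion
  se <- sqrt((mu + mu^2 / disp) / nrow(sim0$cells))
  dev <- abs(colMeans(sim0$counts) - mu) / se
  expect_lte(sum(dev > 3), 2)  # a stray 3-SE excursion in 50 genes is fine
  # a 2-fold-log2 program elevates its genes about 4x in its state
  cfg2 <- small_config(seed = 31, n_cells = 4000L, n_plaques = 0L,
                       frac_states = c(homeostatic = 0.5, DAM = 0.5,
                                       lymphoid_DAM = 0),
                       effect_log2fc = c(homeostatic = 0, dam = 2,
                                         lymphoid = 0),
                       sample_depth = c(1, 1),
                       dropout_cells = c(low_transcripts = 0L,
                                         low_volume = 0L, low_genes = 0L))
  sim2 <- simulate_dataset(cfg2)
  dam_cells <- sim2$truth$cells$cell_state == "DAM"
  for (g in sim2$truth$program_genes$dam) {
    ratio <- mean(sim2$counts[dam_cells, g]) /
      mean(sim2$counts[!dam_cells, g])
    expect_gt(ratio, 3.2)
    expect_lt(ratio, 4.8)
  }
  # large dispersion approaches Poisson: variance ~ mean
  cfgp <- small_config(seed = 32, n_cells = 3000L, n_plaques = 0L,
                       nb_dispersion = 1e6, baseline_sdlog = 0,
                       effect_log2fc = c(homeostatic = 0, dam = 0,
                                         lymphoid = 0),
                       sample_depth = c(1, 1),
                       dropout_cells = c(low_transcripts = 0L,
                                         low_volume = 0L, low_genes = 0L))
  simp <- simulate_dataset(cfgp)
  vmr <- apply(simp$counts, 2, var) / colMeans(simp$counts)
  expect_lt(abs(mean(vmr) - 1), 0.05)
  expect_error(small_config(nb_dispersion = -1), "positive")
})

test_that("intensities follow the mixture and its links", {
  # single-component mixture: everything from one lognormal
  mix1 <- data.frame(component = c("low", "medium", "high"),
                     mean = c(100, 100, 100), sdlog = 0.1,
                     weight = c(1, 0, 0))
  sim1 <- simulate_dataset(small_config(seed = 40, n_cells = 300L,
                                        intensity_mixture = mix1,
                                        intensity_link = "mixture"))
  expect_true(all(sim1$truth$cells$intensity_component == "low"))
  # components whose configured means have ratio 1.25 reproduce that
  # ratio in the sampled high/low means
  mix2 <- data.frame(component = c("low", "medium", "high"),
                     mean = c(100, 110, 125), sdlog = 0.05,
                     weight = c(0.4, 0.2, 0.4))
  sim2 <- simulate_dataset(small_config(seed = 41, n_cells = 5000L,
                                        intensity_mixture = mix2,
                                        intensity_link = "mixture",
                                        dropout_cells = c(low_transcripts = 0L,
                                                          low_volume = 0L,
                                                          low_genes = 0L)))
  comp <- sim2$truth$cells$intensity_component
  ratio <- mean(sim2$intensities$mean_intensity[comp == "high"]) /
    mean(sim2$intensities$mean_intensity[comp == "low"])
  expect_equal(ratio, 1.25, tolerance = 0.01)
  # state link maps lymphoid-DAM nuclei to the low component
  sim3 <- simulate_dataset(small_config(seed = 42, n_cells = 500L))
  tc <- sim3$truth$cells
  expect_true(all(tc$intensity_component[tc$cell_state == "lymphoid_DAM"]
                  == "low"))
  expect_true(all(tc$intensity_component[tc$cell_state == "homeostatic"]
                  == "medium"))
  expect_error(small_config(intensity_mixture = data.frame(
    component = c("low", "medium", "high"), mean = 100, sdlog = 0.1,
    weight = c(0.5, 0.2, 0.2))), "sum to 1")
})

test_that("injected QC failures violate exactly their designated filter", {
  sim <- simulate_dataset(small_config(seed = 44))
  tc <- sim$truth$cells
  totals <- rowSums(sim$counts)
  ngenes <- rowSums(unclass(sim$counts) > 0)
  vols <- sim$cells$volume_um3
  lt <- tc$cell_id[!is.na(tc$qc_fail) & tc$qc_fail == "low_transcripts"]
  expect_true(all(totals[lt] < 40))
  lv <- tc$cell_id[!is.na(tc$qc_fail) & tc$qc_fail == "low_volume"]
  expect_true(all(vols[match(lv, sim$cells$cell_id)] < 100))
  expect_true(all(totals[lv] >= 40))
  lg <- tc$cell_id[!is.na(tc$qc_fail) & tc$qc_fail == "low_genes"]
  expect_true(all(ngenes[lg] == 10))
  expect_true(all(totals[lg] >= 40))
})

test_that("program gene sets are disjoint and every cell has one state", {
  sim <- simulate_dataset(small_config(seed = 45))
  pg <- sim$truth$program_genes
  expect_false(anyDuplicated(unlist(pg)) > 0)
  expect_true(all(sim$truth$cells$cell_state %in%
                    c("homeostatic", "DAM", "lymphoid_DAM")))
  expect_equal(nrow(sim$truth$cells), nrow(sim$cells))
  # all centroids inside the region extents
  r <- sim$config$region
  expect_true(all(sim$cells$x_um >= r["xmin"] & sim$cells$x_um <= r["xmax"]))
  expect_true(all(sim$cells$y_um >= r["ymin"] & sim$cells$y_um <= r["ymax"]))
})

test_that("classification reproduces the generative proximity labels", {
  sim <- simulate_dataset(small_config(seed = 46))
  prox <- compute_proximity(sim$cells, sim$plaques, sim$region,
                            cutoff_um = sim$config$proximity_cutoff_um)
  expect_equal(prox$label, sim$truth$cells$true_proximity_label)
})
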