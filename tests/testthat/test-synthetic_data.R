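# Ground-truth generators: determinism, calibration recovery, band
# structure, and end-to-end pipeline recovery.

test_that("copy calibration generator is seeded and exactly invertible", {
  a <- simulate_copy_dataset(0.9, 2, n = 25, noise_sd = 5, seed = 99)
  b <- simulate_copy_dataset(0.9, 2, n = 25, noise_sd = 5, seed = 99)
  expect_identical(a, b)
  c_ <- simulate_copy_dataset(0.9, 2, n = 25, noise_sd = 5, seed = 100)
  expect_false(identical(a, c_))

  clean <- simulate_copy_dataset(0.9, 2, n = 40, noise_sd = 0, seed = 1)
  m <- fit_copy_model(clean)
  expect_equal(m$slope, 0.9, tolerance = 1e-12)
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_true(all(clean$biovolume_um3 >= 65 & clean$biovolume_um3 <= 523))
  expect_error(simulate_copy_dataset(1, 0, noise_sd = -1), "non-negative")
})

test_that("community generator is bit-reproducible under a fixed seed", {
  cfg <- community_sim_config(n_stations = 12, cml_stations = 4)
  a <- simulate_community(cfg, seed = 7)
  b <- simulate_community(cfg, seed = 7)
  expect_identical(unclass(a$abundance), unclass(b$abundance))
  expect_identical(as.data.frame(a$env), as.data.frame(b$env))
  expect_identical(a$truth$samples, b$truth$samples)
})

test_that("surface band medians track the configured oceanographic profile", {
  sim <- simulate_community(community_sim_config(n_stations = 2000,
                                                 cml_stations = 0,
                                                 missing_rate = 0),
                            seed = 17)
  tr <- sim$truth$samples
  env <- as.data.frame(sim$env)
  cfg_bands <- sim$config$bands
  for (i in seq_len(nrow(cfg_bands))) {
    in_band <- tr$band == cfg_bands$band[i]
    expect_gt(sum(in_band), 50)
    expect_equal(median(env$par_8d[in_band]), cfg_bands$par[i],
                 tolerance = 0.06)
    expect_equal(median(log10(env$no3_no2[in_band])),
                 log10(cfg_bands$no3_no2[i]), tolerance = 0.12)
    expect_equal(median(env$het_bacteria[in_band]) / cfg_bands$hbac[i], 1,
                 tolerance = 0.06)
  }
})

test_that("noise-free gene tables are the cell tables times the group factors", {
  sim <- simulate_community(community_sim_config(n_stations = 8,
                                                 cml_stations = 0,
                                                 resample = FALSE,
                                                 cf_noise_cv = 0),
                            seed = 23)
  cells <- gene_to_cell(sim$abundance, sim$taxonomy, cf_map = sim$config$cf_map)
  expect_equal(unclass(cells), sim$truth$cells, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the full pipeline recovers true trophic indices on noise-free data", {
  sim <- simulate_community(community_sim_config(n_stations = 10,
                                                 cml_stations = 3,
                                                 resample = FALSE,
                                                 cf_noise_cv = 0),
                            seed = 29)
  asn <- assign_modes(sim$taxonomy, sim$db)
  ti <- compute_ti(gene_to_cell(sim$abundance, sim$taxonomy,
                                cf_map = sim$config$cf_map),
                   asn, denominator = "all_retained")
  tr <- sim$truth$samples[match(ti$sample_id, sim$truth$samples$sample_id), ]
  expect_equal(ti$TI_M, tr$TI_M, tolerance = 1e-10)
  expect_equal(ti$TI_A, tr$TI_A, tolerance = 1e-10)
  expect_equal(ti$TI_H, tr$TI_H, tolerance = 1e-10)
})

test_that("null effect sizes leave the nutrient slope sign at chance level", {
  signs <- sapply(1:30, function(s) {
    sim <- simulate_community(community_sim_config(n_stations = 40,
                                                   cml_stations = 0,
                                                   beta_par = 0, beta_n = 0,
                                                   missing_rate = 0),
                              seed = 300 + s)
    asn <- assign_modes(sim$taxonomy, sim$db)
    ti <- compute_ti(gene_to_cell(sim$abundance, sim$taxonomy), asn)
    regress_ti(ti$TI_M, sim$env$no3_no2, log_x = TRUE)$slope > 0
  })
  expect_gte(mean(signs), 0.2)
  expect_lte(mean(signs), 0.8)
})

test_that("culture simulator honours its ground truth", {
  # no grazing: sampled prey identical to the grazer-free control
  none <- simulate_culture(culture_sim_config(clearance = 0, noise_cv = 0),
                           seed = 1)
  expect_equal(none$series[[1]]$prey, none$series[[1]]$control_prey,
               tolerance = 1e-10)

  # mass balance: prey deficit against control equals cumulative grazing
  sim <- simulate_culture(culture_sim_config(noise_cv = 0), seed = 2)
  fine <- sim$truth$fine
  deficit <- tail(fine$control_prey, 1) - tail(fine$prey, 1)
  expect_equal(deficit, sim$truth$removed_total, tolerance = 0.005)

  # same seed, same sampled series
  a <- simulate_culture(culture_sim_config(noise_cv = 0.1, replicates = 2),
                        seed = 5)
  b <- simulate_culture(culture_sim_config(noise_cv = 0.1, replicates = 2),
                        seed = 5)
  expect_identical(a$series[[2]]$prey, b$series[[2]]$prey)
  expect_error(culture_sim_config(horizon_h = 20, interval_h = 12), "horizon")
})

test_that("noise-free sampled cultures return the configured clearance", {
  sim <- simulate_culture(culture_sim_config(clearance = 2e-6, mu = 0.04,
                                             noise_cv = 0, interval_h = 12),
                          seed = 3)
  r <- grazing_rates(sim$series[[1]])
  expect_lt(abs(r$mean_clearance_ml - 2e-6) / 2e-6, 0.1)
  expect_equal(r$mu_max, 0.04, tolerance = 1e-6)
})

test_that("simulated communities write to the standard on-disk formats", {
  sim <- simulate_community(community_sim_config(n_stations = 4,
                                                 cml_stations = 0,
                                                 missing_rate = 0),
                            seed = 13)
  dir <- file.path(tempdir(), "simout")
  paths <- write_community(sim, dir)
  expect_true(all(file.exists(paths)))
  bundle <- read_community_bundle(paths["abundance"], paths["taxonomy"])
  expect_identical(dim(bundle$abundance), dim(sim$abundance))
  expect_length(bundle$unmapped, 0)
  env <- read_env_table(paths["env"])
  expect_identical(env$sample_id, sim$env$sample_id)
  db <- read_trophic_db(paths["trophic_db"])
  expect_identical(nrow(db), nrow(sim$db))
})
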