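test_that("the generator is seeded and deterministic", {
  cfg <- simulation_config(n_replicates = 2, seed = 123,
                           species = c("fuscum", "fallax"))
  a <- generate_library(cfg)
  b <- generate_library(cfg)
  expect_identical(a$library$reflectance, b$library$reflectance)
  expect_identical(a$masses, b$masses)
  expect_identical(a$truth, b$truth)

  c <- generate_library(simulation_config(n_replicates = 2, seed = 124,
                                          species = c("fuscum", "fallax")))
  expect_false(identical(a$library$reflectance, c$library$reflectance))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(generate_library(simulation_config(n_replicates = 1, seed = 9,
                                               species = "fuscum")))
  expect_identical(.Random.seed, before)
})

test_that("zero noise and zero CV make replicates identical", {
  sim <- generate_library(simulation_config(
    n_replicates = 3, seed = 2, noise_sd = 0, intraspecific_cv = 0,
    species = c("fuscum", "fallax")))
  lib <- filter_library(sim$library, species == "fuscum",
                        measurement_time == "0h")
  expect_equal(lib$reflectance[1, ], lib$reflectance[2, ],
               ignore_attr = TRUE)
  expect_equal(lib$reflectance[2, ], lib$reflectance[3, ],
               ignore_attr = TRUE)
})

test_that("the default design yields 9 species x 10 samples x 4 times", {
  sim <- small_sim(n_replicates = 10)
  expect_identical(nrow(sim$library$reflectance), 360L)
  expect_identical(length(unique(sim$library$meta$species)), 9L)
  expect_identical(nrow(sim$masses), 360L)
  expect_true(all(sim$library$reflectance > 0 &
                    sim$library$reflectance < 1))
})

test_that("generated masses invert exactly to the planted moisture", {
  sim <- small_sim()
  mc <- moisture_content(sim$masses)
  joined <- dplyr::inner_join(
    mc, sim$truth, by = c("sample_id", "measurement_time"))
  expect_identical(nrow(joined), nrow(sim$truth))
  expect_lt(max(abs(joined$moist_fraction.x - joined$moist_fraction.y)),
            1e-12)
})

test_that("drying trajectories respect the habitat ordering", {
  pars <- default_drying_params()
  meso <- pars$decay_per_day[pars$habitat_group == "mesotrophic"]
  oligo <- pars$decay_per_day[pars$habitat_group == "oligo-ombrotrophic"]
  expect_gt(min(meso), max(oligo) * 0.9)
  expect_gt(mean(meso), mean(oligo))

  # slow-drying bog moss after a week still wetter than fast-drying fen
  # moss after a day, matching the planted decay-rate contrast
  sim <- small_sim()
  tr <- sim$truth
  cusp_1wk <- tr$moist_fraction[tr$species == "cuspidatum" &
                                  tr$measurement_time == "1week"]
  girg_24h <- tr$moist_fraction[tr$species == "girgensohnii" &
                                  tr$measurement_time == "24h"]
  expect_gt(min(cusp_1wk), max(girg_24h))
})

test_that("fresh and week-old moisture span the intended ranges", {
  sim <- small_sim()
  tr <- sim$truth
  fresh <- tr$moist_fraction[tr$measurement_time == "0h"]
  week <- tr$moist_fraction[tr$measurement_time == "1week"]
  expect_gt(min(fresh), 0.82)
  expect_lt(max(fresh), 1)
  expect_gt(max(week), 0.9)   # bog species barely dry
  expect_lt(min(week), 0.6)   # fen species dry hard
})

test_that("zero-noise libraries have species R2 = 1 wherever means differ", {
  sim <- generate_library(simulation_config(
    n_replicates = 3, seed = 6, noise_sd = 0, intraspecific_cv = 0,
    species = c("fuscum", "fallax", "cuspidatum")))
  lib <- filter_library(sim$library, measurement_time == "0h")
  r2 <- variance_explained(lib, "species")
  means <- rowsum(lib$reflectance, lib$meta$species) / 3
  differ <- apply(means, 2, function(v) max(v) - min(v)) > 1e-12
  expect_true(all(abs(r2$r2[differ] - 1) < 1e-9))
})

test_that("planted truth matches a regenerated library and carries parameters", {
  cfg <- simulation_config(n_replicates = 2, seed = 3,
                           species = c("fuscum", "fallax"))
  tr <- planted_truth(cfg)
  sim <- generate_library(cfg)
  expect_identical(tr, sim$truth)
  expect_s3_class(attr(tr, "water_wells"), "tbl_df")
  expect_identical(attr(tr, "habitat_partition"),
                   c(fuscum = "oligo-ombrotrophic", fallax = "mesotrophic"))
})

test_that("a model pushed outside (0, 1) fails loudly, naming the culprit", {
  models <- default_species_models()
  models$cuspidatum$water_wells$depth <- c(0.05, 0.1, 0.9, 0.28)
  expect_error(
    generate_library(simulation_config(n_replicates = 1, seed = 1,
                                       species = "cuspidatum"),
                     models = models),
    "cuspidatum at 0h")
})
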