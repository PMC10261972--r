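test_that("group mean/sd spectra follow the sample formulas", {
  lib <- toy_library(matrix(rep(c(0.2, 0.4), each = 5), 10, 4, byrow = FALSE),
                     species = rep("fuscum", 10), times = rep("0h", 10))
  # 5 spectra at 0.2 and 5 at 0.4 per band
  out <- group_mean_sd(lib)
  expect_equal(unique(out$mean), 0.3)
  expect_equal(unique(out$sd), sd(rep(c(0.2, 0.4), each = 5)))

  lib2 <- toy_library(matrix(0.7, 10, 4), species = rep("fallax", 10),
                      times = rep("0h", 10))
  out2 <- group_mean_sd(lib2)
  expect_true(all(out2$mean == 0.7) && all(out2$sd == 0))

  # two spectra {0.2, 0.4}: sd = 0.1414...
  lib3 <- toy_library(matrix(c(0.2, 0.4), 2, 3), species = rep("fuscum", 2),
                      times = rep("0h", 2))
  expect_equal(unique(group_mean_sd(lib3)$sd), sqrt(0.02), tolerance = 1e-12)
})

test_that("planted species means are recovered within sampling error", {
  sim <- generate_library(simulation_config(
    n_replicates = 8, seed = 31, species = c("fuscum", "fallax")))
  stats <- group_mean_sd(sim$library)
  truth_mean <- tapply(sim$library$reflectance[, 1000],
                       paste(sim$library$meta$species,
                             sim$library$meta$measurement_time), mean)
  got <- stats[stats$wavelength_nm == sim$library$wavelength[1000], ]
  expect_equal(
    got$mean[order(paste(got$species, got$measurement_time))],
    as.numeric(truth_mean[sort(names(truth_mean))]), tolerance = 1e-12)
})

test_that("identical groups are nowhere significant and yield no regions", {
  vals <- matrix(runif(6 * 20), 6, 20)
  vals[4:6, ] <- vals[1:3, ]    # 1week identical to 0h
  lib <- toy_library(vals, species = rep("fuscum", 6),
                     times = rep(c("0h", "1week"), each = 3))
  mask <- wilcoxon_bands(lib, "fuscum")
  expect_true(all(!mask$significant))
  expect_identical(nrow(mask$regions), 0L)
  expect_true(all(mask$p_value == 1))
})

test_that("a planted reflectance shift is detected as a contiguous region", {
  set.seed(19)
  n <- 8
  vals <- matrix(runif(2 * n * 60, 0.30, 0.35), 2 * n, 60)
  shifted_bands <- 21:35
  vals[(n + 1):(2 * n), shifted_bands] <-
    vals[(n + 1):(2 * n), shifted_bands] + 0.3
  lib <- toy_library(vals, species = rep("fuscum", 2 * n),
                     times = rep(c("0h", "1week"), each = n))
  mask <- wilcoxon_bands(lib, "fuscum")
  wl <- lib$wavelength
  expect_true(all(mask$significant[shifted_bands]))
  in_region <- any(mask$regions$start_nm <= wl[min(shifted_bands)] &
                     mask$regions$end_nm >= wl[max(shifted_bands)])
  expect_true(in_region)
})

test_that("significant regions exactly partition the significant bands", {
  set.seed(4)
  for (i in 1:20) {
    sig <- runif(50) < 0.3
    wl <- 350:399
    regs <- significant_regions(sig, wl)
    covered <- unlist(purrr::map2(regs$start_nm, regs$end_nm, `:`))
    expect_setequal(covered, wl[sig])
    expect_identical(sum(regs$n_bands), sum(sig))
  }
})

test_that("rank-sum p-values are invariant to monotone transforms", {
  set.seed(8)
  x <- runif(7); y <- runif(6) + 0.2
  p0 <- rep_group_test(x, y)
  expect_equal(rep_group_test(exp(3 * x), exp(3 * y)), p0)
  expect_equal(rep_group_test(-1 / (1 + x), -1 / (1 + y)), p0)
})

test_that("red-edge extraction finds the inflection of a sigmoid", {
  wl <- wavelength_grid()
  sigmoid <- 0.05 + 0.4 / (1 + exp(-(wl - 715) / 10))
  expect_equal(compute_rep(sigmoid, wl), 715)

  # linear ramp: every derivative ties; lowest wavelength wins
  ramp <- 0.001 * (wl - 350)
  expect_equal(compute_rep(ramp, wl), 680)

  expect_error(compute_rep(rep(0.4, length(wl)), wl), "Flat")
})

test_that("red-edge positions of generated spectra sit near the planted inflection", {
  sim <- generate_library(simulation_config(
    n_replicates = 3, seed = 23, species = c("fallax", "cuspidatum")))
  reps <- rep_table(smooth_library(sim$library))
  reps0 <- reps[reps$measurement_time == "0h", ]
  planted <- c(fallax = 722, cuspidatum = 698)
  for (sp in names(planted)) {
    got <- reps0$rep_nm[reps0$species == sp]
    expect_true(all(abs(got - planted[[sp]]) <= 5))
    expect_true(all(got >= 690 & got <= 730))
  }
})

test_that("group comparison of red-edge positions matches exact enumeration", {
  expect_equal(rep_group_test(c(700, 701, 702), c(710, 711, 712)), 0.1)
  expect_equal(rep_group_test(c(700, 700, 700), c(700, 700, 700)), 1)
  expect_error(rep_group_test(700, c(710, 711)), ">= 2")
})

test_that("a planted habitat shift in red edge is detected at n = 10", {
  sim <- small_sim(seed = 77, n_replicates = 10)
  reps <- rep_table(smooth_library(filter_library(
    sim$library, measurement_time == "0h")))
  meso <- reps$rep_nm[reps$habitat_group == "mesotrophic"]
  oligo <- reps$rep_nm[reps$habitat_group == "oligo-ombrotrophic"]
  expect_lt(rep_group_test(meso, oligo), 0.05)
})

test_that("variance explained matches the one-way sums-of-squares identity", {
  lib <- toy_library(matrix(c(0.2, 0.4, 0.6, 0.8), 4, 3),
                     species = c("fuscum", "fuscum", "fallax", "fallax"),
                     times = rep("0h", 4))
  out <- variance_explained(lib, "species")
  expect_equal(unique(out$r2), 0.8, tolerance = 1e-12)

  # identical within groups, distinct between -> R^2 = 1
  lib2 <- toy_library(matrix(c(0.2, 0.2, 0.6, 0.6), 4, 3),
                      species = c("fuscum", "fuscum", "fallax", "fallax"),
                      times = rep("0h", 4))
  expect_equal(unique(variance_explained(lib2, "species")$r2), 1)

  # zero total variance -> 0 by convention
  lib3 <- toy_library(matrix(0.5, 4, 3),
                      species = c("fuscum", "fuscum", "fallax", "fallax"),
                      times = rep("0h", 4))
  expect_equal(unique(variance_explained(lib3, "species")$r2), 0)
})

test_that("permuted labels explain less than the planted labels", {
  sim <- generate_library(simulation_config(
    n_replicates = 6, seed = 13, species = c("fuscum", "fallax", "riparium")))
  lib <- filter_library(sim$library, measurement_time == "0h")
  r2_true <- variance_explained(lib, "species")$r2
  set.seed(99)
  for (i in 1:5) {
    perm <- lib
    perm$meta$species <- sample(perm$meta$species)
    r2_perm <- variance_explained(perm, "species")$r2
    expect_lt(mean(r2_perm), mean(r2_true))
  }
})

test_that("species R2 dominates habitat R2 wherever habitat coarsens species", {
  sim <- small_sim()
  lib <- filter_library(sim$library, habitat_group != "excluded",
                        measurement_time == "0h")
  r2_sp <- variance_explained(lib, "species")$r2
  r2_hb <- variance_explained(lib, "habitat")$r2
  expect_true(all(r2_sp >= r2_hb - 1e-12))
})
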