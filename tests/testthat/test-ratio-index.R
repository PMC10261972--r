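test_that("the ratio index is the plain band ratio", {
  wl <- c(500, 600, 700)
  s <- c(0.4, 0.8, 0.4)
  expect_equal(ratio_index(s, wl, 500, 600), 0.5)
  expect_equal(ratio_index(s, wl, 600, 600), 1)
  flat <- rep(0.3, 3)
  for (l1 in wl) for (l2 in wl) {
    expect_equal(ratio_index(flat, wl, l1, l2), 1)
  }
  expect_error(ratio_index(c(0.4, 0, 0.1), wl, 500, 600), "Zero reflectance")
  expect_error(ratio_index(s, wl, 501, 600), "on the grid")
})

test_that("the moisture regression recovers an exact line and handles constants", {
  m <- seq(40, 95, length.out = 12)
  fit <- fit_ri_on_moisture(-0.02 * m + 2.5, m)
  expect_equal(fit$slope, -0.02, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)

  flat <- fit_ri_on_moisture(rep(1.3, 12), m)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  expect_error(fit_ri_on_moisture(1:2, 1:2), ">= 3")
  expect_error(fit_ri_on_moisture(runif(5), rep(50, 5)), "Zero variance")
})

test_that("the regression matches the normal-equations oracle, n-denominator RMSE", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- runif(n, 30, 99)
    ri <- 2 - 0.01 * m + rnorm(n, 0, 0.1)
    fit <- fit_ri_on_moisture(ri, m)
    orc <- ols_oracle(ri, m)
    expect_equal(fit$slope, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$r2, orc$r2, tolerance = 1e-10)
    expect_equal(fit$rmse, orc$rmse, tolerance = 1e-10)
  }
})

# small library with a planted perfect pair: band 2 = (a*m + b) * band 1
planted_pair_library <- function(n = 8) {
  grid <- seq(350, 359)
  m <- seq(40, 95, length.out = n)
  base <- matrix(runif(n * 10, 0.3, 0.6), n, 10)
  base[, 3] <- 0.5
  base[, 7] <- (-0.008 * m + 1.4) * base[, 3]
  lib <- toy_library(base, species = rep("fuscum", n), times = rep("0h", n))
  masses <- tibble::tibble(
    sample_id = lib$meta$sample_id, measurement_time = "0h",
    total_mass_g = 100 / (1 - m / 100) + 50, container_mass_g = 50,
    dry_mass_g = 100)
  list(lib = lib, masses = masses, m = m, l1 = grid[7], l2 = grid[3])
}

test_that("the exhaustive scan finds a planted perfect pair with R2 = 1", {
  set.seed(10)
  pl <- planted_pair_library()
  sc <- scan_all_pairs(pl$lib, pl$masses, "0h")
  expect_equal(sc$best$l1, pl$l1)
  expect_equal(sc$best$l2, pl$l2)
  expect_equal(sc$best$r2, 1, tolerance = 1e-9)
  expect_equal(sc$best$slope, -0.008, tolerance = 1e-9)
  expect_equal(sc$best$intercept, 1.4, tolerance = 1e-9)
})

test_that("scan surfaces satisfy the diagonal and masking conventions", {
  set.seed(10)
  pl <- planted_pair_library()
  sc <- scan_all_pairs(pl$lib, pl$masses, "0h")
  expect_true(all(diag(sc$r2) == 0))
  expect_true(all(sc$r2 >= 0 & sc$r2 <= 1 + 1e-12, na.rm = TRUE))

  # a near-zero denominator band is masked out entirely
  lib2 <- pl$lib
  lib2$reflectance[3, 5] <- 5e-5
  sc2 <- scan_all_pairs(lib2, pl$masses, "0h")
  expect_true(all(is.na(sc2$r2[, 5])))
  expect_false(anyNA(sc2$r2[, 3]))
})

test_that("every surface cell equals explicit per-pair least squares", {
  set.seed(17)
  pl <- planted_pair_library(n = 9)
  sc <- scan_all_pairs(pl$lib, pl$masses, "0h")
  wl <- sc$wavelength
  for (i in 1:100) {
    i1 <- sample(length(wl), 1); i2 <- sample(length(wl), 1)
    if (i1 == i2) next
    ri <- pl$lib$reflectance[, i1] / pl$lib$reflectance[, i2]
    orc <- ols_oracle(ri, pl$m)
    expect_equal(sc$r2[i1, i2], orc$r2, tolerance = 1e-9)
    expect_equal(sc$slope[i1, i2], orc$slope, tolerance = 1e-9)
    expect_equal(sc$intercept[i1, i2], orc$intercept, tolerance = 1e-9)
    expect_equal(sc$rmse[i1, i2], orc$rmse, tolerance = 1e-9)
  }
})

test_that("swapping the pair inverts RI and changes R2 (both triangles matter)", {
  set.seed(10)
  pl <- planted_pair_library()
  sc <- scan_all_pairs(pl$lib, pl$masses, "0h")
  i1 <- which(sc$wavelength == pl$l1)
  i2 <- which(sc$wavelength == pl$l2)
  ri <- pl$lib$reflectance[, i1] / pl$lib$reflectance[, i2]
  expect_equal(ratio_index(pl$lib$reflectance, pl$lib$wavelength,
                           pl$l2, pl$l1), 1 / ri)
  # the planted direction is exactly linear, the inverse is not
  expect_equal(sc$r2[i1, i2], 1, tolerance = 1e-9)
  expect_lt(sc$r2[i2, i1], 1 - 1e-6)
})

test_that("a strided scan never beats the full scan", {
  sim <- generate_library(simulation_config(
    n_replicates = 4, seed = 15, species = c("fuscum", "fallax", "riparium")))
  full <- scan_all_pairs(sim$library, sim$masses, "1week", stride_nm = 10,
                         range_nm = c(1000, 1600))
  coarse <- scan_all_pairs(sim$library, sim$masses, "1week", stride_nm = 50,
                           range_nm = c(1000, 1600))
  expect_lte(coarse$best$r2, full$best$r2 + 1e-12)
})

test_that("high-R2 regions are reported as connected bounding boxes", {
  fake <- function(r2) {
    structure(list(wavelength = seq(500, 500 + nrow(r2) - 1), r2 = r2,
                   time = "0h", n = 9, stride_nm = 1),
              class = "ri_scan")
  }
  empty <- surface_summary(fake(matrix(0.1, 6, 6)), 0.7)
  expect_identical(nrow(empty), 0L)

  one <- matrix(0, 8, 8)
  one[3:5, 2:4] <- 0.9
  box <- surface_summary(fake(one), 0.7)
  expect_identical(nrow(box), 1L)
  expect_equal(unlist(box[1, 1:4], use.names = FALSE),
               c(502, 504, 501, 503))
  expect_identical(box$n_cells, 9L)

  two <- matrix(0, 10, 10)
  two[1:2, 1:2] <- 0.8
  two[7:9, 6:9] <- 0.95
  boxes <- surface_summary(fake(two), 0.7)
  expect_identical(nrow(boxes), 2L)
  expect_equal(boxes$max_r2, c(0.95, 0.8))
  expect_identical(sum(boxes$n_cells), 16L)

  # diagonal touch is not 4-connected: two components
  diag_touch <- matrix(0, 4, 4)
  diag_touch[1, 1] <- 0.9; diag_touch[2, 2] <- 0.9
  expect_identical(nrow(surface_summary(fake(diag_touch), 0.7)), 2L)
})
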