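test_that("species fractions follow the sequential closed form and close
           to one", {
  s <- scheme_5s(rate_fast = 40, rate_slow = 1)
  t <- c(0, 0.01, 0.1, 1, 10)
  fr <- species_fractions(s, t)
  expect_equal(rowSums(fr), rep(1, 5), tolerance = 1e-12)
  expect_equal(fr[, 1], exp(-40 * t))
  expect_equal(fr[, 2], 40 / (1 - 40) * (exp(-40 * t) - exp(-1 * t)),
               tolerance = 1e-12)

  # hold scheme: first species until the lag, then the chain
  s6 <- scheme_601(rate = 0.5, hold = 0.2)
  fr6 <- species_fractions(s6, c(0.1, 0.19, 0.2, 0.2 + log(2) / 0.5))
  expect_equal(unname(fr6[1:2, 1]), c(1, 1))
  expect_equal(as.numeric(fr6[3, 2]), 1)
  expect_equal(as.numeric(fr6[4, 2]), 0.5, tolerance = 1e-9)
  expect_error(species_fractions(s6, -1), ">= 0")
  expect_error(kinetic_scheme(list(1, 2), numeric(0)), "one rate")
  expect_error(kinetic_scheme(list(1, 2, 3), c(1, Inf)), "leading")
})

test_that("zero rates limit: stationary series equals the first species", {
  sch <- scheme_601(rate = 1e-9, hold = 1e9) # effectively frozen
  ts <- simulate_disassembly(sch, times = c(0.02, 0.1, 1),
                             noise = noise_model(0), seed = 1)
  expect_equal(ts$profile[[1]]$I, ts$profile[[3]]$I)
})

test_that("noiseless single-member equilibrium profile equals the Debye
           profile", {
  pool <- default_pool()
  mapping <- list("0.2" = tibble::tibble(name = "L000_R000", weight = 1))
  eq <- simulate_equilibrium_series(salts = 0.2, sucrose = 0.5,
                                    mapping = mapping, pool = pool,
                                    noise = noise_model(0), seed = 1)
  direct <- debye_profile(pool$conformer[[match("L000_R000", pool$name)]],
                          sucrose = 0.5, nacl = 0.2,
                          model = contrast_model(match_salt = 0.2),
                          smear_sigma = 3)
  expect_equal(eq[[1]]$I, direct$I, tolerance = 1e-12)
  bad_map <- list("0.2" = tibble::tibble(name = "L000_R000", weight = 0.5))
  expect_error(simulate_equilibrium_series(salts = 0.2, mapping = bad_map,
                                           pool = pool), "sum to 1")
})

test_that("equilibrium series expands monotonically with salt", {
  eq <- simulate_equilibrium_series(pool = default_pool(), seed = 4)
  rg <- purrr::map_dbl(eq, function(p) {
    d <- scan_dmax(p, seq(100, 560, by = 60))
    attr(d, "rg")
  })
  expect_lt(abs(rg[1] - 45), 5)       # compact NCP-DNA at 0.2 M
  expect_gt(rg[length(rg)], 110)      # approaching free DNA at 2 M
  expect_true(all(diff(rg) > -5))     # monotone within noise
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_disassembly(scheme_601(), times = c(0.02, 0.1, 1), seed = 42)
  b <- simulate_disassembly(scheme_601(), times = c(0.02, 0.1, 1), seed = 42)
  expect_identical(a$profile[[2]]$I, b$profile[[2]]$I)
  e1 <- simulate_equilibrium_series(salts = c(0.2, 1), pool = default_pool(),
                                    seed = 9)
  e2 <- simulate_equilibrium_series(salts = c(0.2, 1), pool = default_pool(),
                                    seed = 9)
  expect_identical(e1[[2]]$I, e2[[2]]$I)
})

test_that("ground truth stored with a series matches its construction", {
  ts <- simulate_disassembly(scheme_601(), times = c(0.02, 0.5, 2), seed = 2)
  gt <- attr(ts, "ground_truth")
  expect_equal(gt$rates, 0.74)
  expect_equal(gt$lag, 0.2)
  expect_equal(nrow(gt$fractions), 3)
  expect_equal(length(gt$i0_species), 3)
  # bound species share I(0); dissociation lowers it (squared-sum rule)
  expect_equal(gt$i0_species[1], gt$i0_species[2], tolerance = 1e-9)
  expect_lt(gt$i0_species[3], gt$i0_species[2])
})

test_that("fixture bundle is complete and deterministic", {
  dir1 <- withr::local_tempdir()
  man <- fixture_bundle(dir1, seed = 5, n_frames = 12)
  expect_equal(length(list.files(file.path(dir1, "pool"), "\\.pdb$")), 32)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "tr_601", "series.json")))
  expect_equal(man$tr_601$rates, 0.74)
  expect_equal(man$tr_5s$rates, c(41.6, 1.13))
  ts <- read_series(file.path(dir1, "tr_601"))
  expect_equal(nrow(ts), 12)

  dir2 <- withr::local_tempdir()
  fixture_bundle(dir2, seed = 5, n_frames = 12)
  f1 <- readLines(file.path(dir1, "tr_601", "frame_00003.dat"))
  f2 <- readLines(file.path(dir2, "tr_601", "frame_00003.dat"))
  expect_identical(f1, f2)
})
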