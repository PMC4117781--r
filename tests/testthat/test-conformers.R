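test_that("straight duplex has the forced geometry", {
  d <- build_duplex(2)
  expect_equal(nrow(d), 4)
  expect_equal(diff(range(d$z)), 3.4)

  d149 <- build_duplex(149)
  expect_equal(nrow(d149), 298)
  # brute-force maximum pairwise distance: rod length plus the duplex
  # cross-section contribution
  dm <- max(dist(as.matrix(d149[, c("x", "y", "z")])))
  expect_gte(dm, 148 * 3.4)
  expect_lte(dm, sqrt((148 * 3.4)^2 + 20^2))
  expect_equal(dmax_of(d149), dm)
  expect_error(build_duplex(1), "bp_total")
})

test_that("straight duplex Rg matches the cylinder closed form within 2%", {
  d <- build_duplex(149)
  L <- 148 * 3.4
  rod <- sqrt(L^2 / 12 + 10^2 / 2)
  expect_lt(abs(rg_of(d) / rod - 1), 0.02)
})

test_that("wrapped model matches canonical nucleosome dimensions", {
  w <- build_wrapped(147)
  expect_equal(nrow(w), 294)
  rg <- rg_of(w)
  expect_gte(rg, 40)
  expect_lte(rg, 50)
  # compact particle: full width ~ 100 A
  expect_lt(dmax_of(w), 150)
})

test_that("wrapped builder degrades gracefully to the duplex limit and
           rejects overlapping geometry", {
  # nearly straight path whose arc length equals the duplex contour: the
  # wrapped model then reduces to the straight duplex
  turns <- 1e-3
  p <- helix_params(superhelix_radius = 19 * 3.4 / (2 * pi * turns),
                    superhelix_pitch = 1e-3, wrapped_turns = turns)
  w <- build_wrapped(20, p)
  expect_equal(dmax_of(w), dmax_of(build_duplex(20)), tolerance = 0.01)
  expect_equal(rg_of(w), rg_of(build_duplex(20)), tolerance = 0.01)

  bad <- helix_params(superhelix_radius = 2, superhelix_pitch = 1,
                      wrapped_turns = 6)
  expect_error(build_wrapped(147, bad), "degenerate geometry")
})

test_that("released models interpolate between wrapped and free", {
  w <- build_wrapped(147)
  r0 <- build_released(147, 0, 0)
  expect_equal(as.matrix(r0[, c("x", "y", "z")]),
               as.matrix(w[, c("x", "y", "z")]))

  j <- build_released(147, 74, 0)
  expect_gte(dmax_of(j), 300)
  expect_lte(dmax_of(j), 350)
  # arm continuity: consecutive bp centres never separated by more than
  # the straight-DNA rise (plus numerical slack)
  xyz <- as.matrix(j[, c("x", "y", "z")])
  centres <- (xyz[1:147, ] + xyz[148:294, ]) / 2
  steps <- sqrt(rowSums(diff(centres)^2))
  expect_lte(max(steps), 3.4 + 1e-6)

  expect_error(build_released(147, -1, 0), "non-negative")
  expect_error(build_released(147, 100, 60), "exceed")

  free <- build_released(147, 147, 0)
  expect_equal(dmax_of(free), dmax_of(build_duplex(147)))
})

test_that("symmetry classification follows the release record", {
  expect_equal(classify_symmetry(build_released(147, 0, 0)), "wrapped")
  expect_equal(classify_symmetry(build_released(147, 74, 0)), "asymmetric")
  expect_equal(classify_symmetry(build_released(147, 37, 37)), "symmetric")
  expect_equal(classify_symmetry(build_released(147, 147, 0)), "free")
  expect_equal(classify_symmetry(released_left = 140, released_right = 0,
                                 bp_total = 147), "free")
})

test_that("rg_of and dmax_of are exact on two beads and rigid-motion
           invariant", {
  two <- nucsaxs:::new_conformer(
    tibble::tibble(x = c(0, 10), y = 0, z = 0, phase = "DNA"), 1, 0, 0, "two")
  expect_equal(rg_of(two), 5)
  expect_equal(dmax_of(two), 10)
  expect_error(rg_of(two[1, ]), "2 beads")

  j <- build_released(147, 55, 12)
  jm <- rigid_motion(j)
  expect_equal(rg_of(jm), rg_of(j), tolerance = 1e-10)
  expect_equal(dmax_of(jm), dmax_of(j), tolerance = 1e-10)
})

test_that("default pool has 32 distinct members spanning wrapped to free", {
  pool <- default_pool()
  expect_equal(nrow(pool), 32)
  expect_false(anyDuplicated(pool$name) > 0)
  expect_true(any(pool$released_left == pool$released_right &
                    pool$symmetry == "symmetric"))
  expect_true(any(abs(pool$released_left - pool$released_right) >= 30))
  expect_true("wrapped" %in% pool$symmetry)
  expect_true("free" %in% pool$symmetry)
  expect_true(all(c("symmetric", "asymmetric") %in% pool$symmetry))
})

test_that("pool handles degenerate and invalid specifications", {
  empty <- generate_pool(pool_spec(release_grid = matrix(numeric(0), 0, 2)))
  expect_equal(nrow(empty), 0)
  expect_error(pool_spec(release_grid = rbind(c(0, 0), c(0, 0))),
               "duplicate")
  expect_error(pool_spec(release_grid = rbind(c(100, 100))), "exceed")
})

test_that("Rg grows with release along the pool's one-parameter families
           and correlates strongly overall", {
  pool <- default_pool()
  single <- dplyr::arrange(
    dplyr::filter(pool, released_right == 0), total_released)
  expect_true(all(diff(single$rg) > -1e-9))
  sym <- dplyr::arrange(
    dplyr::filter(pool, released_left == released_right), total_released)
  expect_true(all(diff(sym$rg) > -1e-9))
  expect_gt(cor(pool$total_released, pool$rg, method = "spearman"), 0.85)
})
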