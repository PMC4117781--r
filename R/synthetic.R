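#' Noise model for synthetic profiles
#'
#' @param relative_gaussian Relative Gaussian noise on 1-D intensities
#'   (fraction of I; the recorded sigma matches the generating noise).
#' @param poisson_flux Photons per frame per unit profile intensity, used
#'   only when rendering detector images.
#' @param buffer_level Flat background added before subtraction, as a
#'   fraction of the profile's first intensity value (inflates sigma only
#'   for 1-D simulation).
#' @return A `noise_model` list.
#' @export
noise_model <- function(relative_gaussian = 0.02, poisson_flux = NA_real_,
                        buffer_level = 0) {
  if (relative_gaussian < 0 || buffer_level < 0 ||
      (!is.na(poisson_flux) && poisson_flux < 0)) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  structure(list(relative_gaussian = relative_gaussian,
                 poisson_flux = poisson_flux, buffer_level = buffer_level),
            class = "noise_model")
}

apply_noise_1d <- function(I, noise) {
  sg <- noise$relative_gaussian * abs(I) +
    noise$buffer_level * abs(I[1]) * noise$relative_gaussian
  list(I = I + stats::rnorm(length(I), 0, sg), sigma = sg)
}

#' Kinetic scheme of sequential species interconversion
#'
#' An ordered chain of species (each a list of independently scattering
#' particles, i.e. conformers with DNA and/or PROTEIN beads) connected by
#' first-order rates. An optional lag holds the system in the first species
#' before the chain starts; a leading rate of `Inf` denotes an effectively
#' instantaneous first step (used for the burst-phase opening of the
#' nucleosome, complete within the mixer dead time).
#'
#' @param species List of species; each species is a list of `conformer`
#'   particles that scatter independently.
#' @param rates First-order rates between successive species, 1/s
#'   (length one less than the number of species; only leading entries may
#'   be `Inf`).
#' @param lag Hold time before the first transition, seconds.
#' @param names Species names.
#' @return A `kinetic_scheme` list.
#' @export
kinetic_scheme <- function(species, rates, lag = 0,
                           names = paste0("species_", seq_along(species))) {
  if (length(species) < 2) stop("need >= 2 species", call. = FALSE)
  if (length(rates) != length(species) - 1) {
    stop("need one rate per transition", call. = FALSE)
  }
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  inf <- !is.finite(rates)
  if (any(inf) && !all(which(inf) == seq_len(sum(inf)))) {
    stop("only leading rates may be Inf", call. = FALSE)
  }
  structure(list(species = species, rates = rates, lag = lag,
                 species_names = names),
            class = "kinetic_scheme")
}

#' Species fractions of a sequential first-order chain
#'
#' Closed-form solution (Bateman equations, distinct rates) of
#' A1 -> A2 -> ... -> An, shifted by the scheme's lag; leading infinite
#' rates collapse their species instantaneously once the lag has elapsed.
#' Fractions sum to one at every time.
#'
#' @param scheme A [kinetic_scheme()].
#' @param times Times, seconds (>= 0).
#' @return Matrix of fractions, one row per time, one column per species.
#' @export
species_fractions <- function(scheme, times) {
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  n <- length(scheme$species)
  out <- matrix(0, length(times), n,
                dimnames = list(NULL, scheme$species_names))
  tp <- times - scheme$lag
  n_inst <- sum(!is.finite(scheme$rates))
  k <- scheme$rates[is.finite(scheme$rates)]
  if (anyDuplicated(k)) {
    stop("finite rates must be distinct (Bateman closed form)", call. = FALSE)
  }
  start <- n_inst + 1 # first species populated once the lag has elapsed
  m <- n - start + 1
  bateman <- function(t) {
    f <- numeric(m)
    if (m == 1) {
      f[1] <- 1
      return(f)
    }
    for (j in seq_len(m - 1)) {
      ks <- k[1:j]
      f[j] <- prod(ks[-j]) * sum(vapply(seq_len(j), function(i) {
        exp(-ks[i] * t) / prod(ks[-i] - ks[i])
      }, 0))
    }
    f[m] <- 1 - sum(f[seq_len(m - 1)])
    f
  }
  for (ti in seq_along(times)) {
    if (tp[ti] < 0) out[ti, 1] <- 1 else out[ti, start:n] <- bateman(tp[ti])
  }
  out
}

species_profile <- function(particles, qgrid, sucrose, nacl, model,
                            smear_sigma = 3) {
  Is <- purrr::map(particles, function(cf) {
    w <- bead_weights(cf, sucrose, nacl, model)
    if (all(abs(w) < 1e-12)) return(rep(0, length(qgrid)))
    debye_profile_w(bead_matrix(cf), w, qgrid, smear_sigma = smear_sigma)$I
  })
  Reduce(`+`, Is)
}

#' Default disassembly scheme for the strong-positioning (601) construct
#'
#' wrapped NCP --(burst opening, hold 0.2 s)--> J-shaped intermediate with
#' the disrupted histone core still bound --(0.74 1/s)--> free DNA plus
#' dissociated protein. The hold reproduces the observed ~200 ms plateau in
#' I(0,t) and Rg(t); the dissociation rate is the construct's measured
#' protein-release rate.
#'
#' @param params A [helix_params()].
#' @param rate Dissociation rate of the intermediate, 1/s.
#' @param hold Intermediate hold (lag), seconds.
#' @return A [kinetic_scheme()].
#' @export
scheme_601 <- function(params = helix_params(), rate = 0.74, hold = 0.2) {
  core <- with_protein_core(build_wrapped(147, params), params)
  ncp <- core
  j_bound <- with_protein_core(build_released(147, 74, 0, params), params)
  free_dna <- build_duplex(149, params, name = "free_dna")
  free_prot <- protein_only(params)
  kinetic_scheme(
    species = list(list(ncp), list(j_bound), list(free_dna, free_prot)),
    rates = c(Inf, rate), lag = hold,
    names = c("wrapped_ncp", "J_bound_core", "dissociated")
  )
}

#' Default disassembly scheme for the weak-positioning (5S) construct
#'
#' wrapped NCP --(41.6 1/s)--> extended DNA with a partially bound,
#' disrupted core (one histone dimer already released) --(1.13 1/s)-->
#' free DNA plus fully dissociated protein. Two resolvable rates, no hold.
#'
#' @param params A [helix_params()].
#' @param rate_fast,rate_slow The two first-order rates, 1/s.
#' @return A [kinetic_scheme()].
#' @export
scheme_5s <- function(params = helix_params(), rate_fast = 41.6,
                      rate_slow = 1.13) {
  ncp <- with_protein_core(build_wrapped(147, params), params)
  ext <- build_released(147, 110, 0, params)
  ext_part <- with_protein_core(ext, params, n_beads = 6)
  dimer <- protein_only(params, n_beads = 2)
  free_dna <- build_duplex(149, params, name = "free_dna")
  free_prot <- protein_only(params)
  kinetic_scheme(
    species = list(list(ncp), list(ext_part, dimer),
                   list(free_dna, free_prot)),
    rates = c(rate_fast, rate_slow),
    names = c("wrapped_ncp", "extended_partial_core", "dissociated")
  )
}

# a free protein particle (dissociated pseudo-histone beads)
protein_only <- function(params = helix_params(), n_beads = 8) {
  ang <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
  beads <- tibble::tibble(x = 15 * cos(ang), y = 15 * sin(ang),
                          z = 8 * sin(2 * ang), phase = "PROTEIN")
  new_conformer(beads, 0L, 0L, 0L, sprintf("protein_%d", n_beads))
}

#' Simulate a stopped-flow disassembly time series
#'
#' Species fractions follow the scheme's sequential first-order closed form;
#' each frame is the fraction-weighted sum of species profiles (computed
#' once at the fixed post-mixing solvent composition - the contrast does not
#' change with time) plus Gaussian noise. Ground truth (rates, lag,
#' fractions, species I(0)) is stored in `attr(, "ground_truth")`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param times Frame times, seconds (default: 20 ms cadence over
#'   0.02-60 s).
#' @param sucrose Sucrose weight fraction.
#' @param nacl Post-mixing NaCl concentration, mol/L.
#' @param noise A [noise_model()].
#' @param qgrid q-grid.
#' @param model A [contrast_model()]; by default calibrated so the 50%
#'   sucrose buffer matches the protein at the post-mixing salt (matching
#'   buffers are prepared per condition).
#' @param seed RNG seed (the global RNG state is restored afterwards).
#' @param frame_duration Frame duration, seconds.
#' @return A [saxs_series()] with ground-truth attributes.
#' @export
simulate_disassembly <- function(scheme, times = seq(0.02, 60, by = 0.02),
                                 sucrose = 0, nacl = 1.88,
                                 noise = noise_model(),
                                 qgrid = qgrid_default(),
                                 model = contrast_model(match_salt = nacl),
                                 seed = NULL,
                                 frame_duration = 0.02) {
  if (any(times < 0)) stop("frame times must be >= 0", call. = FALSE)
  fr <- species_fractions(scheme, times)
  Imat <- vapply(scheme$species, species_profile, numeric(length(qgrid)),
                 qgrid = qgrid, sucrose = sucrose, nacl = nacl,
                 model = model)
  frames <- with_seed(seed, purrr::map(seq_along(times), function(ti) {
    I <- as.vector(Imat %*% fr[ti, ])
    nz <- apply_noise_1d(I, noise)
    saxs_profile(qgrid, nz$I, nz$sigma, salt = nacl, sucrose = sucrose,
                 time = times[ti], label = sprintf("frame_%05d", ti))
  }))
  out <- saxs_series(frames, times, frame_duration = frame_duration)
  attr(out, "ground_truth") <- list(
    rates = scheme$rates[is.finite(scheme$rates)],
    lag = scheme$lag,
    species = scheme$species_names,
    fractions = tibble::as_tibble(cbind(time = times, fr)),
    i0_species = vapply(scheme$species, function(sp) {
      sum(vapply(sp, function(cf) {
        sum(bead_weights(cf, sucrose, nacl, model))^2
      }, 0))
    }, 0),
    noise = unclass(noise), seed = seed
  )
  out
}

#' Default salt-to-ensemble mapping for equilibrium titrations
#'
#' Assigns each NaCl concentration a weighted ensemble of pool members,
#' following the titration picture: predominantly wrapped at 0.2 M, roughly
#' half released (mostly asymmetric, ends uncrossed) near 1 M, deeply
#' released at 1.5-1.8 M and essentially free DNA at 2 M.
#'
#' @return A named list (names = NaCl mol/L as character) of tibbles with
#'   columns `name` (pool member) and `weight`.
#' @export
default_salt_mapping <- function() {
  list(
    "0.2" = tibble::tibble(name = "L000_R000", weight = 1),
    "0.5" = tibble::tibble(name = c("L000_R000", "L024_R000"),
                           weight = c(0.85, 0.15)),
    "1" = tibble::tibble(name = c("L073_R012", "L061_R000", "L037_R037"),
                         weight = c(0.55, 0.30, 0.15)),
    "1.5" = tibble::tibble(name = c("L110_R000", "L092_R000", "L073_R024"),
                           weight = c(0.50, 0.30, 0.20)),
    "1.8" = tibble::tibble(name = c("L128_R000", "L110_R000"),
                           weight = c(0.60, 0.40)),
    "2" = tibble::tibble(name = c("L147_R000", "L128_R000"),
                         weight = c(0.90, 0.10))
  )
}

#' Simulate an equilibrium salt series
#'
#' One profile per NaCl concentration: the mapped weighted sum of
#' pool-member Debye profiles plus Gaussian noise. Ground-truth weights are
#' stored per profile (`attr(, "truth_weights")`) and for the series
#' (`attr(, "ground_truth")`).
#'
#' @param salts NaCl concentrations, mol/L.
#' @param sucrose Sucrose weight fraction (0.5 isolates the DNA signal).
#' @param mapping Salt-to-ensemble mapping as in [default_salt_mapping()].
#' @param pool A pool tibble from [generate_pool()] (built if NULL).
#' @param noise A [noise_model()].
#' @param qgrid q-grid.
#' @param model A [contrast_model()], or NULL (default) for per-salt
#'   matched buffers (`contrast_model(match_salt = salt)`).
#' @param seed RNG seed.
#' @return A list of [saxs_profile()] objects, one per salt.
#' @export
simulate_equilibrium_series <- function(salts = c(0.2, 0.5, 1, 1.5, 1.8, 2),
                                        sucrose = 0.5,
                                        mapping = default_salt_mapping(),
                                        pool = NULL,
                                        noise = noise_model(),
                                        qgrid = qgrid_default(),
                                        model = NULL,
                                        seed = NULL) {
  if (is.null(pool)) pool <- generate_pool()
  profs <- with_seed(seed, purrr::map(salts, function(s) {
    model_s <- model %||% contrast_model(match_salt = s)
    map_s <- mapping[[as.character(s)]]
    if (is.null(map_s)) {
      stop(sprintf("no ensemble mapping for salt %g M", s), call. = FALSE)
    }
    if (abs(sum(map_s$weight) - 1) > 1e-9) {
      stop("mapping weights must sum to 1", call. = FALSE)
    }
    idx <- match(map_s$name, pool$name)
    if (anyNA(idx)) stop("mapping names unknown in pool", call. = FALSE)
    I <- purrr::reduce(purrr::map2(idx, map_s$weight, function(i, w) {
      w * debye_profile(pool$conformer[[i]], qgrid, sucrose = sucrose,
                        nacl = s, model = model_s, smear_sigma = 3)$I
    }), `+`)
    nz <- apply_noise_1d(I, noise)
    p <- saxs_profile(qgrid, nz$I, nz$sigma, salt = s, sucrose = sucrose,
                      label = sprintf("eq_%gM", s))
    attr(p, "truth_weights") <- map_s
    p
  }))
  attr(profs, "ground_truth") <- list(salts = salts, mapping = mapping,
                                      noise = unclass(noise), seed = seed)
  profs
}

#' Render a detector image from a 1-D profile
#'
#' Expected counts per pixel are the profile interpolated at each pixel's q,
#' scaled by flux and exposure; counts are Poisson-sampled unless
#' `poisson = FALSE`.
#'
#' @param profile A [saxs_profile()].
#' @param geometry A [reduction_geometry()].
#' @param dims Detector dimensions (pixels).
#' @param exposure Exposure, seconds.
#' @param flux Expected counts per unit profile intensity per second (> 0).
#' @param poisson Sample Poisson noise?
#' @param seed RNG seed.
#' @return A [detector_image()].
#' @export
render_detector_image <- function(profile, geometry, dims = c(195, 487),
                                  exposure = 1, flux = 1, poisson = TRUE,
                                  seed = NULL) {
  if (flux <= 0) stop("flux must be positive", call. = FALSE)
  blank <- detector_image(matrix(0, dims[1], dims[2]), exposure = exposure)
  qmap <- pixel_q_map(blank, geometry)
  expected <- stats::approx(profile$q, profile$I, xout = as.vector(qmap),
                            rule = 2)$y
  expected[as.vector(qmap) < min(profile$q)] <- profile$I[1]
  expected <- matrix(expected * flux * exposure, dims[1], dims[2])
  counts <- if (poisson) {
    with_seed(seed, matrix(stats::rpois(length(expected),
                                        as.vector(expected)),
                           dims[1], dims[2]))
  } else {
    expected
  }
  detector_image(counts, exposure = exposure)
}

#' Write the canonical synthetic fixture bundle
#'
#' Generates and writes, under `dir`: the 32-member pool (PDB bead files and
#' 0%/50%-sucrose profiles), a 6-salt equilibrium series, 601 and 5S
#' stopped-flow series (as directories of `.dat` frames with a JSON
#' manifest), one rendered detector frame with its geometry, and a
#' `manifest.json` recording every piece of ground truth. Deterministic for
#' a fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed driving all randomness.
#' @param n_frames Frames per kinetic series (20 ms cadence).
#' @return Invisibly, the manifest list.
#' @export
fixture_bundle <- function(dir, seed = 1, n_frames = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- generate_pool()
  pdir <- file.path(dir, "pool")
  dir.create(pdir, showWarnings = FALSE)
  for (i in seq_len(nrow(pool))) {
    write_pdb_beads(pool$conformer[[i]],
                    file.path(pdir, paste0(pool$name[i], ".pdb")))
  }
  for (suc in c(0, 0.5)) {
    sdir <- file.path(dir, sprintf("pool_profiles_suc%02d", suc * 100))
    dir.create(sdir, showWarnings = FALSE)
    pp <- pool_profiles(pool, sucrose = suc)
    purrr::walk2(pp$profile, pp$name, function(p, nm) {
      write_dat(p, file.path(sdir, paste0(nm, ".dat")))
    })
  }
  eq <- simulate_equilibrium_series(pool = pool, seed = seed)
  edir <- file.path(dir, "equilibrium")
  dir.create(edir, showWarnings = FALSE)
  purrr::walk(eq, function(p) {
    write_dat(p, file.path(edir, sprintf("eq_%gM.dat", attr(p, "salt"))))
  })

  times <- seq(0.02, by = 0.02, length.out = n_frames)
  s601 <- simulate_disassembly(scheme_601(), times = times, seed = seed + 1)
  s5s <- simulate_disassembly(scheme_5s(), times = times, seed = seed + 2)
  write_series(s601, file.path(dir, "tr_601"))
  write_series(s5s, file.path(dir, "tr_5s"))

  geo <- reduction_geometry(beam_center = c(98, 98))
  img <- render_detector_image(eq[[1]], geo, dims = c(195, 195),
                               flux = 5e-4, seed = seed + 3)
  utils::write.csv(img$counts, file.path(dir, "detector_frame.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(geo), file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    seed = seed,
    pool = pool[, c("name", "released_left", "released_right", "symmetry",
                    "rg", "dmax")],
    equilibrium = purrr::map(eq, function(p) {
      list(salt = attr(p, "salt"), weights = attr(p, "truth_weights"))
    }),
    tr_601 = attr(s601, "ground_truth")[c("rates", "lag", "species",
                                          "i0_species")],
    tr_5s = attr(s5s, "ground_truth")[c("rates", "lag", "species",
                                        "i0_species")],
    detector = list(flux = 5e-4, geometry = unclass(geo))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
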