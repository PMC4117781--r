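#' Coarse-grained conformers of nucleosomal DNA
#'
#' A conformer is a tibble of beads (columns `x`, `y`, `z` in Angstrom and
#' `phase`, one of `"DNA"` or `"PROTEIN"`) carrying metadata attributes:
#' `bp_total`, `released_left`, `released_right` and `name`. DNA is
#' represented by two backbone beads per base pair placed diametrically at
#' `duplex_radius` about the local duplex axis and rotated by the helical
#' twist from one bp to the next, so the duplex-diameter pair distance lands
#' at ~20 Angstrom.
#'
#' @name conformer
#' @keywords internal
NULL

new_conformer <- function(beads, bp_total, released_left, released_right,
                          name) {
  stopifnot(all(c("x", "y", "z", "phase") %in% names(beads)))
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")])))) {
    stop("conformer coordinates must be finite", call. = FALSE)
  }
  out <- tibble::as_tibble(beads)
  attr(out, "bp_total") <- as.integer(bp_total)
  attr(out, "released_left") <- as.integer(released_left)
  attr(out, "released_right") <- as.integer(released_right)
  attr(out, "name") <- name
  class(out) <- c("conformer", class(out))
  out
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer '%s'> %d beads, %d bp, released L=%d R=%d (%s)\n",
              attr(x, "name"), nrow(x), attr(x, "bp_total"),
              attr(x, "released_left"), attr(x, "released_right"),
              classify_symmetry(x)))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

# place the two backbone beads of each bp given centres (n x 3) and local
# orthonormal frame vectors n1, n2 (n x 3 each), with per-bp twist angles
strand_beads <- function(centres, n1, n2, twist_angles, duplex_radius) {
  u <- cos(twist_angles) * n1 + sin(twist_angles) * n2
  rbind(centres + duplex_radius * u, centres - duplex_radius * u)
}

#' Build a straight B-DNA duplex bead model
#'
#' Two beads per base pair, diametrically opposed at `duplex_radius` from a
#' straight axis, rotated by `twist_per_bp` per step. Models the fully
#' released (free) DNA state.
#'
#' @param bp_total Number of base pairs (>= 2).
#' @param params A [helix_params()] object.
#' @param name Conformer name.
#' @return A `conformer` tibble with `2 * bp_total` DNA beads; the end-to-end
#'   axis length is `(bp_total - 1) * rise_per_bp`.
#' @examples
#' free_dna <- build_duplex(149)
#' dmax_of(free_dna) # ~503 Angstrom
#' @export
build_duplex <- function(bp_total, params = helix_params(),
                         name = sprintf("duplex_%dbp", bp_total)) {
  if (bp_total < 2) stop("bp_total must be >= 2", call. = FALSE)
  i <- seq_len(bp_total) - 1
  centres <- cbind(x = 0, y = 0, z = i * params$rise_per_bp)
  n1 <- cbind(rep(1, bp_total), 0, 0)
  n2 <- cbind(0, rep(1, bp_total), 0)
  xyz <- strand_beads(centres, n1, n2, deg2rad(i * params$twist_per_bp),
                      params$duplex_radius)
  beads <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          phase = "DNA")
  new_conformer(beads, bp_total, bp_total, 0L, name)
}

# centres and frame of the full wrapped superhelical path, evaluated at
# angular positions phi (left-handed wind, z advancing by pitch per turn)
superhelix_path <- function(phi, params) {
  R <- params$superhelix_radius
  cp <- params$superhelix_pitch / (2 * pi)
  centres <- cbind(R * cos(phi), -R * sin(phi), cp * phi)
  tangent <- cbind(-R * sin(phi), -R * cos(phi), rep(cp, length(phi)))
  tangent <- tangent / sqrt(rowSums(tangent^2))
  radial <- cbind(cos(phi), -sin(phi), rep(0, length(phi))) # outward, _|_ tangent
  binorm <- cbind(
    tangent[, 2] * radial[, 3] - tangent[, 3] * radial[, 2],
    tangent[, 3] * radial[, 1] - tangent[, 1] * radial[, 3],
    tangent[, 1] * radial[, 2] - tangent[, 2] * radial[, 1]
  )
  list(centres = centres, tangent = tangent, n1 = radial, n2 = binorm)
}

#' Build the fully wrapped nucleosomal DNA model
#'
#' Winds the duplex along a left-handed superhelix (default 1.65 turns of
#' radius 41.9 Angstrom), transporting the local duplex frame along the path.
#' Base pairs are spaced uniformly in arc length along the superhelix.
#'
#' @inheritParams build_duplex
#' @return A `conformer` with `2 * bp_total` DNA beads.
#' @examples
#' ncp_dna <- build_wrapped(147)
#' rg_of(ncp_dna) # ~40-50 Angstrom
#' @export
build_wrapped <- function(bp_total, params = helix_params(),
                          name = sprintf("wrapped_%dbp", bp_total)) {
  if (bp_total < 2) stop("bp_total must be >= 2", call. = FALSE)
  phi_total <- 2 * pi * params$wrapped_turns
  i <- seq_len(bp_total) - 1
  phi <- i * phi_total / (bp_total - 1)
  path <- superhelix_path(phi, params)
  xyz <- strand_beads(path$centres, path$n1, path$n2,
                      deg2rad(i * params$twist_per_bp), params$duplex_radius)
  check_bead_overlap(xyz)
  beads <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          phase = "DNA")
  new_conformer(beads, bp_total, 0L, 0L, name)
}

check_bead_overlap <- function(xyz, min_sep = 1) {
  # nearest-neighbour screen; small models only, called once per build
  d <- stats::dist(xyz)
  if (min(d) < min_sep) {
    stop(sprintf("degenerate geometry: beads closer than %.1f Angstrom", min_sep),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a partially released nucleosomal DNA model
#'
#' Keeps a central wrapped arc of `bp_total - released_left - released_right`
#' base pairs on the superhelical path and appends straight duplex arms that
#' leave tangentially at each release point (rigid composite; the arms do not
#' bend). Release counts of zero reproduce [build_wrapped()]; releasing
#' (nearly) everything reproduces the straight duplex.
#'
#' @inheritParams build_duplex
#' @param released_left,released_right Base pairs released from each end.
#' @return A `conformer` with `2 * bp_total` DNA beads.
#' @examples
#' j_model <- build_released(147, 74, 0) # "J"-shaped asymmetric intermediate
#' dmax_of(j_model) # ~300-350 Angstrom
#' @export
build_released <- function(bp_total, released_left, released_right,
                           params = helix_params(),
                           name = sprintf("L%03d_R%03d", released_left,
                                          released_right)) {
  if (released_left < 0 || released_right < 0) {
    stop("release counts must be non-negative", call. = FALSE)
  }
  if (released_left + released_right > bp_total) {
    stop("released_left + released_right must not exceed bp_total",
         call. = FALSE)
  }
  n_arc <- bp_total - released_left - released_right
  if (n_arc < 2) { # fully (or all-but-one) released: a straight duplex
    c0 <- build_duplex(bp_total, params, name = name)
    attr(c0, "released_left") <- as.integer(released_left)
    attr(c0, "released_right") <- as.integer(bp_total - released_left)
    return(c0)
  }
  if (n_arc == bp_total) {
    w <- build_wrapped(bp_total, params, name = name)
    return(w)
  }
  phi_total <- 2 * pi * params$wrapped_turns
  dphi <- phi_total / (bp_total - 1)
  i_all <- seq_len(bp_total) - 1
  twist <- deg2rad(i_all * params$twist_per_bp)

  # wrapped arc occupies the angular section it holds in the full particle
  i_arc <- released_left:(bp_total - 1 - released_right)
  path <- superhelix_path(i_arc * dphi, params)
  centres <- path$centres
  n1 <- path$n1
  n2 <- path$n2

  if (released_left > 0) {
    p0 <- superhelix_path(released_left * dphi, params)
    steps <- released_left:1
    arm_c <- p0$centres[rep(1, released_left), , drop = FALSE] -
      steps * params$rise_per_bp * p0$tangent[rep(1, released_left), , drop = FALSE]
    centres <- rbind(arm_c, centres)
    n1 <- rbind(p0$n1[rep(1, released_left), , drop = FALSE], n1)
    n2 <- rbind(p0$n2[rep(1, released_left), , drop = FALSE], n2)
  }
  if (released_right > 0) {
    pe <- superhelix_path((bp_total - 1 - released_right) * dphi, params)
    steps <- 1:released_right
    arm_c <- pe$centres[rep(1, released_right), , drop = FALSE] +
      steps * params$rise_per_bp * pe$tangent[rep(1, released_right), , drop = FALSE]
    centres <- rbind(centres, arm_c)
    n1 <- rbind(n1, pe$n1[rep(1, released_right), , drop = FALSE])
    n2 <- rbind(n2, pe$n2[rep(1, released_right), , drop = FALSE])
  }
  xyz <- strand_beads(centres, n1, n2, twist, params$duplex_radius)
  beads <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          phase = "DNA")
  new_conformer(beads, bp_total, released_left, released_right, name)
}

#' Attach a pseudo-histone protein core to a conformer
#'
#' Adds 8 PROTEIN-phase beads arranged on a ring about the superhelix axis,
#' centred in the wrapped region. This is a contrast/I(0) bookkeeping device
#' (total protein volume at octamer scale), not a structural octamer model.
#'
#' @param conf A `conformer`.
#' @param params A [helix_params()] object (locates the superhelix axis).
#' @param n_beads Number of protein beads.
#' @param ring_radius Radius of the protein bead ring, Angstrom.
#' @return The conformer with protein beads appended.
#' @export
with_protein_core <- function(conf, params = helix_params(), n_beads = 8,
                              ring_radius = 15) {
  z_mid <- params$superhelix_pitch * params$wrapped_turns / 2
  ang <- 2 * pi * (seq_len(n_beads) - 1) / n_beads
  core <- tibble::tibble(
    x = ring_radius * cos(ang),
    y = ring_radius * sin(ang),
    z = z_mid + 8 * sin(2 * ang),
    phase = "PROTEIN"
  )
  out <- dplyr::bind_rows(tibble::as_tibble(conf), core)
  new_conformer(out, attr(conf, "bp_total"), attr(conf, "released_left"),
                attr(conf, "released_right"),
                paste0(attr(conf, "name"), "+core"))
}

#' Default release grid for the conformer pool
#'
#' All unordered (left, right) release pairs over seven levels spanning
#' 0 to ~half the DNA, plus four single-ended deep releases up to fully
#' free — 32 members in total after removing mirror duplicates (P(R) cannot
#' distinguish left- from right-end release). For `bp_total` other than 147
#' the levels scale proportionally.
#'
#' @param bp_total Total base pairs.
#' @return A two-column integer matrix of (released_left, released_right).
#' @export
default_release_grid <- function(bp_total = 147) {
  lev <- round(bp_total * c(0, 12, 24, 37, 49, 61, 73) / 147)
  deep <- round(bp_total * c(85, 92, 110, 128, 147) / 147)
  pairs <- expand.grid(L = lev, R = lev)
  # keep unordered pairs that leave at least a 2 bp wrapped arc (the
  # all-but-released double-arm member would duplicate the free duplex)
  pairs <- pairs[pairs$L >= pairs$R & pairs$L + pairs$R < bp_total - 1, ]
  pairs <- rbind(pairs, data.frame(L = deep, R = 0))
  as.matrix(pairs[order(pairs$L + pairs$R, pairs$L), c("L", "R")])
}

#' Specification of a conformer pool
#'
#' @param bp_total Total base pairs per conformer.
#' @param release_grid Two-column matrix of (released_left, released_right)
#'   pairs; defaults to [default_release_grid()] (32 members).
#' @param include_protein_core Attach the pseudo-histone core to members
#'   whose release leaves at least 10 bp wrapped?
#' @return A `pool_spec` list.
#' @export
pool_spec <- function(bp_total = 147,
                      release_grid = default_release_grid(bp_total),
                      include_protein_core = FALSE) {
  release_grid <- as.matrix(release_grid)
  if (ncol(release_grid) && nrow(release_grid)) {
    if (anyDuplicated(release_grid)) {
      stop("invalid pool spec: duplicate release pairs", call. = FALSE)
    }
    if (any(rowSums(release_grid) > bp_total)) {
      stop("invalid pool spec: release pair exceeds bp_total", call. = FALSE)
    }
  }
  structure(list(bp_total = bp_total, release_grid = release_grid,
                 include_protein_core = include_protein_core),
            class = "pool_spec")
}

#' Generate the candidate conformer pool
#'
#' Builds one conformer per release pair in the pool specification. The
#' default pool has 32 members spanning fully wrapped to fully released,
#' with both symmetric and asymmetric partially released states.
#'
#' @param spec A [pool_spec()].
#' @param params A [helix_params()].
#' @return A tibble with one row per member: `name`, `released_left`,
#'   `released_right`, `total_released`, `symmetry`, `rg`, `dmax` and a
#'   `conformer` list-column.
#' @examples
#' pool <- generate_pool()
#' nrow(pool) # 32
#' table(pool$symmetry)
#' @export
generate_pool <- function(spec = pool_spec(), params = helix_params()) {
  g <- spec$release_grid
  if (is.null(g) || nrow(g) == 0) {
    return(tibble::tibble(name = character(), released_left = integer(),
                          released_right = integer(),
                          total_released = integer(), symmetry = character(),
                          rg = double(), dmax = double(),
                          conformer = list()))
  }
  confs <- purrr::map(seq_len(nrow(g)), function(k) {
    cf <- build_released(spec$bp_total, g[k, 1], g[k, 2], params)
    if (spec$include_protein_core &&
        spec$bp_total - g[k, 1] - g[k, 2] >= 10) {
      cf <- with_protein_core(cf, params)
    }
    cf
  })
  nm <- purrr::map_chr(confs, ~ attr(.x, "name"))
  if (anyDuplicated(nm)) stop("invalid pool spec: duplicate names", call. = FALSE)
  tibble::tibble(
    name = nm,
    released_left = g[, 1],
    released_right = g[, 2],
    total_released = g[, 1] + g[, 2],
    symmetry = purrr::map_chr(confs, classify_symmetry),
    rg = purrr::map_dbl(confs, rg_of),
    dmax = purrr::map_dbl(confs, dmax_of),
    conformer = confs
  )
}

#' Classify the release symmetry of a conformer
#'
#' `wrapped` if both ends have released fewer than 10 bp; `free` if the
#' total release is within 10 bp of everything; otherwise `symmetric` when
#' the two ends differ by at most 10 bp and `asymmetric` when they differ
#' by more.
#'
#' @param conf A `conformer`, or `NULL` if `released_left`/`released_right`/
#'   `bp_total` are given directly.
#' @param released_left,released_right,bp_total Release record, read from
#'   `conf` by default.
#' @return One of `"wrapped"`, `"symmetric"`, `"asymmetric"`, `"free"`.
#' @export
classify_symmetry <- function(conf = NULL,
                              released_left = attr(conf, "released_left"),
                              released_right = attr(conf, "released_right"),
                              bp_total = attr(conf, "bp_total")) {
  L <- released_left
  R <- released_right
  if (is.null(L) || is.null(R) || is.null(bp_total)) {
    stop("release counts not recorded", call. = FALSE)
  }
  if (L < 10 && R < 10) return("wrapped")
  if (L + R >= bp_total - 10) return("free")
  if (abs(L - R) <= 10) "symmetric" else "asymmetric"
}

bead_matrix <- function(conf) as.matrix(conf[, c("x", "y", "z")])

#' Radius of gyration of a conformer
#'
#' Root-mean-square distance of beads from their (weighted) centroid.
#'
#' @param conf A `conformer` (or any tibble with x/y/z columns), >= 2 beads.
#' @param weights Optional per-bead weights (e.g. contrast weights);
#'   uniform by default.
#' @return Radius of gyration in Angstrom.
#' @export
rg_of <- function(conf, weights = NULL) {
  xyz <- bead_matrix(conf)
  if (nrow(xyz) < 2) stop("need at least 2 beads", call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(xyz)) else weights
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Maximum intra-particle distance of a conformer
#'
#' @inheritParams rg_of
#' @return Largest pairwise bead distance, Angstrom.
#' @export
dmax_of <- function(conf) {
  xyz <- bead_matrix(conf)
  if (nrow(xyz) < 2) stop("need at least 2 beads", call. = FALSE)
  max(stats::dist(xyz))
}
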