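#' Geometry parameters for coarse-grained nucleosomal DNA
#'
#' Bundles the geometric constants used by the bead-model builders: the
#' nucleosomal superhelix (radius, pitch, number of wrapped turns) and the
#' B-DNA duplex (rise and twist per base pair, backbone radius).
#'
#' Defaults follow canonical nucleosome geometry: the DNA path winds ~1.65
#' left-handed turns around a superhelix of radius 41.9 Angstrom and pitch
#' 25.9 Angstrom per turn. Note that DNA bent onto this path advances about
#' 3.0 Angstrom per bp along the path (shorter than the 3.4 Angstrom straight
#' B-form rise); the wrapped builders therefore space base pairs by arc
#' length, while `rise_per_bp` governs straight segments (free duplex and
#' released arms).
#'
#' @param superhelix_radius Superhelix radius in Angstrom (to the duplex axis).
#' @param superhelix_pitch Superhelix pitch in Angstrom per turn.
#' @param wrapped_turns Number of superhelical turns for a full wrap.
#' @param rise_per_bp Axial rise per base pair for straight DNA, Angstrom.
#' @param duplex_radius Radial distance of the two backbone beads from the
#'   duplex axis, Angstrom. The duplex-diameter signature in P(R) appears at
#'   twice this value.
#' @param twist_per_bp Helical twist per base pair, degrees.
#' @return An object of class `helix_params` (a named list).
#' @examples
#' helix_params()
#' @export
helix_params <- function(superhelix_radius = 41.9,
                         superhelix_pitch = 25.9,
                         wrapped_turns = 1.65,
                         rise_per_bp = 3.4,
                         duplex_radius = 10,
                         twist_per_bp = 34.3) {
  vals <- c(superhelix_radius = superhelix_radius,
            superhelix_pitch = superhelix_pitch,
            wrapped_turns = wrapped_turns,
            rise_per_bp = rise_per_bp,
            duplex_radius = duplex_radius)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all helix_params lengths and wrapped_turns must be finite and > 0",
         call. = FALSE)
  }
  structure(
    list(superhelix_radius = superhelix_radius,
         superhelix_pitch = superhelix_pitch,
         wrapped_turns = wrapped_turns,
         rise_per_bp = rise_per_bp,
         duplex_radius = duplex_radius,
         twist_per_bp = twist_per_bp),
    class = "helix_params"
  )
}

#' @export
print.helix_params <- function(x, ...) {
  cat("<helix_params>\n")
  cat(sprintf("  superhelix: radius %.1f A, pitch %.1f A/turn, %.2f turns\n",
              x$superhelix_radius, x$superhelix_pitch, x$wrapped_turns))
  cat(sprintf("  duplex: rise %.2f A/bp, twist %.1f deg/bp, backbone radius %.1f A\n",
              x$rise_per_bp, x$twist_per_bp, x$duplex_radius))
  invisible(x)
}

# arc length of the full superhelical path
superhelix_arc_length <- function(params) {
  phi_total <- 2 * pi * params$wrapped_turns
  c_pitch <- params$superhelix_pitch / (2 * pi)
  phi_total * sqrt(params$superhelix_radius^2 + c_pitch^2)
}
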