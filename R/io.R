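#' Read and write 3-column scattering profiles
#'
#' The interchange format is plain ASCII: `#`-prefixed header lines carrying
#' `key: value` metadata (salt, sucrose, time, label), then three columns
#' q, I, sigma. Round trips are lossless to the written precision.
#'
#' @param profile A [saxs_profile()].
#' @param path File path.
#' @param digits Significant digits written.
#' @return `read_dat` returns a [saxs_profile()]; `write_dat` its path,
#'   invisibly.
#' @export
write_dat <- function(profile, path, digits = 8) {
  meta <- profile_meta(profile)
  hdr <- c("# nucsaxs scattering profile",
           sprintf("# %s: %s", names(meta),
                   vapply(meta, function(v) {
                     if (is.null(v) || (is.numeric(v) && is.na(v))) "NA"
                     else as.character(v)
                   }, "")),
           "# q I sigma")
  body <- sprintf(paste0("%.", digits, "g %.", digits, "g %.", digits, "g"),
                  profile$q, profile$I, profile$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_dat
#' @export
read_dat <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  meta <- list(salt = NA_real_, sucrose = NA_real_, time = NA_real_,
               label = "")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(salt|sucrose|time|label):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      meta[[key]] <- if (key == "label") val else
        suppressWarnings(as.numeric(val))
    }
  }
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, 0L) != 3)
  if (length(bad)) {
    stop(sprintf("malformed profile row at line %d of %s",
                 which(!startsWith(lines, "#"))[bad[1]], path), call. = FALSE)
  }
  num <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 3,
                byrow = TRUE)
  if (anyNA(num)) {
    stop(sprintf("non-numeric profile value near line %d of %s",
                 which(apply(is.na(num), 1, any))[1], path), call. = FALSE)
  }
  saxs_profile(num[, 1], num[, 2], num[, 3], salt = meta$salt,
               sucrose = meta$sucrose, time = meta$time, label = meta$label)
}

#' Read and write conformers as PDB bead files
#'
#' One HETATM record per bead; chain A carries DNA beads, chain B protein
#' beads. Release metadata is preserved in REMARK records.
#'
#' @param conf A `conformer`.
#' @param path File path.
#' @return `read_pdb_beads` returns a `conformer`; `write_pdb_beads` its
#'   path, invisibly.
#' @export
write_pdb_beads <- function(conf, path) {
  xyz <- bead_matrix(conf)
  n <- nrow(xyz)
  chain <- ifelse(conf$phase == "DNA", "A", "B")
  pdb_xyz <- as.vector(t(xyz))
  bio3d::write.pdb(
    file = path,
    xyz = pdb_xyz,
    type = rep("HETATM", n),
    resno = seq_len(n),
    resid = ifelse(conf$phase == "DNA", "DNB", "PRB"),
    eleno = seq_len(n),
    elety = rep("C", n),
    chain = chain,
    o = rep(1, n),
    b = rep(0, n)
  )
  # prepend provenance remarks (bio3d has no remark interface)
  rec <- c(sprintf("REMARK 900 NUCSAXS NAME %s", attr(conf, "name")),
           sprintf("REMARK 900 NUCSAXS BP_TOTAL %d RELEASED %d %d",
                   attr(conf, "bp_total"), attr(conf, "released_left"),
                   attr(conf, "released_right")),
           readLines(path))
  writeLines(rec, path)
  invisible(path)
}

#' @rdname write_pdb_beads
#' @export
read_pdb_beads <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    stop("no bead records in ", path, call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  beads <- tibble::tibble(
    x = at$x, y = at$y, z = at$z,
    phase = ifelse(at$chain == "B", "PROTEIN", "DNA")
  )
  if (anyNA(beads$x) || anyNA(beads$y) || anyNA(beads$z)) {
    stop("non-numeric coordinates in ", path, call. = FALSE)
  }
  nm <- sub("^REMARK 900 NUCSAXS NAME ", "",
            grep("^REMARK 900 NUCSAXS NAME ", lines, value = TRUE)[1])
  rel <- grep("^REMARK 900 NUCSAXS BP_TOTAL", lines, value = TRUE)[1]
  bp <- L <- R <- NA_integer_
  if (!is.na(rel)) {
    v <- as.integer(strsplit(rel, "\\s+")[[1]][c(5, 7, 8)])
    bp <- v[1]; L <- v[2]; R <- v[3]
  }
  if (is.na(bp)) bp <- sum(beads$phase == "DNA") / 2
  if (is.na(L)) L <- 0L
  if (is.na(R)) R <- 0L
  new_conformer(beads, bp, L, R, if (is.na(nm)) basename(path) else nm)
}

#' Read and write time series as frame directories
#'
#' A series is stored as a directory of `.dat` frame files plus a
#' `series.json` manifest (frame files, times, frame duration).
#'
#' @param ts A [saxs_series()].
#' @param dir Directory path.
#' @return `read_series` returns a [saxs_series()]; `write_series` the
#'   directory, invisibly.
#' @export
write_series <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("frame_%05d.dat", seq_len(nrow(ts)))
  purrr::walk2(ts$profile, files, function(p, f) {
    write_dat(p, file.path(dir, f))
  })
  jsonlite::write_json(
    list(files = files, time = ts$time,
         frame_duration = attr(ts, "frame_duration")),
    file.path(dir, "series.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "series.json"),
                             simplifyVector = TRUE)
  profiles <- purrr::map(file.path(dir, man$files), read_dat)
  saxs_series(profiles, man$time, frame_duration = man$frame_duration)
}
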