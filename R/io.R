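#' Read and write kinetics profiles as CSV
#'
#' Release profiles are `time_h,fraction` tables; permeation profiles are
#' `time_h,conc_ug_ml` and/or `time_h,q_ug` tables. Writers emit plain CSV;
#' readers validate the required columns. Round trips are lossless at
#' double-precision printing (15 significant digits).
#'
#' @param profile A profile tibble.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name profile_io
NULL

#' @rdname profile_io
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @export
read_release_profile <- function(path) {
  validate_release_profile(as_tibble(read.csv(path)))
}

#' @rdname profile_io
#' @export
read_permeation_profile <- function(path) {
  out <- as_tibble(read.csv(path))
  if (!"time_h" %in% names(out) ||
      !any(c("conc_ug_ml", "q_ug") %in% names(out))) {
    abort("permeation CSV needs `time_h` and `conc_ug_ml` or `q_ug`.")
  }
  out
}

#' Read a square chi matrix from CSV
#'
#' Expects species labels as the first row (header) and first column.
#'
#' @param path CSV path.
#' @return A labelled symmetric numeric matrix.
#' @export
read_chi_matrix <- function(path) {
  raw <- read.csv(path, check.names = FALSE)
  labels <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- labels
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    abort("chi matrix row and column labels disagree.")
  }
  m
}

#' Serialise an interaction table
#'
#' Writes `chi.csv` and `a.csv` (square labelled matrices) plus a single
#' JSON document `interactions.json` carrying the matrices and the bridge
#' metadata (temperature, density, reference volume).
#'
#' @param x An `interaction_table`.
#' @param dir Output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_interaction_table <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wmat <- function(m, path) {
    df <- data.frame(species = rownames(m), m, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  }
  wmat(x$chi, file.path(dir, "chi.csv"))
  wmat(x$a, file.path(dir, "a.csv"))
  json_path <- file.path(dir, "interactions.json")
  jsonlite::write_json(
    list(species = x$species, chi = x$chi, a = x$a, temp = x$temp,
         rho = x$rho, v_ref = x$v_ref),
    json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(json_path)
}

#' Read an interaction table from its JSON serialisation
#'
#' @param path Path to `interactions.json` written by
#'   [write_interaction_table()].
#' @return An `interaction_table`.
#' @export
read_interaction_table <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_interaction_table(doc$species, matrix(doc$chi, nrow = length(doc$species)),
                          temp = doc$temp, rho = doc$rho, v_ref = doc$v_ref)
}

#' Write a bead configuration as extended XYZ
#'
#' One frame per call: a count line, a comment line carrying
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"` and the step counter, then
#' `species x y z` per bead. Append frames to build a trajectory file.
#'
#' @param state A `dpd_state`.
#' @param path Output path.
#' @param append Append as an extra frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, append = FALSE) {
  n <- nrow(state$positions)
  b <- state$box
  header <- c(
    as.character(n),
    sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" step=%d', b[1], b[2], b[3],
            state$step_count)
  )
  rows <- sprintf("%s %.10g %.10g %.10g", state$species,
                  state$positions[, 1], state$positions[, 2],
                  state$positions[, 3])
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read the first frame of an extended XYZ file
#'
#' @param path XYZ path written by [write_xyz()].
#' @return A `dpd_state` with zero velocities and no bonds.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  lat <- regmatches(lines[2], regexpr('Lattice="[^"]*"', lines[2]))
  nums <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                              " ")[[1]])
  box <- nums[c(1, 5, 9)]
  step <- as.integer(sub(".*step=(\\d+).*", "\\1", lines[2]))
  parts <- strsplit(lines[3:(2 + n)], " +")
  species <- vapply(parts, `[[`, "", 1)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  new_dpd_state(pos, matrix(0, n, 3), species,
                bonds = matrix(integer(0), 0, 2), box = box,
                step_count = step)
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' @param surface An `iso_surface` (or list with `vertices` and `faces`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(surface, path) {
  v <- sprintf("v %.8g %.8g %.8g", surface$vertices[, 1],
               surface$vertices[, 2], surface$vertices[, 3])
  f <- sprintf("f %d %d %d", surface$faces[, 1], surface$faces[, 2],
               surface$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}
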