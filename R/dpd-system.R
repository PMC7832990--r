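#' DPD run parameters
#'
#' Reduced-unit parameter set for the Groot-Warren engine. The cutoff
#' `rc = 1` defines the length unit and all beads carry reduced mass 1;
#' `kbt = 1` is the reduced temperature. The random-force strength is tied
#' to the dissipative strength by the fluctuation-dissipation relation
#' `sigma^2 = 2 gamma kbt` and is always derived, never set directly.
#'
#' @param gamma Dissipative (friction) strength, reduced units. Default 4.5,
#'   the standard DPD choice.
#' @param dt Integration timestep, reduced time. Default 0.04.
#' @param lambda Velocity-prediction mixing factor of the modified
#'   velocity-Verlet scheme. Default 0.65. Irrelevant when `gamma = 0`
#'   (the scheme then reduces to plain velocity-Verlet).
#' @param spring_c Harmonic (zero rest length) bond constant for bead-spring
#'   chains, reduced units. Default 4.0.
#' @param kbt Reduced temperature. Default 1.
#' @param seed Integer seed for the engine's own deterministic noise stream.
#' @param time_scale Optional physical time per reduced time unit (e.g.
#'   picoseconds); recorded for reporting only, never used by the engine.
#' @return A `dpd_params` object.
#' @export
dpd_params <- function(gamma = 4.5, dt = 0.04, lambda = 0.65, spring_c = 4,
                       kbt = 1, seed = 1L, time_scale = NULL) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (gamma < 0) abort("`gamma` must be non-negative.")
  if (spring_c < 0) abort("`spring_c` must be non-negative.")
  if (kbt <= 0) abort("`kbt` must be positive.")
  p <- list(rc = 1, kbt = kbt, gamma = gamma,
            sigma = sqrt(2 * gamma * kbt), dt = dt, lambda = lambda,
            spring_c = spring_c, seed = as.integer(seed),
            time_scale = time_scale)
  stopifnot(abs(p$sigma^2 - 2 * p$gamma * p$kbt) < 1e-12)
  structure(p, class = "dpd_params")
}

new_dpd_state <- function(positions, velocities, species, bonds, box,
                          step_count = 0L) {
  structure(
    list(positions = positions, velocities = velocities,
         species = species, bonds = bonds, box = as.numeric(box),
         step_count = as.integer(step_count)),
    class = "dpd_state"
  )
}

#' @export
print.dpd_state <- function(x, ...) {
  cat("<dpd_state> ", nrow(x$positions), " beads, ", nrow(x$bonds),
      " bonds, box ", paste(format(x$box), collapse = " x "),
      ", step ", x$step_count, "\n", sep = "")
  print(table(x$species))
  invisible(x)
}

#' Beads of a simulation state as a tibble
#'
#' @param x A `dpd_state`.
#' @param ... Unused.
#' @return A tibble with one row per bead: `bead`, `species`, `x`, `y`, `z`,
#'   `vx`, `vy`, `vz`.
#' @export
tidy.dpd_state <- function(x, ...) {
  tibble(
    bead = seq_len(nrow(x$positions)),
    species = x$species,
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
    vx = x$velocities[, 1], vy = x$velocities[, 2], vz = x$velocities[, 3]
  )
}

validate_dpd_state <- function(state) {
  n <- nrow(state$positions)
  if (length(state$box) != 3 || any(state$box <= 2)) {
    abort("box must have three edges, each > 2 rc.")
  }
  if (nrow(state$velocities) != n || length(state$species) != n) {
    abort("positions, velocities and species must agree in length.")
  }
  if (nrow(state$bonds) > 0 &&
      (max(state$bonds) > n || min(state$bonds) < 1)) {
    abort("bond indices out of range.")
  }
  invisible(state)
}

#' Build an initial simulation state from molecule counts
#'
#' Places molecules at uniform-random positions in a periodic box. Chain
#' molecules (beads-per-molecule > 1) grow as random walks with a fixed step
#' of 0.7 rc from a random first bead, wrapped periodically, with
#' consecutive beads bonded; 1-bead molecules are free beads. Velocities are
#' drawn from the Maxwell-Boltzmann distribution at `kbt` and shifted to
#' zero net momentum. Deterministic: the same `seed` reproduces the state
#' bit for bit.
#'
#' @param counts A data frame with columns `component`, `n_molecules` and
#'   `blocks` (chain spec such as `"A:5;B:16"`), e.g. the output of
#'   [bead_counts_from_formulation()] joined with the formulation's `blocks`.
#' @param box Numeric length-3 (or scalar, recycled) box edge lengths in rc.
#' @param seed Integer seed.
#' @param kbt Reduced temperature for the initial velocities.
#' @return A `dpd_state`.
#' @examples
#' build_system(tibble::tibble(component = "water", n_molecules = 100,
#'                             blocks = "water:1"), box = 5, seed = 1)
#' @export
build_system <- function(counts, box, seed, kbt = 1) {
  counts <- as_tibble(counts)
  need <- c("component", "n_molecules", "blocks")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")))
  }
  counts <- filter(counts, .data$n_molecules > 0)
  if (nrow(counts) == 0 || sum(counts$n_molecules) == 0) {
    abort("empty system: no molecules to place.")
  }
  box <- rep(as.numeric(box), length.out = 3)
  if (any(box <= 2)) abort("box edges must exceed 2 rc.")

  withr::with_seed(as.integer(seed), {
    pos_list <- list()
    sp_list <- list()
    bond_list <- list()
    offset <- 0L
    step_len <- 0.7
    for (k in seq_len(nrow(counts))) {
      chain <- parse_blocks(counts$blocks[k])
      nb <- length(chain)
      nm <- counts$n_molecules[k]
      for (m in seq_len(nm)) {
        p <- matrix(0, nb, 3)
        p[1, ] <- runif(3) * box
        if (nb > 1) {
          # random-walk growth at bond-length spacing
          dirs <- matrix(rnorm(3 * (nb - 1)), ncol = 3)
          dirs <- dirs / sqrt(rowSums(dirs^2))
          for (i in 2:nb) p[i, ] <- p[i - 1, ] + step_len * dirs[i - 1, ]
          p <- p %% matrix(box, nb, 3, byrow = TRUE)
          bond_list[[length(bond_list) + 1L]] <-
            cbind(offset + 1:(nb - 1), offset + 2:nb)
        }
        pos_list[[length(pos_list) + 1L]] <- p
        sp_list[[length(sp_list) + 1L]] <- chain
        offset <- offset + nb
      }
    }
    positions <- do.call(rbind, pos_list)
    species <- unlist(sp_list)
    bonds <- if (length(bond_list)) do.call(rbind, bond_list) else
      matrix(integer(0), 0, 2)
    n <- nrow(positions)
    velocities <- matrix(rnorm(3 * n, sd = sqrt(kbt)), ncol = 3)
    velocities <- sweep(velocities, 2, colMeans(velocities))
    new_dpd_state(positions, velocities, species,
                  bonds = bonds, box = box)
  })
}

#' Instantaneous kinetic temperature
#'
#' Reduced kinetic temperature `sum(m v^2) / (3N - 3)` with m = 1; the three
#' subtracted degrees of freedom account for the conserved zero total
#' momentum.
#'
#' @param state A `dpd_state`.
#' @return Reduced temperature.
#' @export
kinetic_temperature <- function(state) {
  n <- nrow(state$positions)
  if (n < 2) abort("kinetic temperature needs at least 2 beads.")
  sum(state$velocities^2) / (3 * n - 3)
}
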