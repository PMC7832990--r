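# map bead species labels onto interaction-table row indices (0-based)
species_codes <- function(state, interaction_table) {
  codes <- match(state$species, interaction_table$species)
  if (anyNA(codes)) {
    missing <- unique(state$species[is.na(codes)])
    abort(paste0("species not in interaction table: ",
                 paste(missing, collapse = ", ")))
  }
  as.integer(codes - 1L)
}

empty_bonds <- function() matrix(integer(0), 0, 2)

#' Non-bonded DPD pair forces
#'
#' Conservative soft repulsion `a_ij (1 - r/rc) rhat` inside the cutoff,
#' plus the
#' pairwise thermostat: dissipative `-gamma w(r)^2 (rhat . v_ij) rhat` and,
#' optionally, random `sigma w(r) theta_ij rhat / sqrt(dt)` with symmetric
#' per-pair noise (`theta_ij = theta_ji`), so all contributions are pairwise
#' antisymmetric and total force sums to zero.
#'
#' @param state A `dpd_state`.
#' @param interaction_table An [build_interaction_table()] result covering
#'   every bead species in `state`.
#' @param params A [dpd_params()] object.
#' @param include_random Include the random force (default `FALSE`, so the
#'   result is deterministic).
#' @param brute Use the all-pairs reference evaluation instead of the cell
#'   list.
#' @return An N x 3 matrix of forces in reduced units.
#' @export
pair_forces <- function(state, interaction_table, params = dpd_params(),
                        include_random = FALSE, brute = FALSE) {
  validate_dpd_state(state)
  codes <- species_codes(state, interaction_table)
  res <- dpd_forces_cpp(state$positions, state$velocities, codes,
                        interaction_table$a, empty_bonds(), state$box,
                        params$gamma, params$sigma, params$dt,
                        spring_c = 0, random = include_random,
                        seed = params$seed + state$step_count,
                        brute = brute)
  res$forces
}

#' Harmonic bond forces
#'
#' Zero-rest-length springs `F = -C r` along each bond, with the
#' minimum-image convention across periodic boundaries; antisymmetric per
#' bond.
#'
#' @inheritParams pair_forces
#' @return An N x 3 matrix of forces.
#' @export
bond_forces <- function(state, params = dpd_params()) {
  validate_dpd_state(state)
  n <- nrow(state$positions)
  zero_a <- matrix(0, 1, 1)
  res <- dpd_forces_cpp(state$positions, state$velocities,
                        integer(n), zero_a,
                        bonds_for_cpp(state$bonds), state$box,
                        gamma = 0, sigma = 0, dt = params$dt,
                        spring_c = params$spring_c, random = FALSE,
                        seed = 0, brute = TRUE)
  res$forces
}

bonds_for_cpp <- function(bonds) {
  b <- matrix(as.integer(bonds - 1L), ncol = 2)
  storage.mode(b) <- "integer"
  b
}

#' Advance a DPD state by one timestep
#'
#' One step of the modified velocity-Verlet scheme: velocities are predicted
#' with mixing factor `lambda` for the dissipative force, positions advanced
#' and re-wrapped, forces recomputed, velocities corrected with the mean of
#' old and new forces. With `gamma = 0` this is plain velocity-Verlet.
#'
#' @inheritParams pair_forces
#' @return The updated `dpd_state` (step counter incremented).
#' @export
integrate_step <- function(state, interaction_table, params = dpd_params()) {
  run_simulation(state, interaction_table, params, n_steps = 1,
                 snapshot_every = 1)$state
}

#' Run a DPD simulation
#'
#' Integrates `n_steps` timesteps, logging kinetic temperature, potential
#' energy and net-momentum magnitude every `snapshot_every` steps.
#' Deterministic: the same state, parameters and seed reproduce the
#' trajectory bit for bit. The random-force noise stream is seeded from
#' `params$seed` plus the state's step counter, so consecutive
#' [integrate_step()] calls reproduce a single [run_simulation()] call.
#'
#' @inheritParams pair_forces
#' @param n_steps Number of timesteps (>= 1).
#' @param snapshot_every Logging/snapshot interval in steps.
#' @param keep_snapshots Keep bead positions at every snapshot (memory), not
#'   just the final state.
#' @return A `dpd_trajectory`: list with the final `state`, a `log` tibble
#'   (`step`, `temperature`, `epot`, `net_momentum`), `snapshots` (list of
#'   position matrices if requested) and the `params` used.
#' @export
run_simulation <- function(state, interaction_table, params = dpd_params(),
                           n_steps, snapshot_every = 1000,
                           keep_snapshots = FALSE) {
  if (n_steps < 1) abort("`n_steps` must be >= 1.")
  validate_dpd_state(state)
  codes <- species_codes(state, interaction_table)
  res <- dpd_run_cpp(state$positions, state$velocities, codes,
                     interaction_table$a, bonds_for_cpp(state$bonds),
                     state$box, params$dt, params$gamma, params$sigma,
                     params$lambda, params$spring_c,
                     as.integer(n_steps), as.integer(snapshot_every),
                     seed = params$seed + state$step_count,
                     keep_snapshots = keep_snapshots)
  out_state <- new_dpd_state(res$positions, res$velocities, state$species,
                             state$bonds, state$box,
                             step_count = state$step_count + n_steps)
  structure(
    list(state = out_state, log = as_tibble(res$log),
         snapshots = res$snapshots, params = params,
         species = state$species),
    class = "dpd_trajectory"
  )
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat("<dpd_trajectory> ", nrow(x$state$positions), " beads, ",
      max(x$log$step), " steps logged, final T* = ",
      signif(tail(x$log$temperature, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Per-snapshot log of a trajectory
#'
#' @param x A `dpd_trajectory`.
#' @param ... Unused.
#' @return The log tibble: `step`, `temperature`, `epot`, `net_momentum`.
#' @export
tidy.dpd_trajectory <- function(x, ...) x$log

#' @export
glance.dpd_trajectory <- function(x, ...) {
  tibble(
    n_beads = nrow(x$state$positions),
    n_bonds = nrow(x$state$bonds),
    steps = x$state$step_count,
    mean_temperature = mean(x$log$temperature),
    final_temperature = tail(x$log$temperature, 1),
    max_net_momentum = max(x$log$net_momentum)
  )
}

#' @export
autoplot.dpd_trajectory <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step,
                                           y = .data$temperature)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$params$kbt, linetype = 2) +
    ggplot2::labs(x = "step", y = "kinetic temperature (reduced)")
}
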