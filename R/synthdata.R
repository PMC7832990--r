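#' Synthetic drug-release profile
#'
#' Generates a release curve from one of the three empirical laws with
#' additive Gaussian noise on the fractions, clipped to \[0, 1.05\]
#' (clipping is a deliberate boundary distortion; use `noise_sd = 0` for
#' exact curves). The `"reference_gel"` preset reproduces the sustained
#' release of the GMO lamellar gel, a Ritger-Peppas curve interpolating its
#' two characteristic points exactly: 10% released at 0.5 h and 67% at 7 h
#' (exponent n = log(6.7)/log(14) ~ 0.72, erosion-dominated release).
#'
#' @param model `"zero_order"`, `"higuchi"` or `"ritger_peppas"`.
#' @param k Release rate constant (h^-n).
#' @param n Release exponent (used by `ritger_peppas`; forced to 1 and 0.5
#'   by the other two laws).
#' @param times Sampling times, h (positive, increasing).
#' @param noise_sd SD of the additive Gaussian noise on fractions.
#' @param seed Integer seed (mandatory for noisy draws).
#' @param preset `NULL` or `"reference_gel"`; a preset overrides `model`,
#'   `k` and `n`.
#' @return A release-profile tibble (`time_h`, `fraction`) with attributes
#'   `model`, `k`, `n`, `provenance` (`"synthetic"` or `"reference"`).
#' @examples
#' gen_release(preset = "reference_gel", seed = 1)
#' @export
gen_release <- function(model = c("ritger_peppas", "zero_order", "higuchi"),
                        k = 0.2, n = 0.5,
                        times = c(0.25, 0.5, 1, 2, 3, 4, 5, 6, 7, 8),
                        noise_sd = 0, seed, preset = NULL) {
  provenance <- "synthetic"
  if (!is.null(preset)) {
    if (!identical(preset, "reference_gel")) {
      abort(paste0("unknown preset: '", preset, "'"))
    }
    # Ritger-Peppas curve through (0.5 h, 0.10) and (7 h, 0.67)
    model <- "ritger_peppas"
    n <- log(0.67 / 0.10) / log(7 / 0.5)
    k <- 0.10 / 0.5^n
    if (!any(times == 0.5) || !any(times == 7)) {
      times <- sort(union(times, c(0.5, 7)))
    }
    provenance <- "reference"
  } else {
    model <- match.arg(model)
  }
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be positive and strictly increasing.")
  }
  n_eff <- switch(model, zero_order = 1, higuchi = 0.5, ritger_peppas = n)
  fraction <- k * times^n_eff
  if (noise_sd > 0) {
    if (missing(seed)) abort("`seed` is mandatory for noisy generation.")
    fraction <- withr::with_seed(as.integer(seed), {
      fraction + rnorm(length(times), sd = noise_sd)
    })
    fraction <- pmin(pmax(fraction, 0), 1.05)
  }
  out <- tibble(time_h = times, fraction = fraction)
  structure(out, model = model, k = k, n = n_eff, provenance = provenance,
            class = class(out))
}

#' Synthetic Franz-cell permeation profile
#'
#' Generates cumulative permeated amounts with a lag phase followed by a
#' linear steady state, `Q(t) = max(0, Jss * area * (t - lag))`, plus
#' additive Gaussian noise. Two presets return the reference corneal
#' permeation triples verbatim (cumulative micrograms at 3, 5 and 11 h):
#' `"reference_gel"` gives (412, 845, 1557) for the lamellar gel and
#' `"reference_suspension"` gives (59, 213, 807) for the hyaluronic-acid
#' suspension comparator.
#'
#' @param jss Steady-state flux, ug/cm^2/h (> 0).
#' @param lag Lag time, h (>= 0).
#' @param area Diffusion area, cm^2. Default 0.5.
#' @param times Sampling times, h. Default the 7-point Franz-cell schedule
#'   1, 3, 5, 7, 11, 19, 24 h.
#' @param noise_sd SD of additive Gaussian noise on Q, ug.
#' @param seed Integer seed (mandatory for noisy draws).
#' @param preset `NULL`, `"reference_gel"` or `"reference_suspension"`.
#' @return A permeation tibble (`time_h`, `q_ug`) with attributes `area` and
#'   `provenance`.
#' @export
gen_permeation <- function(jss = 100, lag = 0, area = 0.5,
                           times = c(1, 3, 5, 7, 11, 19, 24),
                           noise_sd = 0, seed, preset = NULL) {
  if (!is.null(preset)) {
    pts <- switch(preset,
      reference_gel = tibble(time_h = c(3, 5, 11),
                             q_ug = c(412, 845, 1557)),
      reference_suspension = tibble(time_h = c(3, 5, 11),
                                    q_ug = c(59, 213, 807)),
      abort(paste0("unknown preset: '", preset, "'"))
    )
    return(structure(pts, area = area, provenance = "reference",
                     class = class(pts)))
  }
  if (jss <= 0) abort("`jss` must be positive.")
  if (lag < 0) abort("`lag` must be non-negative.")
  q <- pmax(0, jss * area * (times - lag))
  if (noise_sd > 0) {
    if (missing(seed)) abort("`seed` is mandatory for noisy generation.")
    q <- withr::with_seed(as.integer(seed), {
      pmax(0, q + rnorm(length(times), sd = noise_sd))
    })
  }
  out <- tibble(time_h = times, q_ug = q)
  structure(out, area = area, provenance = "synthetic", class = class(out))
}

#' Hand-built lamellar bead configuration
#'
#' Places beads in alternating slabs of a given period along z: each period
#' is split into two half-slabs assigned the two entries of
#' `species_pattern`, and beads are distributed uniformly inside their
#' slabs. Used as the analytic oracle for the structure factor: a species
#' occupying every other half-slab is a square-wave density with
#' fundamental peak at `q = 2 pi / period` and odd harmonics.
#'
#' @param box Box edge (scalar or length 3), rc.
#' @param period Lamellar repeat distance along z; must divide the z edge.
#' @param species_pattern Length-2 character vector of alternating species.
#' @param beads Total bead count (split evenly between the two species).
#' @param seed Integer seed.
#' @return A `dpd_state` with zero velocities and no bonds.
#' @export
gen_lamellar_config <- function(box = 20, period = 5,
                                species_pattern = c("A", "B"),
                                beads = 2000, seed = 1) {
  box <- rep(as.numeric(box), length.out = 3)
  if (abs(box[3] / period - round(box[3] / period)) > 1e-9) {
    abort("`period` must divide the z box edge.")
  }
  if (length(species_pattern) != 2) {
    abort("`species_pattern` must have exactly 2 entries.")
  }
  n_periods <- round(box[3] / period)
  half <- period / 2
  withr::with_seed(as.integer(seed), {
    n1 <- ceiling(beads / 2)
    n2 <- beads - n1
    place <- function(n_sp, phase) {
      # uniform in the union of this species' half-slabs
      slab <- sample.int(n_periods, n_sp, replace = TRUE) - 1
      z <- slab * period + phase + runif(n_sp) * half
      cbind(runif(n_sp) * box[1], runif(n_sp) * box[2], z)
    }
    pos <- rbind(place(n1, 0), place(n2, half))
    species <- c(rep(species_pattern[1], n1), rep(species_pattern[2], n2))
    new_dpd_state(pos, matrix(0, beads, 3), species,
                  bonds = matrix(integer(0), 0, 2), box = box)
  })
}

#' Small amphiphile/solvent DPD fixture
#'
#' Builds a reproducible test system of A5-B16 bead-spring amphiphiles
#' (the GMO coarse-graining: 5 head beads, 16 tail beads) in water, with
#' the bridged interaction table of the reference gel system.
#'
#' @param n_chains Number of 21-bead amphiphile chains.
#' @param n_solvent Number of water beads.
#' @param box Box edge (scalar or length 3), rc.
#' @param seed Integer seed.
#' @return A list with `state` (a `dpd_state`) and `interaction_table`.
#' @examples
#' fx <- gen_dpd_fixture(10, 500, box = 10, seed = 1)
#' nrow(fx$state$positions) # 710
#' @export
gen_dpd_fixture <- function(n_chains, n_solvent, box = 10, seed = 1) {
  counts <- tibble(
    component = c("gmo", "water"),
    n_molecules = c(n_chains, n_solvent),
    blocks = c("A:5;B:16", "water:1")
  )
  counts <- filter(counts, .data$n_molecules > 0)
  state <- build_system(counts, box = box, seed = seed)
  list(state = state, interaction_table = rolg_interaction_table())
}
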