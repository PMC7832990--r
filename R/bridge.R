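#' Flory-Huggins interaction parameter from solubility parameters
#'
#' For a non-polar pair without specific interactions, the interaction
#' parameter follows from the solubility-parameter difference:
#' \deqn{\chi_{ij} = (\delta_i - \delta_j)^2 V_{ref} / (R T)}
#' with \eqn{\delta} in (J/cm^3)^0.5, `v_ref` in cm^3/mol and `temp` in K, so
#' the result is dimensionless. The function is vectorised and symmetric in
#' `delta_i`, `delta_j`, and its result is non-negative, zero only for equal
#' solubility parameters.
#'
#' @param delta_i,delta_j Solubility parameters, (J/cm^3)^0.5.
#' @param v_ref Reference (bead) molar volume, cm^3/mol. Defaults to 18, the
#'   molar volume of water, the smallest bead in the GMO/water coarse-graining.
#' @param temp Temperature, K. Defaults to 328 K (55 degrees C), the
#'   temperature of the parent atomistic simulations.
#' @return Dimensionless chi value(s).
#' @examples
#' chi_from_solubility(43.5, 16.2) # water / lipid tail
#' @export
chi_from_solubility <- function(delta_i, delta_j, v_ref = 18, temp = 328) {
  if (any(temp <= 0)) abort("`temp` must be positive (Kelvin).")
  if (any(v_ref <= 0)) abort("`v_ref` must be positive (cm^3/mol).")
  if (any(delta_i < 0) || any(delta_j < 0)) {
    abort("solubility parameters must be non-negative.")
  }
  (delta_i - delta_j)^2 * v_ref / (.R_GAS * temp)
}

#' Flory-Huggins interaction parameter from mixing energies
#'
#' For polar pairs or pairs with specific interactions (hydrogen bonding),
#' chi is estimated from cohesive-energy densities of the pure components and
#' of their mixture:
#' \deqn{\Delta E_{mix} = \Phi_i (E_{coh}/V)_i + \Phi_j (E_{coh}/V)_j -
#'       (E_{coh}/V)_{mix}, \qquad \chi_{ij} = \Delta E_{mix} V_{ref}/(R T).}
#' Unlike the solubility-parameter route this may be negative (net
#' attraction, e.g. hydrogen-bonded pairs).
#'
#' @param ced_i,ced_j,ced_mix Cohesive-energy densities of component i,
#'   component j and the mixture, J/cm^3.
#' @param phi_i,phi_j Volume fractions of the two components; must sum to 1.
#' @inheritParams chi_from_solubility
#' @return Dimensionless chi.
#' @export
chi_from_mixing_energy <- function(ced_i, ced_j, ced_mix, phi_i, phi_j,
                                   v_ref = 18, temp = 328) {
  if (any(temp <= 0)) abort("`temp` must be positive (Kelvin).")
  if (any(v_ref <= 0)) abort("`v_ref` must be positive (cm^3/mol).")
  if (any(abs(phi_i + phi_j - 1) > 1e-9)) {
    abort("volume fractions `phi_i` + `phi_j` must sum to 1.")
  }
  if (!all(is.finite(c(ced_i, ced_j, ced_mix)))) {
    abort("cohesive-energy densities must be finite.")
  }
  de_mix <- phi_i * ced_i + phi_j * ced_j - ced_mix
  de_mix * v_ref / (.R_GAS * temp)
}

#' Map Flory-Huggins chi to a DPD repulsion parameter
#'
#' The linear bridge between atomistic thermodynamics and the DPD
#' conservative force, calibrated at reduced bead density rho = 5 and
#' T = 328 K: \deqn{a_{ij} = 16.5 + 1.45\,\chi_{ij}.}
#' Like species (chi = 0) get the baseline a = 16.5.
#'
#' @param chi Dimensionless Flory-Huggins parameter(s).
#' @return Repulsion parameter(s) in DPD reduced units.
#' @export
aij_from_chi <- function(chi) {
  if (!all(is.finite(chi))) abort("`chi` must be finite.")
  16.5 + 1.45 * chi
}

#' Invert the chi-to-a bridge
#'
#' @param a DPD repulsion parameter(s), reduced units.
#' @return chi value(s) such that `aij_from_chi(chi)` reproduces `a`.
#' @export
chi_from_aij <- function(a) {
  if (!all(is.finite(a))) abort("`a` must be finite.")
  (a - 16.5) / 1.45
}

#' Assemble a DPD interaction table from a chi matrix
#'
#' Validates the chi matrix (symmetric, zero diagonal) and applies
#' [aij_from_chi()] elementwise; the diagonal gets the like-species baseline
#' a = 16.5.
#'
#' @param species Character vector of species labels, in bead-species order.
#' @param chi Square numeric matrix of Flory-Huggins parameters over
#'   `species`; symmetric with zero diagonal.
#' @param temp Temperature in K recorded with the table.
#' @param rho Reduced bead density at which the bridge was calibrated.
#' @param v_ref Reference volume recorded with the table, cm^3/mol.
#' @return An `interaction_table` object with fields `species`, `chi`, `a`,
#'   `temp`, `rho`, `v_ref`.
#' @examples
#' it <- build_interaction_table(c("water", "tail"),
#'                               matrix(c(0, 5.1, 5.1, 0), 2))
#' it$a
#' @export
build_interaction_table <- function(species, chi, temp = 328, rho = 5,
                                    v_ref = 18) {
  species <- as.character(species)
  n <- length(species)
  if (anyDuplicated(species)) abort("species labels must be unique.")
  chi <- as.matrix(chi)
  if (!is.numeric(chi) || nrow(chi) != n || ncol(chi) != n) {
    abort("`chi` must be a numeric matrix matching `species` in size.")
  }
  if (!all(is.finite(chi))) abort("`chi` must be finite.")
  if (max(abs(chi - t(chi))) > 1e-12) abort("`chi` must be symmetric.")
  if (max(abs(diag(chi))) > 1e-12) abort("`chi` must have a zero diagonal.")
  dimnames(chi) <- list(species, species)
  a <- aij_from_chi(chi)
  diag(a) <- 16.5
  structure(
    list(species = species, chi = chi, a = a,
         temp = temp, rho = rho, v_ref = v_ref),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", length(x$species), " species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  bridge a = 16.5 + 1.45 chi  (rho = ", x$rho, ", T = ", x$temp,
      " K, V_ref = ", x$v_ref, " cm^3/mol)\n", sep = "")
  print(round(x$a, 2))
  invisible(x)
}

#' Tidy an interaction table into pairwise rows
#'
#' @param x An `interaction_table`.
#' @param ... Unused.
#' @return A tibble with one row per unordered species pair (upper triangle,
#'   diagonal included): `species_i`, `species_j`, `chi`, `a`.
#' @export
tidy.interaction_table <- function(x, ...) {
  idx <- which(upper.tri(x$chi, diag = TRUE), arr.ind = TRUE)
  tibble(
    species_i = x$species[idx[, 1]],
    species_j = x$species[idx[, 2]],
    chi = x$chi[idx],
    a = x$a[idx]
  )
}

#' Check printed repulsion parameters against the bridge
#'
#' Compares reported `a` values with the value recomputed from chi via
#' [aij_from_chi()] at one-decimal rounding, flagging rows that are
#' internally inconsistent with the linear bridge.
#'
#' @param pairs A data frame with columns `chi` and `a_printed` (one row per
#'   species pair), e.g. [rolg_chi_pairs()].
#' @return The input as a tibble with `a_recomputed` and logical `consistent`
#'   columns.
#' @export
check_bridge_consistency <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("chi", "a_printed") %in% names(pairs))) {
    abort("`pairs` needs columns `chi` and `a_printed`.")
  }
  pairs |>
    mutate(
      a_recomputed = round(aij_from_chi(.data$chi), 1),
      consistent = abs(.data$a_recomputed - .data$a_printed) < 0.05
    )
}
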