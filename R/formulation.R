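#' Reference GMO gel formulation
#'
#' The resveratrol-loaded ocular lamellar gel (ROLG) recipe: resveratrol
#' 42 mg dissolved in ethanol 0.6 g, mixed with GMO 6 g and water 3 g.
#' Bead topology follows the coarse-graining used throughout the package:
#' water = 1 bead, ethanol = 3-bead chain, resveratrol = 5-bead chain, GMO =
#' 21-bead chain of 5 head (A) beads then 16 tail (B) beads.
#'
#' @return A tibble with columns `component`, `mass_g`, `molar_mass`,
#'   `beads_per_molecule`, `blocks` (bead-species chain spec, e.g.
#'   `"A:5;B:16"`), and logical `is_drug`.
#' @export
rolg_formulation <- function() {
  tibble(
    component = c("gmo", "ethanol", "water", "resveratrol"),
    mass_g = c(6, 0.6, 3, 0.042),
    molar_mass = c(356.5, 46.07, 18.02, 228.25),
    beads_per_molecule = c(21L, 3L, 1L, 5L),
    blocks = c("A:5;B:16", "ethanol:3", "water:1", "resveratrol:5"),
    is_drug = c(FALSE, FALSE, FALSE, TRUE)
  )
}

#' Bead-species reference data for the GMO gel system
#'
#' Solubility parameters (from parent atomistic simulations at 328 K) for
#' the five bead species of the coarse-grained gel: water, ethanol,
#' resveratrol, and the GMO head (A, glycerol + carboxyl) and tail (B, long
#' carbon chain) fragments.
#'
#' @return A tibble with columns `species`, `delta` ((J/cm^3)^0.5).
#' @export
rolg_bead_species <- function() {
  path <- system.file("extdata", "rolg_bead_species.csv",
                      package = "mesogelkit", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Reported pairwise chi and repulsion parameters for the GMO gel
#'
#' The ten unordered pairs over \{water, ethanol, resveratrol, A, B\} with
#' their Flory-Huggins parameters (mixing-energy route for hydrogen-bonded
#' pairs, solubility-parameter route otherwise) and the repulsion parameters
#' as printed in the source data, together with the value recomputed from
#' the linear bridge. Two printed rows disagree with the bridge at
#' one-decimal rounding (resveratrol/A and A/ethanol); the recomputed column
#' is what the simulation modules consume.
#'
#' @return A tibble with columns `species_i`, `species_j`, `chi`,
#'   `a_printed`, `a_recomputed`, `consistent`.
#' @seealso [check_bridge_consistency()], [rolg_interaction_table()]
#' @export
rolg_chi_pairs <- function() {
  path <- system.file("extdata", "rolg_chi_pairs.csv",
                      package = "mesogelkit", mustWork = TRUE)
  check_bridge_consistency(as_tibble(read.csv(path, stringsAsFactors = FALSE)))
}

#' Full interaction table for the GMO gel bead species
#'
#' Expands [rolg_chi_pairs()] into the symmetric chi matrix over the five
#' bead species and bridges it to repulsion parameters with
#' [build_interaction_table()]. All `a` values come from the bridge (the two
#' bridge-inconsistent printed entries are not used).
#'
#' @inheritParams build_interaction_table
#' @return An `interaction_table` over water, ethanol, resveratrol, A, B.
#' @export
rolg_interaction_table <- function(temp = 328, rho = 5, v_ref = 18) {
  pairs <- rolg_chi_pairs()
  species <- c("water", "ethanol", "resveratrol", "A", "B")
  chi <- matrix(0, 5, 5, dimnames = list(species, species))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$species_i[k]
    j <- pairs$species_j[k]
    chi[i, j] <- chi[j, i] <- pairs$chi[k]
  }
  build_interaction_table(species, chi, temp = temp, rho = rho, v_ref = v_ref)
}

#' Drug loading of a formulation
#'
#' Mass of drug per gram of total formulation, in mg/g. The reference ROLG
#' recipe (42 mg resveratrol in 9.642 g total) gives 4.36 mg/g, i.e. 4.4 at
#' one decimal. Scale-invariant: multiplying all masses by a constant leaves
#' the loading unchanged.
#'
#' @param formulation A data frame with columns `mass_g` and logical
#'   `is_drug` (at least one `TRUE` row), e.g. [rolg_formulation()].
#' @return Loading in mg drug per g formulation.
#' @examples
#' drug_loading(rolg_formulation())
#' @export
drug_loading <- function(formulation) {
  formulation <- as_tibble(formulation)
  if (!all(c("mass_g", "is_drug") %in% names(formulation))) {
    abort("`formulation` needs columns `mass_g` and `is_drug`.")
  }
  if (any(formulation$mass_g <= 0)) abort("all component masses must be > 0.")
  if (!any(formulation$is_drug)) {
    abort("no component is flagged as the drug (`is_drug`).")
  }
  1000 * sum(formulation$mass_g[formulation$is_drug]) /
    sum(formulation$mass_g)
}

#' Apportion a bead budget over formulation components
#'
#' Converts component masses to mole fractions and apportions a requested
#' total bead count into whole molecules, so that per-species bead fractions
#' match the mole-weighted target \eqn{f_i = n_i b_i / \sum_j n_j b_j}
#' (moles n, beads-per-molecule b) as closely as whole molecules allow.
#' Rounding uses largest-remainder apportionment: molecule quotas are
#' floored, then molecules are added one at a time to the species with the
#' largest outstanding remainder among those that still fit the remaining
#' bead deficit (ties broken by component order). The realised total never
#' exceeds the request and falls short by less than the smallest
#' beads-per-molecule present, so it is always within +/- max(b) of the
#' request (exact whenever a 1-bead species such as water is present).
#'
#' @param formulation As in [drug_loading()], with `molar_mass` and
#'   `beads_per_molecule` columns.
#' @param total_beads Requested total bead count (>= one molecule of each
#'   component).
#' @return A tibble with columns `component`, `beads_per_molecule`,
#'   `n_molecules`, `n_beads`, `bead_fraction`, `target_fraction`; attribute
#'   `total_beads` holds the realised total.
#' @examples
#' bead_counts_from_formulation(rolg_formulation(), 27302)
#' @export
bead_counts_from_formulation <- function(formulation, total_beads) {
  f <- as_tibble(formulation)
  need <- c("component", "mass_g", "molar_mass", "beads_per_molecule")
  if (!all(need %in% names(f))) {
    abort(paste("`formulation` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(f$mass_g <= 0) || any(f$molar_mass <= 0)) {
    abort("masses and molar masses must be > 0.")
  }
  b <- as.integer(f$beads_per_molecule)
  if (any(b < 1)) abort("`beads_per_molecule` must be >= 1.")
  if (total_beads < sum(b)) {
    abort("`total_beads` too small to place one molecule of each component.")
  }
  moles <- f$mass_g / f$molar_mass
  target_frac <- moles * b / sum(moles * b)
  # molecule quotas implied by the bead-fraction target
  quota <- total_beads * target_frac / b
  n_mol <- floor(quota)
  remainder <- quota - n_mol
  deficit <- total_beads - sum(n_mol * b)
  repeat {
    fits <- which(b <= deficit)
    if (length(fits) == 0L) break
    k <- fits[which.max(remainder[fits])]
    n_mol[k] <- n_mol[k] + 1
    remainder[k] <- remainder[k] - 1
    deficit <- deficit - b[k]
  }
  out <- tibble(
    component = f$component,
    beads_per_molecule = b,
    n_molecules = as.integer(n_mol),
    n_beads = as.integer(n_mol * b),
    bead_fraction = n_mol * b / sum(n_mol * b),
    target_fraction = target_frac
  )
  attr(out, "total_beads") <- sum(out$n_beads)
  out
}

# parse a chain spec like "A:5;B:16" into a per-bead species vector
parse_blocks <- function(blocks) {
  parts <- strsplit(blocks, ";", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2 || is.na(as.integer(kv[2]))) {
      abort(paste0("malformed block spec: '", p, "'"))
    }
    rep(kv[1], as.integer(kv[2]))
  }))
}
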