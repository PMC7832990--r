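# Independent reference implementations used as oracles. Deliberately plain
# (double loops, no cell lists, no compiled code) so they share nothing with
# the package's evaluation paths.

# minimum-image displacement
ref_minimg <- function(d, L) d - L * round(d / L)

# all-pairs conservative + dissipative DPD forces, plain R
ref_pair_forces <- function(state, a, gamma = 0) {
  pos <- state$positions
  vel <- state$velocities
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- ref_minimg(pos[i, ] - pos[j, ], state$box)
      r <- sqrt(sum(d^2))
      if (r >= 1 || r < 1e-12) next
      e <- d / r
      w <- 1 - r
      aij <- a[state$species[i], state$species[j]]
      fm <- aij * w
      if (gamma > 0) {
        fm <- fm - gamma * w^2 * sum(e * (vel[i, ] - vel[j, ]))
      }
      f[i, ] <- f[i, ] + fm * e
      f[j, ] <- f[j, ] - fm * e
    }
  }
  f
}

# harmonic zero-rest-length bond forces, plain R
ref_bond_forces <- function(state, spring_c) {
  n <- nrow(state$positions)
  f <- matrix(0, n, 3)
  for (b in seq_len(nrow(state$bonds))) {
    i <- state$bonds[b, 1]
    j <- state$bonds[b, 2]
    d <- ref_minimg(state$positions[i, ] - state$positions[j, ], state$box)
    f[i, ] <- f[i, ] - spring_c * d
    f[j, ] <- f[j, ] + spring_c * d
  }
  f
}

# structure factor via the N^2 pair-difference route:
# S(q) = (1/N) sum_jk cos(q . (r_j - r_k))
ref_structure_factor <- function(pos, qvecs) {
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  vapply(seq_len(nrow(qvecs)), function(m) {
    q <- qvecs[m, ]
    sum(cos(q[1] * dx + q[2] * dy + q[3] * dz)) / n
  }, numeric(1))
}

# bare dpd_state constructor for hand-built fixtures
make_state <- function(pos, species, box, bonds = matrix(integer(0), 0, 2),
                       vel = NULL) {
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  mesogelkit:::new_dpd_state(pos, vel, species, bonds, box)
}

# released-fraction laws for generator/fitter round trips
ref_release_curve <- function(model, k, n, t) {
  switch(model,
    zero_order = k * t,
    higuchi = k * sqrt(t),
    ritger_peppas = k * t^n
  )
}
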