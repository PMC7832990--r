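test_that("density deposition conserves mass and localises correctly", {
  # all beads at one voxel centre: that voxel carries the full mass
  box <- c(8, 8, 8)
  h <- 8 / 16
  centre <- c(3.5 * h, 3.5 * h, 3.5 * h)
  st <- make_state(matrix(rep(centre, 5), ncol = 3, byrow = TRUE),
                   rep("w", 5), box = box)
  fld <- density_field(st, "w", 16)
  expect_equal(fld[4, 4, 4] * attr(fld, "voxel_volume"), 5)
  expect_equal(sum(fld) * attr(fld, "voxel_volume"), 5)

  # conservation on random fixtures of several sizes and grids
  withr::with_seed(31, {
    for (n in c(10, 500, 4000)) {
      stn <- make_state(matrix(runif(3 * n) * 8, ncol = 3), rep("w", n),
                        box = box)
      for (g in c(8, 20)) {
        f2 <- density_field(stn, "w", g)
        expect_equal(sum(f2) * attr(f2, "voxel_volume"), n,
                     tolerance = 1e-9)
      }
    }
  })
  expect_error(density_field(st, "absent", 16), "no beads")
})

test_that("uniform beads give voxel noise shrinking as 1/sqrt(occupancy)", {
  withr::with_seed(5, {
    st <- make_state(matrix(runif(3 * 64000) * 8, ncol = 3),
                     rep("w", 64000), box = c(8, 8, 8))
  })
  f_coarse <- density_field(st, "w", 8)   # 125 beads/voxel
  f_fine <- density_field(st, "w", 16)    # ~15.6 beads/voxel
  rel_sd <- function(f) sd(f) / mean(f)
  expect_equal(rel_sd(f_coarse), 1 / sqrt(125), tolerance = 0.25)
  expect_gt(rel_sd(f_fine), 1.5 * rel_sd(f_coarse))
})

test_that("iso-surface of a Gaussian blob recovers the analytic sphere", {
  n <- 48
  L <- 10
  sigma <- 1.5
  ax <- (seq_len(n) - 0.5) * L / n - L / 2
  g <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    g[, , k] <- exp(-(outer(ax^2, ax^2, "+") + ax[k]^2) / (2 * sigma^2))
  }
  fld <- mesogelkit:::new_density_field(g, c(L, L, L))
  surf <- isodensity_surface(fld, 0.5)
  r_half <- sigma * sqrt(2 * log(2))
  expect_equal(surf$area, 4 * pi * r_half^2, tolerance = 0.05)
  expect_true(all(surf$faces >= 1 & surf$faces <= nrow(surf$vertices)))
  # vertices sit on the sphere of the half-max radius
  rad <- sqrt(rowSums(sweep(surf$vertices, 2, c(L, L, L) / 2)^2))
  expect_lt(max(abs(rad - r_half)), 0.1)
  flat <- mesogelkit:::new_density_field(array(1, c(4, 4, 4)), c(L, L, L))
  expect_error(isodensity_surface(flat, 1), "strictly between")
})

test_that("structure factor matches the pair-sum oracle and is ~1 for ideal gas", {
  withr::with_seed(23, {
    pos <- matrix(runif(900) * 8, ncol = 3)
  })
  st <- make_state(pos, rep("w", 300), box = c(8, 8, 8))
  sq <- structure_factor(st, "w", q_max = 3, n_bins = 12)
  # brute-force double loop over bead pairs on the same q modes
  nmax <- floor(3 * 8 / (2 * pi))
  qv <- as.matrix(expand.grid(nx = 0:nmax, ny = 0:nmax, nz = 0:nmax))
  qv <- qv[rowSums(qv) > 0, ] * 2 * pi / 8
  keep <- sqrt(rowSums(qv^2)) <= 3
  qv <- qv[keep, ]
  s_ref <- ref_structure_factor(pos, qv)
  # compare mode-by-mode against the complex-exponential direct sum
  phase <- pos %*% t(qv)
  s_direct <- (colSums(cos(phase))^2 + colSums(sin(phase))^2) / 300
  expect_lt(max(abs(s_direct - s_ref)), 1e-8)
  # ideal gas: S ~ 1 within sampling noise (per-mode S is ~Exp(1), so the
  # mode-weighted mean is the stable statistic; single bins stay below the
  # expected extreme of a few hundred exponential draws)
  expect_lt(abs(weighted.mean(sq$s, sq$n_modes) - 1), 0.25)
  expect_lt(max(sq$s), 5)
  expect_true(all(sq$s >= 0) && all(sq$q > 0))
})

test_that("hand-built lamellae produce the square-wave Fourier signature", {
  st <- gen_lamellar_config(box = 20, period = 5, beads = 4000, seed = 3)
  sq <- structure_factor(st, "A", q_max = 2 * pi, n_bins = 40)
  q1 <- 2 * pi / 5
  bin_w <- 2 * pi / 40
  expect_lt(abs(attr(sq, "q_peak") - q1), bin_w)          # within one bin
  expect_equal(attr(sq, "q_peak_mode"), q1, tolerance = 1e-9)
  expect_equal(attr(sq, "d_spacing"), 5, tolerance = bin_w / q1 * 5)
  # square-wave Fourier series: odd z-harmonics present (amplitude ~ 1/m),
  # even z-harmonics suppressed; checked at the exact harmonic modes
  pos_a <- st$positions[st$species == "A", ]
  s_mode <- function(nz) {
    ph <- pos_a[, 3] * 2 * pi * nz / 20
    (sum(cos(ph))^2 + sum(sin(ph))^2) / nrow(pos_a)
  }
  expect_gt(s_mode(4), 100)              # fundamental (q1 = 2 pi / 5)
  expect_gt(s_mode(12), 5)               # 3rd harmonic
  expect_gt(s_mode(4) / s_mode(8), 50)   # 2nd harmonic suppressed
  expect_equal(s_mode(12) / s_mode(4), 1 / 9, tolerance = 0.5)
  # rigid translation leaves |FT| unchanged
  st2 <- st
  st2$positions <- (st$positions +
                      matrix(c(1.3, -2.1, 0.7), nrow(st$positions), 3,
                             byrow = TRUE)) %% 20
  sq2 <- structure_factor(st2, "A", q_max = 2 * pi, n_bins = 40)
  expect_equal(sq2$s, sq$s, tolerance = 1e-6)
  expect_error(structure_factor(st, "A", n_bins = 40)[0, ], NA)
  one <- make_state(matrix(1, 1, 3), "w", box = c(8, 8, 8))
  expect_error(structure_factor(one, "w"), "at least 2")
})

test_that("interface enrichment reduces to the voxel-counting oracle", {
  # A and B sit on every voxel centre of the z < 10 half-box (deterministic
  # density, no Poisson holes); target beads occupy interior centres only
  box <- c(20, 20, 20)
  centres <- as.matrix(expand.grid(x = 0:19 + 0.5, y = 0:19 + 0.5,
                                   z = 0:9 + 0.5))
  n_ab <- nrow(centres) # 4000
  withr::with_seed(41, {
    pick <- centres[, 3] >= 2 & centres[, 3] <= 8
    pos_t <- centres[sample(which(pick), 500), ]
  })
  st <- make_state(rbind(centres, centres, pos_t),
                   c(rep("A", n_ab), rep("water", n_ab), rep("eth", 500)),
                   box = box)
  enr <- interface_enrichment(st, "eth", grid_shape = 20)
  # all target mass inside interface voxels -> ratio = total/interface
  expect_equal(enr$n_interface, 4000)
  expect_equal(enr$ratio, enr$n_voxels / enr$n_interface, tolerance = 1e-9)
  expect_equal(enr$ratio, 2, tolerance = 1e-9)

  # a uniformly distributed target scores ~1
  withr::with_seed(42, {
    pos_u <- matrix(runif(3 * 2000) * 20, ncol = 3)
  })
  st_u <- make_state(rbind(centres, centres, pos_u),
                     c(rep("A", n_ab), rep("water", n_ab),
                       rep("eth", 2000)), box = box)
  enr_u <- interface_enrichment(st_u, "eth", grid_shape = 20)
  expect_equal(enr_u$ratio, 1, tolerance = 0.1)

  # relabelling a species not involved in the score changes nothing
  extra <- make_state(rbind(centres, centres, pos_t,
                            matrix(10, 5, 3)),
                      c(rep("A", n_ab), rep("water", n_ab),
                        rep("eth", 500), rep("spectator", 5)), box = box)
  extra2 <- extra
  extra2$species[extra2$species == "spectator"] <- "bystander"
  e1 <- interface_enrichment(extra, "eth", grid_shape = 20)
  e2 <- interface_enrichment(extra2, "eth", grid_shape = 20)
  expect_equal(e1$ratio, e2$ratio)
})
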