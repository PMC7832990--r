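zero_table <- function(species = "w") {
  it <- build_interaction_table(species, matrix(0, length(species),
                                                length(species)))
  it$a[] <- 0
  it
}

water_counts <- function(n) {
  tibble::tibble(component = "water", n_molecules = n, blocks = "water:1")
}

test_that("build_system places molecules, chains and momentum-free velocities", {
  st <- build_system(water_counts(100), box = 5, seed = 1)
  expect_equal(nrow(st$positions), 100)
  expect_equal(nrow(st$bonds), 0)
  expect_lt(max(abs(colSums(st$velocities))), 1e-10)
  expect_true(all(st$positions >= 0 & st$positions < 5))

  gmo <- tibble::tibble(component = "gmo", n_molecules = 10,
                        blocks = "A:5;B:16")
  stg <- build_system(gmo, box = 10, seed = 2)
  expect_equal(nrow(stg$positions), 210)
  expect_equal(nrow(stg$bonds), 200)
  # every chain is 5 head beads then 16 tail beads, bonded consecutively
  for (m in 0:9) {
    idx <- m * 21 + 1:21
    expect_equal(stg$species[idx], c(rep("A", 5), rep("B", 16)))
  }
  expect_equal(stg$bonds[1:20, ], cbind(1:20, 2:21), ignore_attr = TRUE)

  expect_identical(build_system(gmo, box = 10, seed = 7),
                   build_system(gmo, box = 10, seed = 7))
  expect_error(build_system(water_counts(0), box = 5, seed = 1), "empty")
})

test_that("pair forces obey cutoff, closed form, and Newton's third law", {
  it <- build_interaction_table("w", matrix(0, 1, 1)) # a = 16.5
  two <- make_state(rbind(c(1, 1, 1), c(2.5, 1, 1)), c("w", "w"),
                    box = c(8, 8, 8))
  expect_equal(pair_forces(two, it), matrix(0, 2, 3))
  near <- make_state(rbind(c(1, 1, 1), c(1.5, 1, 1)), c("w", "w"),
                     box = c(8, 8, 8))
  f <- pair_forces(near, it)
  # conservative closed form a (1 - r/rc) = 16.5 * 0.5 along x
  expect_equal(f[1, ], c(-8.25, 0, 0))
  expect_equal(f[2, ], c(8.25, 0, 0))

  fx <- gen_dpd_fixture(5, 100, box = 5, seed = 3)
  ff <- pair_forces(fx$state, fx$interaction_table)
  expect_lt(max(abs(colSums(ff))), 1e-9)
  bad <- fx$state
  bad$species[1] <- "unknown"
  expect_error(pair_forces(bad, fx$interaction_table),
               "not in interaction table")
})

test_that("cell-list evaluation equals brute force and the R reference", {
  withr::with_seed(17, {
    pos <- matrix(runif(600) * 6, ncol = 3)
    vel <- matrix(rnorm(600), ncol = 3)
    sp <- sample(c("A", "B"), 200, replace = TRUE)
  })
  st <- make_state(pos, sp, box = c(6, 6, 6), vel = vel)
  chi <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  it <- build_interaction_table(c("A", "B"), chi)
  params <- dpd_params(gamma = 4.5)
  f_cell <- pair_forces(st, it, params)
  f_brute <- pair_forces(st, it, params, brute = TRUE)
  expect_lt(max(abs(f_cell - f_brute)), 1e-12)
  f_ref <- ref_pair_forces(st, it$a, gamma = params$gamma)
  expect_lt(max(abs(f_cell - f_ref)), 1e-9)
})

test_that("bond forces are harmonic, antisymmetric, minimum-image", {
  p <- dpd_params(spring_c = 4)
  pair0 <- make_state(rbind(c(2, 2, 2), c(2, 2, 2)), c("w", "w"),
                      box = c(6, 6, 6), bonds = cbind(1L, 2L))
  expect_equal(bond_forces(pair0, p), matrix(0, 2, 3))
  pair <- make_state(rbind(c(2, 2, 2), c(2.5, 2, 2)), c("w", "w"),
                     box = c(6, 6, 6), bonds = cbind(1L, 2L))
  f <- bond_forces(pair, p)
  expect_equal(f[1, ], c(2, 0, 0))   # attractive, magnitude C r = 2
  expect_equal(f[2, ], c(-2, 0, 0))
  # across the periodic boundary the image distance is used
  wrapped <- make_state(rbind(c(0.1, 2, 2), c(5.9, 2, 2)), c("w", "w"),
                        box = c(6, 6, 6), bonds = cbind(1L, 2L))
  fw <- bond_forces(wrapped, p)
  expect_equal(fw[1, ], c(-0.8, 0, 0)) # pulled towards x = 5.9 via x = 0
  # symmetric 3-chain: middle bead force-free
  chain <- make_state(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1)),
                      rep("w", 3), box = c(8, 8, 8),
                      bonds = rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(bond_forces(chain, p)[2, ], c(0, 0, 0))
  expect_equal(bond_forces(chain, p), ref_bond_forces(chain, 4))
  badbond <- make_state(rbind(c(1, 1, 1), c(2, 1, 1)), c("w", "w"),
                        box = c(6, 6, 6), bonds = cbind(1L, 5L))
  expect_error(bond_forces(badbond, p), "out of range")
})

test_that("integration drifts freely without forces and conserves momentum", {
  st <- make_state(rbind(c(1, 1, 1), c(3, 3, 3)), c("w", "w"),
                   box = c(8, 8, 8),
                   vel = rbind(c(1, -0.5, 0.25), c(-1, 0.5, -0.25)))
  p <- dpd_params(gamma = 0, dt = 0.04)
  out <- integrate_step(st, zero_table(), p)
  expect_equal(out$positions, st$positions + 0.04 * st$velocities)
  expect_equal(out$step_count, 1L)

  fx <- gen_dpd_fixture(5, 200, box = 5, seed = 9)
  tr <- run_simulation(fx$state, fx$interaction_table,
                       dpd_params(seed = 9), n_steps = 1000,
                       snapshot_every = 1)
  expect_lt(max(tr$log$net_momentum), 1e-8)
  # chain integrity: bonds untouched by the run
  expect_identical(tr$state$bonds, fx$state$bonds)
})

test_that("a harmonic dimer oscillates at the analytic period", {
  # relative coordinate: mu = 1/2, omega = sqrt(2C/m), T = 2 pi sqrt(m/(2C))
  p <- dpd_params(gamma = 0, dt = 0.01, spring_c = 4)
  st <- make_state(rbind(c(4, 4, 4), c(4.5, 4, 4)), c("w", "w"),
                   box = c(8, 8, 8), bonds = cbind(1L, 2L))
  it <- zero_table()
  sep <- numeric(600)
  for (i in seq_len(600)) {
    st <- integrate_step(st, it, p)
    d <- st$positions[1, 1] - st$positions[2, 1]
    sep[i] <- d - 8 * round(d / 8)
  }
  zc <- which(diff(sign(sep)) != 0)
  expect_gte(length(zc), 3)
  period_est <- 2 * mean(diff(zc[1:3])) * p$dt
  expect_equal(period_est, 2 * pi * sqrt(1 / 8), tolerance = 0.01)
})

test_that("trajectories are deterministic and validate their inputs", {
  fx <- gen_dpd_fixture(3, 80, box = 5, seed = 4)
  p <- dpd_params(seed = 21)
  t1 <- run_simulation(fx$state, fx$interaction_table, p, n_steps = 50,
                       snapshot_every = 10)
  t2 <- run_simulation(fx$state, fx$interaction_table, p, n_steps = 50,
                       snapshot_every = 10)
  expect_identical(t1$state$positions, t2$state$positions)
  expect_identical(t1$log, t2$log)
  expect_error(run_simulation(fx$state, fx$interaction_table, p,
                              n_steps = 0), "n_steps")
})

test_that("non-finite coordinates abort the run naming the step", {
  st <- make_state(rbind(c(4, 4, 4), c(NaN, 4, 4)), c("w", "w"),
                   box = c(8, 8, 8))
  expect_error(
    run_simulation(st, zero_table(), dpd_params(), n_steps = 5,
                   snapshot_every = 1),
    "blow-up.*at step 1"
  )
})

test_that("kinetic temperature matches its definition and sampling", {
  st <- make_state(rbind(c(1, 1, 1), c(2, 2, 2)), c("w", "w"),
                   box = c(8, 8, 8), vel = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(kinetic_temperature(st), 2 / 3)
  st2 <- st
  st2$velocities <- 2 * st$velocities
  expect_equal(kinetic_temperature(st2), 4 * kinetic_temperature(st))
  st0 <- st
  st0$velocities[] <- 0
  expect_equal(kinetic_temperature(st0), 0)
  one <- make_state(matrix(1, 1, 3), "w", box = c(8, 8, 8))
  expect_error(kinetic_temperature(one), "at least 2")
  # Maxwell-Boltzmann draw at kBT = 1
  big <- build_system(water_counts(10000), box = 25, seed = 12)
  expect_equal(kinetic_temperature(big), 1, tolerance = 0.03)
})

test_that("thermostat bias grows monotonically with the timestep", {
  counts <- water_counts(648)
  it <- build_interaction_table("water", matrix(0, 1, 1))
  it$a[1, 1] <- 25
  st <- build_system(counts, box = 6, seed = 5)
  dev <- vapply(c(0.01, 0.04, 0.1), function(dt) {
    nst <- round(160 / dt)
    tr <- run_simulation(st, it, dpd_params(dt = dt, seed = 5),
                         n_steps = nst, snapshot_every = 50)
    abs(mean(tr$log$temperature[tr$log$step > nst / 2]) - 1)
  }, numeric(1))
  expect_lt(dev[1], 0.03) # within tolerance at small dt
  expect_lt(dev[2], 0.03) # and at the default dt
  expect_true(all(diff(dev) > 0))
})

test_that("an ideal-gas thermostatted fluid stays structureless", {
  # a = 0 with gamma > 0: radial distribution flat within sampling noise
  st <- build_system(water_counts(600), box = 6, seed = 8)
  tr <- run_simulation(st, zero_table("water"), dpd_params(seed = 8),
                       n_steps = 400, snapshot_every = 400)
  pos <- tr$state$positions
  dd <- lapply(1:3, function(k) {
    dx <- outer(pos[, k], pos[, k], "-")
    dx - 6 * round(dx / 6) # minimum image
  })
  d <- sqrt(dd[[1]]^2 + dd[[2]]^2 + dd[[3]]^2)
  d <- d[upper.tri(d)]
  edges <- seq(0.3, 1.5, by = 0.3)
  counts <- hist(d[d < 1.5 & d > 0.3], breaks = edges, plot = FALSE)$counts
  shell <- diff(edges^3) # ideal-gas expectation scales with shell volume
  rel <- counts / shell
  expect_lt(max(abs(rel / mean(rel) - 1)), 0.2)
})
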