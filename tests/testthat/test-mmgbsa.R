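settings <- gb_settings()

test_that("energy components always sum exactly and entropy stays zero", {
  ec <- energy_components(0, -5.25, -3.5, 1.125, 0.875)
  expect_identical(ec$total, -5.25 - 3.5 + 1.125 + 0.875)
  expect_identical(ec$ts_entropy, 0)
  expect_error(energy_components(ts_entropy = 1.2), "fixed at zero")
})

test_that("bonded energy reproduces hand values and a term-by-term oracle", {
  di <- tiny_system(rbind(c(0, 0, 0), c(1.0, 0, 0)), charges = c(0, 0),
                    bonds = data.frame(i = 1, j = 2, kb = 100, b0 = 1.0))
  expect_equal(bonded_energy(di), 0)
  di$xyz[2, 1] <- 1.1
  expect_equal(bonded_energy(di), 1.00, tolerance = 1e-12)
  # random strained molecule vs an explicit loop oracle
  toy <- make_toy_complex(2, 1, seed = 81)
  sys <- toy$system
  coords <- sys$xyz + rand_coords(n_atoms(sys), spread = 0.25, seed = 82)
  e_oracle <- 0
  for (r in seq_len(nrow(sys$bonds))) {
    b <- sys$bonds[r, ]
    d <- sqrt(sum((coords[b$i, ] - coords[b$j, ])^2))
    e_oracle <- e_oracle + b$kb * (d - b$b0)^2
  }
  for (r in seq_len(nrow(sys$angles))) {
    a <- sys$angles[r, ]
    v1 <- coords[a$i, ] - coords[a$j, ]; v2 <- coords[a$k, ] - coords[a$j, ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    e_oracle <- e_oracle + a$ktheta * (th - a$theta0 * pi / 180)^2
  }
  expect_equal(bonded_energy(sys, coords), e_oracle, tolerance = 1e-12)
})

test_that("Coulomb energy matches hand arithmetic and a double-loop oracle", {
  two <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  expect_equal(coulomb_energy(two, c(1, -1)), -100.00, tolerance = 1e-10)
  expect_equal(coulomb_energy(two, c(0, 0)), 0)
  set.seed(91)
  coords <- rand_coords(10, seed = 91)
  q <- runif(10, -1, 1)
  expect_equal(coulomb_energy(coords, q), oracle_coulomb(coords, q),
               tolerance = 1e-10)
  expect_error(coulomb_energy(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "singularity")
})

test_that("LJ energy has its minimum at rmin and decays to zero", {
  epsv <- c(0.12, 0.27); rmh <- c(1.5, 1.9)
  rmin <- sum(rmh); emin <- -sqrt(prod(epsv))
  at <- function(r) lj_energy(rbind(c(0, 0, 0), c(r, 0, 0)), epsv, rmh)
  expect_equal(at(rmin), emin, tolerance = 1e-12)
  expect_gt(at(rmin * 0.9), at(rmin))
  rs <- seq(rmin, 4 * rmin, length.out = 30)
  es <- vapply(rs, at, numeric(1))
  expect_true(all(diff(es) > 0))          # monotone rise toward 0 past rmin
  expect_lt(abs(es[30]), 1e-3)
  set.seed(92)
  coords <- rand_coords(8, spread = 5, seed = 92)
  ev <- runif(8, 0.05, 0.3); rh <- runif(8, 1.2, 2.0)
  expect_equal(lj_energy(coords, ev, rh), oracle_lj(coords, ev, rh),
               tolerance = 1e-10)
})

test_that("effective Born radii hit the isolated-atom and far-pair limits", {
  s0 <- gb_settings(radius_offset = 0)
  expect_equal(effective_born_radii(rbind(c(0, 0, 0)), 1.5, s0), 1.5,
               tolerance = 1e-6)
  # default 0.09 A offset: isolated radius is the offset-corrected one
  expect_equal(effective_born_radii(rbind(c(0, 0, 0)), 1.5, settings), 1.41,
               tolerance = 1e-6)
  far <- effective_born_radii(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.5, 1.7),
                              settings)
  expect_lt(max(abs(far - c(1.41, 1.61))), 1e-4)
  expect_error(effective_born_radii(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    c(1.5, 1.5), settings), "overlapping")
})

test_that("pairwise descreening matches a volume-quadrature oracle", {
  # two atoms at 3 A, uniform screen 0.8
  rho <- c(1.41, 1.61); scr <- 0.8
  for (i in 1:2) {
    j <- 3 - i
    closed <- pepaffinity:::hct_integral(3.0, rho[i], scr * rho[j])
    quad <- oracle_descreen(3.0, rho[i], scr * rho[j])
    expect_equal(closed, quad, tolerance = 0.05)
  }
})

test_that("GB polar energy reproduces the Born ion and Still's sum", {
  born <- gb_polar_energy(rbind(c(0, 0, 0)), 1, 2, settings)
  exact <- -0.5 * 332.0636 * (1 - 1 / 78.5) / 2
  expect_equal(born, exact, tolerance = 1e-6)
  expect_equal(gb_polar_energy(rand_coords(4, seed = 1), rep(0, 4),
                               rep(1.5, 4), settings), 0)
  coords <- rand_coords(5, spread = 3, seed = 93)
  set.seed(93)
  q <- runif(5, -0.8, 0.8)
  R <- runif(5, 1.2, 2.2)
  expect_equal(gb_polar_energy(coords, q, R, settings),
               oracle_still(coords, q, R, 1, 78.5), tolerance = 1e-10)
})

test_that("GB polar energy vanishes as solvent dielectric approaches solute", {
  coords <- rand_coords(5, spread = 3, seed = 94)
  set.seed(94)
  q <- runif(5, -0.8, 0.8)
  R <- effective_born_radii(coords, runif(5, 1.3, 1.9), settings)
  close_eps <- gb_settings(eps_solvent = 1 + 1e-7)
  expect_lt(abs(gb_polar_energy(coords, q, R, close_eps)), 1e-4)
})

test_that("at infinite separation only self (Born) terms survive", {
  radii <- c(1.5, 1.8); q <- c(0.7, -0.4)
  coords <- rbind(c(0, 0, 0), c(1e7, 0, 0))
  R <- effective_born_radii(coords, radii, settings)
  together <- gb_polar_energy(coords, q, R, settings)
  selfsum <- sum(vapply(1:2, function(i)
    gb_polar_energy(coords[i, , drop = FALSE], q[i],
                    effective_born_radii(coords[i, , drop = FALSE], radii[i],
                                         settings),
                    settings), numeric(1)))
  expect_equal(together, selfsum, tolerance = 1e-6)
})

test_that("SASA matches sphere area, burial, and the two-sphere closed form", {
  a1 <- sasa(rbind(c(0, 0, 0)), 1.6, probe = 1.4, n_points = 960)
  expect_equal(a1, 4 * pi * 3.0^2, tolerance = 0.005)
  # atom caged by 14 tight neighbours has zero accessible area
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3))
  caged <- rbind(c(0, 0, 0), dirs * 2.0)
  ac <- sasa(caged, c(1.5, rep(2.5, 14)), probe = 1.4, n_points = 960)
  expect_equal(ac[1], 0)
  # two overlapping spheres against the spherical-cap closed form
  R1 <- 1.6 + 1.4; R2 <- 1.9 + 1.4; d <- 2.4
  a2 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.6, 1.9), probe = 1.4,
             n_points = 4000)
  expect_equal(a2[1], oracle_two_sphere_area(R1, R2, d), tolerance = 0.01)
  expect_equal(a2[2], oracle_two_sphere_area(R2, R1, d), tolerance = 0.01)
})

test_that("total SASA is invariant under rigid motion", {
  coords <- rand_coords(7, spread = 3, seed = 95)
  set.seed(95)
  radii <- runif(7, 1.3, 2.0)
  base <- sum(sasa(coords, radii, n_points = 960))
  th <- 1.1; ax <- c(2, -1, 1) / sqrt(6)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- sweep(coords %*% t(R), 2, c(10, -4, 7), "+")
  expect_equal(sum(sasa(moved, radii, n_points = 960)), base,
               tolerance = 0.005)
})

test_that("nonpolar term is linear in area with the configured tension", {
  s <- gb_settings(surface_tension = 0.00542, nonpolar_offset = 0.92)
  expect_equal(nonpolar_energy(250, s), 0.00542 * 250 + 0.92)
})

test_that("single-trajectory binding cancels internal energy exactly", {
  for (seed in c(101, 102)) {
    toy <- make_toy_complex(3, 2,
                            contacts = data.frame(distance = 2.9,
                                                  receptor_charge = 0.6,
                                                  ligand_charge = -0.6),
                            seed = seed)
    ec <- snapshot_binding(toy$system$xyz, toy$system, toy$partition, settings)
    expect_identical(ec$e_internal, 0)
    expect_identical(ec$total,
                     ec$e_elect + ec$e_vdw + ec$g_polar + ec$g_nonpolar)
  }
})

test_that("an LJ-only dimer binds by exactly the pair well depth", {
  epsv <- c(0.15, 0.21); rmh <- c(1.6, 1.8)
  sys <- tiny_system(rbind(c(0, 0, 0), c(sum(rmh), 0, 0)),
                     charges = c(0, 0), eps = epsv, rmin_half = rmh)
  part <- complex_partition(1, 2)
  ec <- snapshot_binding(sys$xyz, sys, part, settings)
  expect_equal(ec$e_vdw, -sqrt(prod(epsv)), tolerance = 1e-12)
  expect_equal(ec$e_elect, 0)
  expect_identical(ec$e_internal, 0)
})

test_that("charged dimer components match a fully independent three-evaluation oracle", {
  q <- c(0.8, -0.6); radii <- c(1.6, 1.5); d <- 3.1
  epsv <- c(0.12, 0.18); rmh <- c(1.7, 1.6)
  coords <- rbind(c(0, 0, 0), c(d, 0, 0))
  sys <- tiny_system(coords, charges = q, eps = epsv, rmin_half = rmh,
                     gb_radius = radii)
  ec <- snapshot_binding(sys$xyz, sys, complex_partition(1, 2), settings)
  # MM cross terms by hand
  expect_equal(ec$e_elect, 332.0636 * q[1] * q[2] / d, tolerance = 1e-10)
  rmin <- sum(rmh); s6 <- (rmin / d)^6
  expect_equal(ec$e_vdw, sqrt(prod(epsv)) * (s6^2 - 2 * s6),
               tolerance = 1e-10)
  # GB: oracle radii from the quadrature integral + OBC rescaling ("CA" toy
  # atoms are carbon, screen 0.72), Still sums by hand, minus isolated ions
  rho <- radii - 0.09
  R_orc <- numeric(2)
  for (i in 1:2) {
    j <- 3 - i
    I <- oracle_descreen(d, rho[i], 0.72 * rho[j])
    psi <- rho[i] * I
    R_orc[i] <- 1 / (1 / rho[i] -
                       tanh(1.0 * psi - 0.8 * psi^2 + 4.85 * psi^3) / radii[i])
  }
  g_cx <- oracle_still(coords, q, R_orc, 1, 78.5)
  g_sep <- sum(-0.5 * 332.0636 * (1 - 1 / 78.5) * q^2 / rho)
  expect_lt(abs(ec$g_polar - (g_cx - g_sep)), 0.05 * abs(g_cx - g_sep))
  # SASA: two-sphere closed form minus isolated spheres
  R1 <- radii[1] + 1.4; R2 <- radii[2] + 1.4
  d_area <- oracle_two_sphere_area(R1, R2, d) +
    oracle_two_sphere_area(R2, R1, d) - 4 * pi * (R1^2 + R2^2)
  expect_lt(abs(ec$g_nonpolar - 0.00542 * d_area),
            0.02 * abs(0.00542 * d_area) + 1e-6)
})

test_that("ensemble averaging keeps components additive and counts honest", {
  toy <- make_toy_complex(2, 1,
                          contacts = data.frame(distance = 3.0,
                                                receptor_charge = 0.5,
                                                ligand_charge = -0.5),
                          seed = 111)
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames = 12, sigma = 0.08,
                                       seed = 112))
  bs <- ensemble_binding(ens, toy$partition, settings, stride = 2)
  expect_equal(bs$n_snapshots, 6L)
  expect_equal(bs$per_snapshot$frame, seq(1, 12, by = 2))
  per <- bs$per_snapshot
  expect_equal(per$total,
               per$e_internal + per$e_elect + per$e_vdw + per$g_polar +
                 per$g_nonpolar, tolerance = 1e-12)
  expect_equal(bs$mean[["total"]],
               sum(bs$mean[c("e_internal", "e_elect", "e_vdw", "g_polar",
                             "g_nonpolar")]), tolerance = 1e-12)
  bs2 <- ensemble_binding(ens, toy$partition, settings, n_snapshots = 4)
  expect_equal(bs2$n_snapshots, 4L)
})

test_that("relative ddG maps the reference to zero and differences elsewhere", {
  tabs <- reference_tables()
  r4 <- relative_ddg(data.frame(system = tabs$mutant_components$system,
                                dg_mean = tabs$mutant_components$dg_mean),
                     "WT")
  expect_equal(r4$ddg[r4$system == "WT"], 0)
  expect_equal(r4$ddg[r4$system == "R18A"], 20.55, tolerance = 1e-9)
  r6 <- relative_ddg(data.frame(system = tabs$short_peptide_components$system,
                                dg_mean = tabs$short_peptide_components$dg_mean),
                     "WT")
  expect_equal(r6$ddg[r6$system == "LRRASL"], 10.21, tolerance = 1e-9)
  expect_error(relative_ddg(r4[, c("system", "dg_mean")], "nope"),
               "not among")
})

test_that("stronger complementary contact charges monotonically favour binding", {
  mags <- c(0.2, 0.5, 0.8)
  res <- lapply(mags, function(m) {
    toy <- make_toy_complex(2, 1,
                            contacts = data.frame(distance = 2.9,
                                                  receptor_charge = m,
                                                  ligand_charge = -m),
                            seed = 121)   # same seed: identical geometry
    snapshot_binding(toy$system$xyz, toy$system, toy$partition, settings)
  })
  elec <- vapply(res, `[[`, numeric(1), "e_elect")
  tot <- vapply(res, `[[`, numeric(1), "total")
  expect_true(all(diff(elec) < 0))
  expect_true(all(diff(tot) < 0))
})
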