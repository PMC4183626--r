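test_that("superposition is exact for identity and rigid transforms", {
  xyz <- rand_coords(8, seed = 21)
  expect_equal(superpose(xyz, xyz)$rmsd_fit, 0, tolerance = 1e-12)
  # arbitrary proper rotation + translation
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- sweep(xyz %*% t(R), 2, c(5, -3, 2), "+")
  fit <- superpose(moved, xyz)
  expect_lt(fit$rmsd_fit, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$transform(moved), xyz, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("superposition matches brute-force quaternion minimisation", {
  for (seed in c(31, 32)) {
    a <- rand_coords(5, seed = seed)
    b <- rand_coords(5, seed = seed + 100)
    expect_equal(superpose(a, b)$rmsd_fit, oracle_min_rmsd(a, b),
                 tolerance = 1e-5)
  }
})

test_that("degenerate fit geometry is rejected", {
  line <- cbind(1:4, 1:4, 1:4) * 1.0
  expect_error(superpose(line, line + 0.5), "degenerate")
  expect_error(superpose(rand_coords(2, seed = 1)[1:2, , drop = FALSE],
                         rand_coords(2, seed = 2)), "3 fit atoms")
})

test_that("rmsd series is zero against itself and tracks noise level", {
  toy <- make_toy_complex(3, 2, seed = 41)
  sigma <- 0.2
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames = 40, sigma = sigma,
                                       seed = 42))
  rs <- rmsd_series(ens, reference_frame = 1)
  expect_equal(rs$rmsd[1], 0, tolerance = 1e-10)
  expect_equal(rs$time_ps, ens$time_ps)
  # Monte-Carlo oracle for the expected fitted RMSD between two frames that
  # are each reference + isotropic N(0, sigma) noise (quaternion search,
  # independent of the package's Kabsch path)
  sel <- select_atoms(toy$system, "backbone")
  set.seed(43)
  mc <- replicate(25, {
    f1 <- toy$system$xyz + matrix(rnorm(3 * n_atoms(toy$system), sd = sigma),
                                  ncol = 3)
    f2 <- toy$system$xyz + matrix(rnorm(3 * n_atoms(toy$system), sd = sigma),
                                  ncol = 3)
    oracle_min_rmsd(f1[sel, ], f2[sel, ], n_grid = 600)
  })
  expect_equal(mean(rs$rmsd[-1]), mean(mc), tolerance = 0.10)
})

test_that("occupancy counts frames inside the cutoff with two denominators", {
  # two atoms pinned at fixed distances across frames
  sys <- tiny_system(rbind(c(0, 0, 0), c(2.9, 0, 0), c(0, 3.6, 0)),
                     charges = c(0, 0, 0))
  frames <- replicate(20, sys$xyz, simplify = FALSE)
  ens <- snapshot_ensemble(sys, frames)
  st <- hbond_occupancy(ens, rbind(c(1, 2), c(1, 3)))
  expect_equal(st$occupancy_pct, c(100, 0))
  expect_equal(st$mean_distance[1], 2.9)
  expect_equal(st$sd_distance[1], 0)
  expect_true(is.na(st$mean_distance[2]))
  expect_error(hbond_occupancy(ens, matrix(numeric(0), ncol = 2)), "pairs")
})

test_that("occupancy equals a brute-force recount on a noisy ensemble", {
  toy <- make_toy_complex(2, 2, seed = 51)
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames = 100, sigma = 0.6,
                                       seed = 52))
  pairs <- rbind(c(1, 9), c(2, 12), c(5, 16))
  st <- hbond_occupancy(ens, pairs, cutoff = 8.0)
  for (k in 1:3) {
    d <- vapply(ens$frames, function(fr)
      sqrt(sum((fr[pairs[k, 1], ] - fr[pairs[k, 2], ])^2)), numeric(1))
    q <- d < 8.0
    expect_equal(st$occupancy_pct[k], 100 * sum(q) / length(d))
    if (any(q)) {
      expect_equal(st$mean_distance[k], mean(d[q]))
      expect_equal(st$sd_distance[k], sd(d[q]))
      expect_lt(st$mean_distance[k], 8.0)
    }
  }
})

test_that("occupancy never increases as the cutoff tightens", {
  toy <- make_toy_complex(2, 1, seed = 61)
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames = 60, sigma = 0.8, seed = 62))
  pairs <- rbind(c(1, 9), c(3, 10), c(4, 11))
  cuts <- c(12, 9, 7, 5, 3.5, 2)
  occ <- sapply(cuts, function(cc)
    hbond_occupancy(ens, pairs, cutoff = cc)$occupancy_pct)
  for (k in seq_len(nrow(occ)))
    expect_true(all(diff(occ[k, ]) <= 0))
})

test_that("stable_interactions filters, orders, and handles over-cutoff rows", {
  st <- data.frame(donor = c("B", "A", "C"), acceptor = c("x", "y", "z"),
                   occupancy_pct = c(80, 55, 20),
                   mean_distance = c(3.0, 3.8, 2.9),
                   sd_distance = c(0.1, 0.2, 0.1))
  attr(st, "cutoff") <- 3.5
  kept <- stable_interactions(st, threshold = 50)
  expect_equal(kept$donor, "B")           # A is stable but over-cutoff
  kept2 <- stable_interactions(st, threshold = 50, include_over_cutoff = TRUE)
  expect_equal(kept2$donor, c("A", "B"))  # deterministic (donor, acceptor) order
})

test_that("hydrophobic contacts demand carbon atoms and use the 4.5 A cutoff", {
  sys <- tiny_system(rbind(c(0, 0, 0), c(4.2, 0, 0), c(9, 0, 0)),
                     charges = c(0, 0, 0), names = c("CA", "CB", "N"))
  frames <- replicate(10, sys$xyz, simplify = FALSE)
  ens <- snapshot_ensemble(sys, frames)
  cc <- hydrophobic_contacts(ens, rbind(c(1, 2)))
  expect_equal(cc$occupancy_pct, 100)
  expect_equal(cc$mean_distance, 4.2)
  expect_error(hydrophobic_contacts(ens, rbind(c(1, 3))), "carbon")
})

test_that("candidate enumeration is a superset of qualifying pairs", {
  toy <- make_toy_complex(3, 2,
                          contacts = data.frame(distance = 2.9,
                                                receptor_charge = 0.5,
                                                ligand_charge = -0.5),
                          seed = 71)
  ens <- make_ensemble(toy$system,
                       ensemble_recipe(n_frames = 30, sigma = 0.3, seed = 72))
  cand <- enumerate_candidate_pairs(ens, toy$partition, max_distance = 5.0,
                                    kind = "hbond")
  expect_gt(nrow(cand), 0)
  # brute force: every polar receptor-ligand pair ever inside 3.5 A must be
  # among the candidates screened at 5.0 A
  sys <- ens$system
  el <- sys$atoms$element
  polar <- which(el %in% c("N", "O"))
  rec <- intersect(toy$partition$receptor, polar)
  lig <- intersect(toy$partition$ligand, polar)
  seen <- paste(cand[, 1], cand[, 2])
  for (i in rec) for (j in lig) {
    dmin <- min(vapply(ens$frames, function(fr)
      sqrt(sum((fr[i, ] - fr[j, ])^2)), numeric(1)))
    if (dmin < 3.5) {
      expect_true(paste(i, j) %in% seen,
                  label = sprintf("pair %d-%d (dmin %.2f) screened", i, j, dmin))
    }
  }
})
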