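# Independent numerical oracles used across the suite. These deliberately
# re-derive quantities by brute force (loops, quadrature, grid searches)
# rather than calling the package's vectorised implementations.

# --- pairwise energy oracles ------------------------------------------------

oracle_coulomb <- function(coords, charges, kC = 332.0636, eps = 1,
                           weights = NULL) {
  n <- nrow(coords)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- if (is.null(weights)) 1 else weights[[paste(i, j)]]
    if (is.null(w)) w <- 1
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e <- e + w * kC * charges[i] * charges[j] / (eps * r)
  }
  e
}

oracle_lj <- function(coords, eps_v, rmin_half, weights = NULL) {
  n <- nrow(coords)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- if (is.null(weights)) 1 else weights[[paste(i, j)]]
    if (is.null(w)) w <- 1
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    eij <- sqrt(eps_v[i] * eps_v[j])
    rm <- rmin_half[i] + rmin_half[j]
    e <- e + w * eij * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# Still's pairwise GB sum, written out term by term.
oracle_still <- function(coords, charges, R, eps_in, eps_out,
                         kC = 332.0636) {
  n <- nrow(coords)
  tau <- 1 / eps_in - 1 / eps_out
  e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((coords[i, ] - coords[j, ])^2)
    f <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    e <- e - 0.5 * kC * tau * charges[i] * charges[j] / f
  }
  e
}

# Volume quadrature of the descreening integral (1/4pi) Int |x|^-4 dV over
# the neighbour sphere (radius s at distance r), excluding the core r < rho.
oracle_descreen <- function(r, rho, s, h = 0.035) {
  g <- seq(-s, s, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  keep <- rowSums(pts^2) <= s^2
  pts <- pts[keep, , drop = FALSE]
  pts[, 1] <- pts[, 1] + r              # neighbour centre on the x axis
  d2 <- rowSums(pts^2)
  d2 <- d2[d2 >= rho^2]
  sum(1 / d2^2) * h^3 / (4 * pi)
}

# Exposed area of sphere 1 (radius R1) partially buried by sphere 2
# (radius R2) at centre distance d: full area minus the spherical cap.
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  cosal <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  h <- R1 * (1 - cosal)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# --- rigid-body superposition oracle ---------------------------------------

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Brute-force minimum RMSD over rotations: coarse random-quaternion grid,
# then Nelder-Mead refinement of the best cell.
oracle_min_rmsd <- function(mobile, reference, n_grid = 4000, seed = 99) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  val <- function(q) {
    rot <- quat_to_rot(q)
    sqrt(mean(rowSums((m0 %*% t(rot) - r0)^2)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  best <- qs[which.min(apply(qs, 1, val)), ]
  opt <- optim(best, val, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# --- misc helpers -----------------------------------------------------------

# A tiny fully parameterized system built by hand (no generator involved).
tiny_system <- function(coords, charges, eps = NULL, rmin_half = NULL,
                        gb_radius = NULL, bonds = NULL, angles = NULL,
                        names = NULL) {
  n <- nrow(coords)
  atoms <- data.frame(
    serial = seq_len(n),
    name = if (is.null(names)) rep("CA", n) else names,
    resname = "TOY", resid = seq_len(n), chain = "A",
    element = NA_character_,
    charge = charges,
    lj_epsilon = if (is.null(eps)) rep(0.1, n) else eps,
    lj_rmin_half = if (is.null(rmin_half)) rep(1.7, n) else rmin_half,
    gb_radius = if (is.null(gb_radius)) rep(1.5, n) else gb_radius,
    stringsAsFactors = FALSE)
  molecular_system(atoms, coords, bonds = bonds, angles = angles)
}

rand_coords <- function(n, spread = 4, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  out <- matrix(runif(3 * n, -spread, spread), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}
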