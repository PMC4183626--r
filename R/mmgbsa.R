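#' Generalized-Born / surface-area settings
#'
#' All tunables of the implicit-solvent rescoring model in one place.
#' Defaults: water dielectric 78.5 over solute dielectric 1.0; electrostatic
#' constant 332.0636 kcal A / (mol e^2); solvent probe 1.4 A; nonpolar
#' surface tension 0.00542 kcal/mol/A^2 with zero offset; OBC-II rescaling
#' (alpha 1.0, beta 0.8, gamma 4.85) with a 0.09 A intrinsic-radius offset.
#'
#' @param eps_solvent solvent dielectric constant (> eps_solute).
#' @param eps_solute solute interior dielectric (>= 1).
#' @param coulomb_constant kcal A / (mol e^2).
#' @param probe_radius SASA probe radius, Angstrom.
#' @param surface_tension nonpolar coefficient gamma, kcal/mol/A^2.
#' @param nonpolar_offset additive constant b in `gamma * SASA + b`, kcal/mol.
#' @param obc_alpha,obc_beta,obc_gamma OBC tanh-rescaling coefficients.
#' @param radius_offset intrinsic Born radius offset, Angstrom.
#' @param sasa_points quadrature points per atom for Shrake-Rupley SASA.
#' @param default_screen HCT screening factor for elements not in
#'   `screen_by_element`.
#' @param screen_by_element named vector of per-element HCT descreening
#'   scaling factors.
#' @return object of class `gb_settings`.
#' @export
gb_settings <- function(eps_solvent = 78.5, eps_solute = 1.0,
                        coulomb_constant = 332.0636,
                        probe_radius = 1.4,
                        surface_tension = 0.00542, nonpolar_offset = 0.0,
                        obc_alpha = 1.0, obc_beta = 0.8, obc_gamma = 4.85,
                        radius_offset = 0.09,
                        sasa_points = 512L,
                        default_screen = 0.80,
                        screen_by_element = c(H = 0.85, C = 0.72, N = 0.79,
                                              O = 0.85, S = 0.96, P = 0.86)) {
  if (!(eps_solvent > eps_solute) || eps_solute < 1)
    stop("require eps_solvent > eps_solute >= 1")
  if (probe_radius < 0 || surface_tension < 0 || sasa_points < 8L)
    stop("invalid SASA settings")
  structure(list(eps_solvent = eps_solvent, eps_solute = eps_solute,
                 coulomb_constant = coulomb_constant,
                 probe_radius = probe_radius,
                 surface_tension = surface_tension,
                 nonpolar_offset = nonpolar_offset,
                 obc_alpha = obc_alpha, obc_beta = obc_beta,
                 obc_gamma = obc_gamma, radius_offset = radius_offset,
                 sasa_points = as.integer(sasa_points),
                 default_screen = default_screen,
                 screen_by_element = screen_by_element),
            class = "gb_settings")
}

#' Bundle energy components
#'
#' The five-term decomposition of a (binding) energy plus the entropy slot.
#' The entropy term is carried for completeness but fixed at zero in this
#' implementation: for closely related complexes its change is assumed to
#' cancel in relative comparisons. `total` is always the exact sum
#' `e_internal + e_elect + e_vdw + g_polar + g_nonpolar - ts_entropy`.
#'
#' @param e_internal,e_elect,e_vdw,g_polar,g_nonpolar component energies,
#'   kcal/mol.
#' @param ts_entropy must be 0.
#' @return object of class `energy_components`.
#' @export
energy_components <- function(e_internal = 0, e_elect = 0, e_vdw = 0,
                              g_polar = 0, g_nonpolar = 0, ts_entropy = 0) {
  if (!identical(ts_entropy, 0) && ts_entropy != 0)
    stop("ts_entropy is carried but fixed at zero in this implementation")
  structure(list(e_internal = e_internal, e_elect = e_elect, e_vdw = e_vdw,
                 g_polar = g_polar, g_nonpolar = g_nonpolar,
                 ts_entropy = ts_entropy,
                 total = e_internal + e_elect + e_vdw + g_polar + g_nonpolar -
                   ts_entropy),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf(paste0("<energy_components> total %.3f kcal/mol ",
                     "(int %.3f, elec %.3f, vdw %.3f, polar %.3f, ",
                     "nonpolar %.3f)\n"),
              x$total, x$e_internal, x$e_elect, x$e_vdw, x$g_polar,
              x$g_nonpolar))
  invisible(x)
}

# Arithmetic on components: used for complex - receptor - ligand.
ec_minus <- function(a, b) {
  energy_components(a$e_internal - b$e_internal, a$e_elect - b$e_elect,
                    a$e_vdw - b$e_vdw, a$g_polar - b$g_polar,
                    a$g_nonpolar - b$g_nonpolar)
}

# ---------------------------------------------------------------------------
# Molecular-mechanics terms
# ---------------------------------------------------------------------------

#' Internal (bonded) energy
#'
#' Harmonic bonds `kb (b - b0)^2`, harmonic angles `ktheta (theta - theta0)^2`
#' (theta0 in degrees, evaluated in radians) and cosine dihedrals
#' `kphi (1 + cos(n phi - delta))`. CHARMM-style force constants with the
#' factor of 1/2 absorbed into k.
#'
#' @param system a parameterized `molsys`.
#' @param coords N x 3 coordinates (default: the system's own).
#' @param indices restrict to bonded terms whose atoms all lie in this set.
#' @return energy in kcal/mol.
#' @export
bonded_energy <- function(system, coords = system$xyz,
                          indices = seq_len(n_atoms(system))) {
  coords <- as.matrix(coords)
  e <- 0
  inset <- function(...) {
    cols <- list(...)
    Reduce(`&`, lapply(cols, function(v) v %in% indices))
  }
  b <- system$bonds
  if (NROW(b)) {
    b <- b[inset(b$i, b$j), , drop = FALSE]
    if (nrow(b)) {
      if (anyNA(b$kb) || anyNA(b$b0)) stop("bond parameters missing")
      d <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
      r <- sqrt(rowSums(d * d))
      e <- e + sum(b$kb * (r - b$b0)^2)
    }
  }
  a <- system$angles
  if (NROW(a)) {
    a <- a[inset(a$i, a$j, a$k), , drop = FALSE]
    if (nrow(a)) {
      if (anyNA(a$ktheta) || anyNA(a$theta0)) stop("angle parameters missing")
      v1 <- coords[a$i, , drop = FALSE] - coords[a$j, , drop = FALSE]
      v2 <- coords[a$k, , drop = FALSE] - coords[a$j, , drop = FALSE]
      cth <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
      th <- acos(pmin(1, pmax(-1, cth)))
      e <- e + sum(a$ktheta * (th - a$theta0 * pi / 180)^2)
    }
  }
  d4 <- system$dihedrals
  if (NROW(d4)) {
    d4 <- d4[inset(d4$i, d4$j, d4$k, d4$l), , drop = FALSE]
    if (nrow(d4)) {
      if (anyNA(d4$kphi) || anyNA(d4$n) || anyNA(d4$delta))
        stop("dihedral parameters missing")
      phi <- dihedral_angle(coords, d4$i, d4$j, d4$k, d4$l)
      e <- e + sum(d4$kphi * (1 + cos(d4$n * phi - d4$delta * pi / 180)))
    }
  }
  e
}

# Signed dihedral angles (radians) for index vectors i-j-k-l.
dihedral_angle <- function(coords, i, j, k, l) {
  b1 <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  b2 <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  b3 <- coords[l, , drop = FALSE] - coords[k, , drop = FALSE]
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2 * b2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Coulomb energy
#'
#' `sum kC qi qj / (eps r_ij)` over the supplied pair list (no distance
#' cutoff: the gas-phase molecular-mechanics convention for end-state
#' rescoring). Pair weights carry 1-4 scaling; 1-2/1-3 pairs are expected to
#' be absent (see [nonbonded_pairs()]).
#'
#' @param coords N x 3 coordinates, Angstrom.
#' @param charges partial charges, e.
#' @param pairs list `(i, j, w)` as from [nonbonded_pairs()], or `NULL` for
#'   all distinct pairs at weight 1.
#' @param eps relative dielectric (default 1, vacuum MM convention).
#' @param coulomb_constant kcal A / (mol e^2).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, charges, pairs = NULL, eps = 1,
                           coulomb_constant = 332.0636) {
  coords <- as.matrix(coords)
  if (is.null(pairs)) pairs <- all_pairs(nrow(coords))
  if (!length(pairs$i)) return(0)
  d <- coords[pairs$i, , drop = FALSE] - coords[pairs$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-9))
    stop("coincident atoms in an interacting pair (r = 0): Coulomb singularity")
  sum(pairs$w * coulomb_constant * charges[pairs$i] * charges[pairs$j] /
        (eps * r))
}

all_pairs <- function(n) {
  if (n < 2L) return(list(i = integer(0), j = integer(0), w = numeric(0)))
  cmb <- utils::combn(n, 2L)
  list(i = cmb[1L, ], j = cmb[2L, ], w = rep(1.0, ncol(cmb)))
}

#' Lennard-Jones energy
#'
#' `sum eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with Lorentz-Berthelot
#' style combining from per-atom parameters: `eps_ij = sqrt(eps_i eps_j)`,
#' `rmin_ij = rmin_half_i + rmin_half_j`.
#'
#' @param coords N x 3 coordinates, Angstrom.
#' @param lj_epsilon per-atom well depths, kcal/mol.
#' @param lj_rmin_half per-atom half distances at the pair minimum, Angstrom.
#' @param pairs as in [coulomb_energy()].
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(coords, lj_epsilon, lj_rmin_half, pairs = NULL) {
  coords <- as.matrix(coords)
  if (is.null(pairs)) pairs <- all_pairs(nrow(coords))
  if (!length(pairs$i)) return(0)
  d <- coords[pairs$i, , drop = FALSE] - coords[pairs$j, , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-9))
    stop("coincident atoms in an interacting pair (r = 0): LJ singularity")
  epsij <- sqrt(lj_epsilon[pairs$i] * lj_epsilon[pairs$j])
  rmin <- lj_rmin_half[pairs$i] + lj_rmin_half[pairs$j]
  s6 <- (rmin / r)^6
  sum(pairs$w * epsij * (s6 * s6 - 2 * s6))
}

# ---------------------------------------------------------------------------
# Generalized Born (OBC-II over HCT pairwise descreening, Still's f_GB)
# ---------------------------------------------------------------------------

# HCT pairwise descreening integral H(r, rho, s): contribution of a
# descreening sphere of (scaled) radius s at distance r to the inverse-Born
# integral of an atom of offset radius rho. Closed form of
# (1/4pi) * Int_{sphere} |x|^-4 dV over the part outside radius rho.
hct_integral <- function(r, rho, s) {
  H <- numeric(length(r))
  engulfed_i <- s >= r + rho      # atom i buried inside neighbour sphere
  outside <- rho >= r + s         # neighbour buried inside atom i: no term
  active <- !outside
  if (any(active)) {
    ra <- r[active]; sa <- s[active]
    L <- pmax(abs(ra - sa), rho[active])
    U <- ra + sa
    H[active] <- 0.5 * ((1 / L - 1 / U) +
                        0.25 * (ra - sa^2 / ra) * (1 / U^2 - 1 / L^2) +
                        0.5 / ra * log(L / U))
    eng <- engulfed_i[active]
    if (any(eng))
      H[active][eng] <- H[active][eng] +
        2 * (1 / rho[active][eng] - 1 / L[eng])
  }
  H
}

#' Effective Born radii (OBC-II)
#'
#' Pairwise-descreening effective radii: the Hawkins-Cramer-Truhlar
#' descreening integral over scaled neighbour spheres, rescaled through the
#' OBC tanh formula `1/R_i = 1/rho_i - tanh(a P - b P^2 + c P^3) / radius_i`
#' with `rho_i = radius_i - offset` and `P = rho_i * I_i`. An isolated atom
#' has effective radius equal to its offset-corrected intrinsic radius.
#'
#' @param coords N x 3 coordinates, Angstrom.
#' @param gb_radii intrinsic Born radii, Angstrom (> 0).
#' @param settings a [gb_settings()].
#' @param screen per-atom HCT screening factors; default derived from
#'   elements via `settings$screen_by_element` (`elements` argument), or
#'   `settings$default_screen` when unknown.
#' @param elements element symbols used to look up default screening.
#' @return per-atom effective Born radii, Angstrom.
#' @export
effective_born_radii <- function(coords, gb_radii, settings = gb_settings(),
                                 screen = NULL, elements = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (any(gb_radii <= 0)) stop("intrinsic Born radii must be > 0")
  if (is.null(screen)) {
    screen <- rep(settings$default_screen, n)
    if (!is.null(elements)) {
      m <- settings$screen_by_element[elements]
      screen[!is.na(m)] <- m[!is.na(m)]
    }
  }
  rho <- gb_radii - settings$radius_offset
  if (any(rho <= 0))
    stop("radius_offset leaves non-positive offset radii")
  if (n == 1L) return(rho)
  dm <- as.matrix(stats::dist(coords))
  if (any(dm[upper.tri(dm)] < 1e-9))
    stop("overlapping identical centers: Born radii undefined")
  I <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    I[i] <- sum(hct_integral(dm[i, j], rep(rho[i], length(j)),
                             screen[j] * rho[j]))
  }
  psi <- rho * I
  inv <- 1 / rho - tanh(settings$obc_alpha * psi -
                        settings$obc_beta * psi^2 +
                        settings$obc_gamma * psi^3) / gb_radii
  if (any(inv <= 0))
    stop("negative effective Born radius: geometry outside model validity")
  1 / inv
}

#' Generalized-Born polar solvation energy (Still's pairwise form)
#'
#' `-(1/2) kC (1/eps_in - 1/eps_out) sum_ij qi qj / f_GB` over all ordered
#' pairs including the `i = j` self (Born) terms, with
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))`.
#'
#' @param coords N x 3 coordinates, Angstrom.
#' @param charges partial charges, e.
#' @param born_radii effective Born radii from [effective_born_radii()].
#' @param settings a [gb_settings()].
#' @return energy in kcal/mol.
#' @export
gb_polar_energy <- function(coords, charges, born_radii,
                            settings = gb_settings()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  tau <- 1 / settings$eps_solute - 1 / settings$eps_solvent
  pref <- -0.5 * settings$coulomb_constant * tau
  e <- sum(charges^2 / born_radii)          # self terms: f_GB(0) = R_i
  if (n > 1L) {
    cmb <- utils::combn(n, 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r2 <- rowSums(d * d)
    RiRj <- born_radii[i] * born_radii[j]
    fgb <- sqrt(r2 + RiRj * exp(-r2 / (4 * RiRj)))
    e <- e + 2 * sum(charges[i] * charges[j] / fgb)
  }
  pref * e
}

# ---------------------------------------------------------------------------
# SASA (Shrake-Rupley spherical quadrature)
# ---------------------------------------------------------------------------

# Deterministic quasi-uniform unit-sphere point set (golden-spiral /
# Fibonacci lattice).
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * k
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Spherical quadrature on each atom's expanded sphere (radius + probe): the
#' accessible fraction is the fraction of quadrature points not buried in
#' any neighbour's expanded sphere. The point set is deterministic for a
#' fixed point count.
#'
#' @param coords N x 3 coordinates, Angstrom.
#' @param radii per-atom radii, Angstrom (van der Waals-like; the intrinsic
#'   Born radii serve this role in [snapshot_binding()]).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 512).
#' @return per-atom accessible areas, Angstrom^2 (sum for the total).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 512L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("radii length != atom count")
  pts <- sphere_points(n_points)
  R <- radii + probe
  areas <- numeric(n)
  dm <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < R[i] + R & seq_len(n) != i)
    p <- sweep(pts * R[i], 2L, coords[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        d <- sweep(p, 2L, coords[j, ], "-")
        free <- free & rowSums(d * d) > R[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    } else acc <- n_points
    areas[i] <- 4 * pi * R[i]^2 * acc / n_points
  }
  areas
}

#' Nonpolar solvation energy from total SASA
#'
#' `gamma * SASA + b` with the surface tension and offset from the settings.
#'
#' @param total_sasa total accessible area, Angstrom^2.
#' @param settings a [gb_settings()].
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(total_sasa, settings = gb_settings()) {
  settings$surface_tension * total_sasa + settings$nonpolar_offset
}

# ---------------------------------------------------------------------------
# Snapshot and ensemble binding energies (single-trajectory protocol)
# ---------------------------------------------------------------------------

# Score one subsystem (set of atom indices) at the given coordinates.
score_subsystem <- function(system, coords, indices, settings,
                            excl = exclusion_info(system)) {
  a <- system$atoms
  if (anyNA(a$charge[indices]) || anyNA(a$lj_epsilon[indices]) ||
      anyNA(a$gb_radius[indices]))
    stop("system is not fully parameterized; run merge_parameters() first")
  sub <- coords[indices, , drop = FALSE]
  prs <- nonbonded_pairs(system, indices, excl)
  loc <- match(prs$i, indices); locj <- match(prs$j, indices)
  pairs <- list(i = loc, j = locj, w = prs$w)
  q <- a$charge[indices]
  e_int <- bonded_energy(system, coords, indices)
  e_el <- coulomb_energy(sub, q, pairs, eps = settings$eps_solute,
                         coulomb_constant = settings$coulomb_constant)
  e_vdw <- lj_energy(sub, a$lj_epsilon[indices], a$lj_rmin_half[indices],
                     pairs)
  br <- effective_born_radii(sub, a$gb_radius[indices], settings,
                             screen = if (all(is.na(a$gb_screen[indices])))
                               NULL else a$gb_screen[indices],
                             elements = a$element[indices])
  g_pol <- gb_polar_energy(sub, q, br, settings)
  ar <- sasa(sub, a$gb_radius[indices], probe = settings$probe_radius,
             n_points = settings$sasa_points)
  g_np <- nonpolar_energy(sum(ar), settings)
  energy_components(e_int, e_el, e_vdw, g_pol, g_np)
}

#' Binding energy components for one snapshot
#'
#' Single-trajectory protocol: complex, receptor and ligand are all scored
#' on coordinates extracted from the same frame, and the binding components
#' are `X(complex) - X(receptor) - X(ligand)`. Because the internal
#' coordinates of each side are identical in all three evaluations,
#' `e_internal` cancels exactly (and is asserted to).
#'
#' @param frame N x 3 coordinates of the complex.
#' @param system a parameterized `molsys`.
#' @param partition a `partition`; its union defines the scored subsystem.
#' @param settings a [gb_settings()].
#' @return an [energy_components()] of binding (Delta) values.
#' @export
snapshot_binding <- function(frame, system, partition,
                             settings = gb_settings()) {
  stopifnot(inherits(system, "molsys"), inherits(partition, "partition"))
  frame <- as.matrix(frame)
  if (nrow(frame) != n_atoms(system))
    stop("frame/topology mismatch: ", nrow(frame), " coordinate rows for ",
         n_atoms(system), " atoms")
  if (max(partition$receptor, partition$ligand) > n_atoms(system))
    stop("partition indices out of range for this topology")
  excl <- exclusion_info(system)
  both <- sort(c(partition$receptor, partition$ligand))
  cx <- score_subsystem(system, frame, both, settings, excl)
  rc <- score_subsystem(system, frame, partition$receptor, settings, excl)
  lg <- score_subsystem(system, frame, partition$ligand, settings, excl)
  d <- ec_minus(ec_minus(cx, rc), lg)
  # bonded terms never cross the partition, so this cancels identically;
  # enforce exactness rather than carry rounding noise
  if (abs(d$e_internal) > 1e-9)
    stop("bonded terms cross the receptor/ligand partition")
  energy_components(0, d$e_elect, d$e_vdw, d$g_polar, d$g_nonpolar)
}

#' Ensemble-averaged binding energy with component decomposition
#'
#' Applies [snapshot_binding()] over a deterministic uniform selection of
#' frames and reports per-component mean and standard deviation (the
#' per-snapshot SD, not the standard error).
#'
#' @param ensemble an `ensemble`.
#' @param partition a `partition`.
#' @param settings a [gb_settings()].
#' @param stride keep every `stride`-th frame (default 1).
#' @param first_frame first frame used (default 1); set past the
#'   equilibration span when frames include it.
#' @param n_snapshots optionally, a target snapshot count: frames are chosen
#'   at the uniform stride that reaches (at most) this count. Overrides
#'   `stride`.
#' @return object of class `binding_summary`: list with `per_snapshot` (data
#'   frame of components per frame), `mean`, `sd`, `n_snapshots`, and the
#'   selection metadata.
#' @export
ensemble_binding <- function(ensemble, partition, settings = gb_settings(),
                             stride = 1L, first_frame = 1L,
                             n_snapshots = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  avail <- seq(first_frame, n_frames(ensemble))
  if (!length(avail)) stop("no frames after first_frame")
  if (!is.null(n_snapshots)) {
    stride <- max(1L, floor(length(avail) / n_snapshots))
  }
  use <- avail[seq(1L, length(avail), by = stride)]
  if (!is.null(n_snapshots)) use <- head(use, n_snapshots)
  comps <- lapply(use, function(f)
    snapshot_binding(ensemble$frames[[f]], ensemble$system, partition,
                     settings))
  per <- data.frame(
    frame = use, time_ps = ensemble$time_ps[use],
    e_internal = vapply(comps, `[[`, numeric(1), "e_internal"),
    e_elect = vapply(comps, `[[`, numeric(1), "e_elect"),
    e_vdw = vapply(comps, `[[`, numeric(1), "e_vdw"),
    g_polar = vapply(comps, `[[`, numeric(1), "g_polar"),
    g_nonpolar = vapply(comps, `[[`, numeric(1), "g_nonpolar"),
    total = vapply(comps, `[[`, numeric(1), "total"))
  cols <- c("e_internal", "e_elect", "e_vdw", "g_polar", "g_nonpolar", "total")
  structure(list(per_snapshot = per,
                 mean = colMeans(per[cols]),
                 sd = vapply(per[cols], sd, numeric(1)),
                 n_snapshots = nrow(per), stride = stride,
                 first_frame = first_frame),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("<binding_summary> n = %d snapshots, dG = %.2f +/- %.2f kcal/mol\n",
              x$n_snapshots, x$mean[["total"]], x$sd[["total"]]))
  invisible(x)
}

#' Relative binding free energies versus a reference system
#'
#' `ddG(i) = mean_total(i) - mean_total(reference)`; the reference maps to
#' exactly 0.
#'
#' @param summaries named list of `binding_summary` objects, or a data frame
#'   with columns `system` and `dg_mean`.
#' @param reference_name name of the reference system.
#' @return data frame `(system, dg_mean, ddg)`.
#' @export
relative_ddg <- function(summaries, reference_name) {
  if (is.data.frame(summaries)) {
    df <- data.frame(system = summaries$system, dg_mean = summaries$dg_mean,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(system = names(summaries),
                     dg_mean = vapply(summaries, function(s)
                       s$mean[["total"]], numeric(1)),
                     stringsAsFactors = FALSE)
  }
  if (!reference_name %in% df$system)
    stop("reference system '", reference_name, "' not among summaries")
  ref <- df$dg_mean[df$system == reference_name][1L]
  df$ddg <- df$dg_mean - ref
  df
}
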