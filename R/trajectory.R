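#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between the
#' fit atoms of a mobile frame and a reference frame.
#'
#' @param mobile,reference N x 3 coordinate matrices with matching atom order.
#' @param fit_indices atom indices used for the fit (default: all); at least
#'   three non-collinear atoms.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   `rmsd_fit` (Angstrom over the fit atoms), and `transform(coords)`
#'   applying the fit to arbitrary coordinates.
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L)
    stop("need at least 3 fit atoms")
  m <- mobile[fit_indices, , drop = FALSE]
  r <- reference[fit_indices, , drop = FALSE]
  cm <- colMeans(m); cr <- colMeans(r)
  m0 <- sweep(m, 2L, cm); r0 <- sweep(r, 2L, cr)
  s <- svd(crossprod(m0, r0))
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1e-300))
    stop("degenerate (collinear) fit geometry: superposition is ill-defined")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - as.vector(cm %*% rot)
  fitted <- sweep(m %*% rot, 2L, trans, "+")
  rmsd_fit <- sqrt(mean(rowSums((fitted - r)^2)))
  list(rotation = rot, translation = trans, rmsd_fit = rmsd_fit,
       transform = function(coords)
         sweep(as.matrix(coords) %*% rot, 2L, trans, "+"))
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' Each frame is first superposed on the reference over the selection, then
#' the RMSD over the same selection is reported. The default reference is
#' the first frame (by convention, the first post-equilibration snapshot).
#'
#' @param ensemble an `ensemble`.
#' @param reference_frame frame index used as reference (default 1).
#' @param selection [select_atoms()] expression; default `"backbone"`
#'   (atoms named N, CA, C, O).
#' @return data frame `(time_ps, rmsd)` in Angstrom.
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L,
                        selection = "backbone") {
  stopifnot(inherits(ensemble, "ensemble"))
  sel <- select_atoms(ensemble$system, selection)
  if (!length(sel)) stop("selection '", selection, "' matches no atoms")
  ref <- ensemble$frames[[reference_frame]]
  rmsd <- vapply(ensemble$frames, function(fr)
    superpose(fr, ref, sel)$rmsd_fit, numeric(1))
  data.frame(time_ps = ensemble$time_ps, rmsd = rmsd)
}

# Distances for a set of atom pairs in every frame: matrix frames x pairs.
pair_distance_matrix <- function(ensemble, pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  res <- vapply(ensemble$frames, function(fr) {
    d <- fr[pairs[, 1L], , drop = FALSE] - fr[pairs[, 2L], , drop = FALSE]
    sqrt(rowSums(d * d))
  }, numeric(nrow(pairs)))
  # vapply collapses a single pair to a plain vector; keep frames as rows
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
}

#' Hydrogen-bond occupancy statistics over an ensemble
#'
#' A donor-acceptor heavy-atom pair counts as hydrogen bonded in a frame
#' when its distance is below `cutoff`. Occupancy is the percentage of all
#' frames bonded; the conditional mean and SD distance are computed over the
#' bonded (qualifying) frames only — two deliberately different denominators.
#'
#' @param ensemble an `ensemble`.
#' @param candidate_pairs two-column matrix or data frame of atom indices
#'   (donor heavy atom, acceptor heavy atom).
#' @param cutoff donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @return data frame of class `hbond_stats`: `donor`, `acceptor` (labels),
#'   `donor_idx`, `acceptor_idx`, `occupancy_pct`, `mean_distance`,
#'   `sd_distance` (NA when no frame qualifies), `n_frames`.
#' @export
hbond_occupancy <- function(ensemble, candidate_pairs, cutoff = 3.5) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (!n_frames(ensemble)) stop("ensemble has no frames")
  pairs <- as.matrix(as.data.frame(candidate_pairs)[, 1:2])
  if (!nrow(pairs)) stop("no candidate pairs supplied")
  dm <- pair_distance_matrix(ensemble, pairs)
  nf <- nrow(dm)
  stat_one <- function(k) {
    d <- dm[, k]
    q <- d < cutoff
    c(occ = 100 * sum(q) / nf,
      mu = if (any(q)) mean(d[q]) else NA_real_,
      sig = if (any(q)) sd(d[q]) else NA_real_)
  }
  s <- t(vapply(seq_len(nrow(pairs)), stat_one, numeric(3)))
  out <- data.frame(
    donor = atom_labels(ensemble$system, pairs[, 1L]),
    acceptor = atom_labels(ensemble$system, pairs[, 2L]),
    donor_idx = pairs[, 1L], acceptor_idx = pairs[, 2L],
    occupancy_pct = s[, "occ"], mean_distance = s[, "mu"],
    sd_distance = s[, "sig"], n_frames = nf,
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("hbond_stats", class(out))
  out
}

#' Keep only stable interactions
#'
#' Filters occupancy statistics to those present at least `threshold` percent
#' of the time, ordered deterministically by (donor, acceptor) label.
#'
#' @param stats output of [hbond_occupancy()] or [hydrophobic_contacts()].
#' @param threshold occupancy threshold in percent (default 50).
#' @param include_over_cutoff if `FALSE` (default) rows whose conditional
#'   mean distance exceeds the cutoff they were computed with are dropped;
#'   set `TRUE` to keep them for comparison.
#' @export
stable_interactions <- function(stats, threshold = 50,
                                include_over_cutoff = FALSE) {
  out <- stats[!is.na(stats$occupancy_pct) & stats$occupancy_pct >= threshold, ]
  cutoff <- attr(stats, "cutoff")
  if (!include_over_cutoff && !is.null(cutoff))
    out <- out[is.na(out$mean_distance) | out$mean_distance < cutoff, ]
  out <- out[order(out$donor, out$acceptor), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Hydrophobic carbon-carbon contact statistics
#'
#' Same occupancy machinery as [hbond_occupancy()] with a carbon-carbon
#' distance criterion (default cutoff 4.5 Angstrom); only pairs of carbon
#' atoms are admitted.
#'
#' @param ensemble an `ensemble`.
#' @param carbon_pairs two-column matrix of carbon atom indices.
#' @param cutoff C-C distance cutoff in Angstrom (default 4.5).
#' @param stability_threshold occupancy threshold for the returned stable
#'   set, percent (default 50).
#' @return filtered `hbond_stats`-style data frame of stable contacts.
#' @export
hydrophobic_contacts <- function(ensemble, carbon_pairs, cutoff = 4.5,
                                 stability_threshold = 50) {
  pairs <- as.matrix(as.data.frame(carbon_pairs)[, 1:2])
  el <- ensemble$system$atoms$element
  bad <- el[pairs[, 1L]] != "C" | el[pairs[, 2L]] != "C"
  if (any(bad))
    stop("hydrophobic contacts are defined between carbon atoms only; ",
         sum(bad), " pair(s) involve non-carbon atoms")
  stats <- hbond_occupancy(ensemble, pairs, cutoff = cutoff)
  stable_interactions(stats, threshold = stability_threshold)
}

#' Enumerate candidate interaction pairs across a partition
#'
#' Pre-screens receptor-ligand atom pairs so the per-frame occupancy scan
#' does not need all-versus-all distances. A pair is kept when its distance
#' falls below `max_distance` in any examined frame. With `stride = 1`
#' (default) every frame is examined, so the result is a strict superset of
#' all pairs that ever qualify at any cutoff `<= max_distance`; a larger
#' stride is faster but can miss pairs that only approach between examined
#' frames.
#'
#' @param ensemble an `ensemble`.
#' @param partition a `partition`.
#' @param max_distance screening distance in Angstrom; choose at least the
#'   analysis cutoff (e.g. 3.5 + slack for hydrogen bonds).
#' @param kind `"hbond"` restricts to donor/acceptor chemistry (receptor and
#'   ligand N/O atoms per the packaged chemistry table, either orientation);
#'   `"contact"` restricts to carbon-carbon pairs; `"any"` applies no
#'   chemistry filter.
#' @param stride examine every `stride`-th frame (default 1).
#' @param chemistry donor/acceptor chemistry table, as
#'   [donor_acceptor_table()].
#' @return two-column matrix of atom indices (receptor atom, ligand atom).
#' @export
enumerate_candidate_pairs <- function(ensemble, partition, max_distance,
                                      kind = c("hbond", "contact", "any"),
                                      stride = 1L,
                                      chemistry = donor_acceptor_table()) {
  kind <- match.arg(kind)
  stopifnot(inherits(ensemble, "ensemble"), inherits(partition, "partition"))
  sys <- ensemble$system
  el <- sys$atoms$element
  rec <- partition$receptor; lig <- partition$ligand
  if (kind == "contact") {
    rec <- rec[el[rec] == "C"]; lig <- lig[el[lig] == "C"]
  } else if (kind == "hbond") {
    role <- atom_roles(sys, chemistry)
    polar <- role != "none"
    rec <- rec[polar[rec]]; lig <- lig[polar[lig]]
  }
  if (!length(rec) || !length(lig))
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  grid <- expand.grid(i = rec, j = lig, KEEP.OUT.ATTRS = FALSE)
  if (kind == "hbond") {
    role <- atom_roles(sys, chemistry)
    ok <- (role[grid$i] %in% c("donor", "both") &
           role[grid$j] %in% c("acceptor", "both")) |
          (role[grid$i] %in% c("acceptor", "both") &
           role[grid$j] %in% c("donor", "both"))
    grid <- grid[ok, , drop = FALSE]
  }
  if (!nrow(grid))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  keep <- rep(FALSE, nrow(grid))
  for (f in seq(1L, n_frames(ensemble), by = stride)) {
    fr <- ensemble$frames[[f]]
    d <- fr[grid$i, , drop = FALSE] - fr[grid$j, , drop = FALSE]
    keep <- keep | sqrt(rowSums(d * d)) < max_distance
  }
  out <- as.matrix(grid[keep, , drop = FALSE])
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Donor/acceptor chemistry table
#'
#' Which heavy atoms may act as hydrogen-bond donors and acceptors. Shipped
#' as an editable TSV (`residue_name` `"*"` wildcards any residue); the
#' defaults make nitrogens donors and oxygens acceptors, with hydroxyl and
#' amide oxygens allowed both roles.
#'
#' @param path alternative TSV with columns `residue_name`, `atom_name`,
#'   `role` (donor / acceptor / both).
#' @export
donor_acceptor_table <- function(path = system.file("extdata",
                                                    "donor_acceptor_atoms.tsv",
                                                    package = "pepaffinity")) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

# Role of each atom under a chemistry table: "donor", "acceptor", "both" or
# "none". Specific (residue, atom) entries win over "*" wildcards; atoms not
# listed fall back to element defaults (N donor, O acceptor).
atom_roles <- function(system, chemistry = donor_acceptor_table()) {
  a <- system$atoms
  key <- paste(a$resname, a$name, sep = "/")
  idx <- match(key, paste(chemistry$residue_name, chemistry$atom_name, sep = "/"))
  wild <- which(is.na(idx))
  idx[wild] <- match(paste("*", a$name[wild], sep = "/"),
                     paste(chemistry$residue_name, chemistry$atom_name, sep = "/"))
  role <- chemistry$role[idx]
  role[is.na(role) & a$element == "N"] <- "donor"
  role[is.na(role) & a$element == "O"] <- "acceptor"
  role[is.na(role)] <- "none"
  role
}
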