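# Trajectory container and superposition-based metrics (RMSD, RMSF, Rg,
# group distances, DCC).

#' Construct a trajectory object
#'
#' @param topology atom data frame as in a `structure3d` (`$atoms`):
#'   columns elety, resid, chain, resno, elem, mass, radius, het at least.
#' @param coords numeric array of dimension (n_frames, n_atoms, 3), in
#'   angstrom.
#' @param times optional per-frame time stamps (ns).
#' @param replicate optional replicate identifier.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, replicate = NA) {
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3) {
    stop("coords must be an (n_frames, n_atoms, 3) array")
  }
  if (d[2] != nrow(topology)) {
    stop("coords atom count (", d[2], ") does not match topology (",
         nrow(topology), ")")
  }
  if (d[1] < 1) stop("trajectory needs at least one frame")
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords,
                 times = times, replicate = replicate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory:", d[1], "frames x", d[2], "atoms",
      if (!is.na(x$replicate)) paste0("(replicate ", x$replicate, ")"),
      "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
frame_xyz <- function(traj, t) {
  matrix(traj$coords[t, , ], ncol = 3)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; the topology is taken from the first
#' model via [read_structure()].
#'
#' @param path PDB path.
#' @param replicate optional replicate id attached to the result.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, replicate = NA) {
  s <- read_structure(path, model = 1L)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  na <- nrow(s$atoms)
  coords <- array(NA_real_, c(nf, na, 3))
  for (t in seq_len(nf)) {
    coords[t, , ] <- matrix(pdb$xyz[t, ], ncol = 3, byrow = TRUE)
  }
  trajectory(s$atoms, coords, replicate = replicate)
}

#' A time-series of one scalar metric
#'
#' @param name metric name.
#' @param values one value per frame.
#' @param units unit string (e.g. `"A"`, `"A^2"`, `"count"`).
#' @param replicate replicate id.
#' @return a `time_series` with a `summary()` giving mean and SD.
#' @export
time_series <- function(name, values, units = "", replicate = NA) {
  structure(list(name = name, values = as.numeric(values), units = units,
                 replicate = replicate),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("%s: %d frames, %.3f +/- %.3f %s\n", x$name,
              length(x$values), mean(x$values), stats::sd(x$values),
              x$units))
  invisible(x)
}

#' Summarize time series as mean +/- SD
#' @param series a `time_series` or list of them (pooled over frames).
#' @return named list: `mean`, `sd`, `n_frames`.
#' @export
series_summary <- function(series) {
  v <- if (inherits(series, "time_series")) series$values
       else unlist(lapply(series, `[[`, "values"))
  list(mean = mean(v), sd = stats::sd(v), n_frames = length(v))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rigid-body fit of `frame` onto `ref` over a subset of
#' atoms; a proper rotation (det = +1) is enforced, so mirror images are
#' not matched by reflection.
#'
#' @param frame n x 3 coordinate matrix to transform.
#' @param ref n x 3 reference coordinates.
#' @param fit_idx indices of the atoms used for the fit; default all.
#' @return list with `coords` (transformed full frame), `rotation`
#'   (3 x 3), `rmsd_fit` (RMSD over the fit atoms after superposition).
#' @export
superpose <- function(frame, ref, fit_idx = seq_len(nrow(frame))) {
  if (length(fit_idx) < 3) stop("superposition needs at least 3 fit atoms")
  A <- frame[fit_idx, , drop = FALSE]
  B <- ref[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2 || qr(Bc)$rank < 2) {
    stop("degenerate fit: selection atoms are collinear")
  }
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(frame, 2, ca) %*% t(R)
  out <- sweep(out, 2, cb, `+`)
  dev <- out[fit_idx, , drop = FALSE] - B
  list(coords = out, rotation = R, rmsd_fit = sqrt(mean(rowSums(dev^2))))
}

# atom indices for a selection spec against a topology:
# NULL -> all atoms; "ca" / "heavy" strings; residue_selection; int vector
resolve_selection <- function(topology, selection) {
  if (is.null(selection)) return(seq_len(nrow(topology)))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.character(selection) && length(selection) == 1) {
    return(switch(selection,
      ca = which(topology$elety == "CA"),
      heavy = which(!(topology$elem %in% c("H", "D"))),
      protein = which(!topology$het),
      stop("unknown selection: ", selection)))
  }
  if (inherits(selection, "residue_selection")) {
    s <- list(atoms = topology)
    return(selection_atoms(s, selection))
  }
  stop("unsupported selection specification")
}

#' RMSD time series against a reference
#'
#' Each frame is rigid-body superposed onto the reference over the
#' selection, then the RMSD over the same selection is reported.
#'
#' @param traj a [trajectory()].
#' @param ref reference coordinates: a `structure3d`, a [trajectory()]
#'   frame index, or an n x 3 matrix matching the topology.
#' @param selection atom selection (default `"ca"`).
#' @return a [time_series()] in angstrom.
#' @export
rmsd_series <- function(traj, ref = 1L, selection = "ca") {
  idx <- resolve_selection(traj$topology, selection)
  refm <- ref_coords(traj, ref)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_xyz(traj, t)
    fitted <- if (length(idx) >= 3) {
      superpose(x, refm, idx)$coords
    } else {
      # too few atoms to determine a rotation: translation-only fit
      shift <- colMeans(refm[idx, , drop = FALSE]) -
        colMeans(x[idx, , drop = FALSE])
      sweep(x, 2, shift, `+`)
    }
    dev <- fitted[idx, , drop = FALSE] - refm[idx, , drop = FALSE]
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  time_series("rmsd", vals, "A", traj$replicate)
}

ref_coords <- function(traj, ref) {
  if (inherits(ref, "structure3d")) {
    return(as.matrix(ref$atoms[, c("x", "y", "z")]))
  }
  if (is.matrix(ref)) return(ref)
  frame_xyz(traj, as.integer(ref))
}

# Superpose all frames onto the iteratively refined mean structure
# (2 refinement passes); returns (n_frames, n_sel, 3) array of the
# selection atoms only.
superposed_selection <- function(traj, idx) {
  nf <- n_frames(traj)
  sel <- array(NA_real_, c(nf, length(idx), 3))
  ref <- frame_xyz(traj, 1)[idx, , drop = FALSE]
  for (pass in 1:2) {
    for (t in seq_len(nf)) {
      sp <- superpose(frame_xyz(traj, t)[idx, , drop = FALSE], ref)
      sel[t, , ] <- sp$coords
    }
    ref <- apply(sel, c(2, 3), mean)
  }
  # final pass against the refined mean
  for (t in seq_len(nf)) {
    sp <- superpose(frame_xyz(traj, t)[idx, , drop = FALSE], ref)
    sel[t, , ] <- sp$coords
  }
  sel
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto the iteratively refined mean structure (two
#' refinement passes), then RMSF_i = sqrt(mean_t ||x_i(t) - xbar_i||^2)
#' is reported per selected atom (default one Calpha per residue).
#'
#' @param traj a [trajectory()].
#' @param selection atom selection; default `"ca"`.
#' @return data frame with `resno`, `chain`, `rmsf` (angstrom).
#' @export
rmsf_profile <- function(traj, selection = "ca") {
  if (n_frames(traj) < 2) stop("RMSF undefined for a single frame")
  idx <- resolve_selection(traj$topology, selection)
  sel <- superposed_selection(traj, idx)
  mu <- apply(sel, c(2, 3), mean)
  dev2 <- sweep(sel, c(2, 3), mu)^2
  msf <- apply(dev2, 2, mean) * 3   # mean over frames & axes, x3 = sum axes
  data.frame(resno = traj$topology$resno[idx],
             chain = traj$topology$chain[idx],
             rmsf = sqrt(msf))
}

#' Radius of gyration time series
#'
#' Rg = sqrt( sum_i m_i ||x_i - x_com||^2 / sum_i m_i ) per frame.
#'
#' @param traj a [trajectory()].
#' @param selection atom selection; default `"heavy"`.
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return a [time_series()] in angstrom.
#' @export
rg_series <- function(traj, selection = "heavy", mass_weighted = TRUE) {
  idx <- resolve_selection(traj$topology, selection)
  if (!length(idx)) stop("empty selection")
  w <- if (mass_weighted) traj$topology$mass[idx] else rep(1, length(idx))
  if (any(is.na(w)) || sum(w) <= 0) stop("zero or missing total mass")
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_xyz(traj, t)[idx, , drop = FALSE]
    com <- colSums(x * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w))
  }, numeric(1))
  time_series("rg", vals, "A", traj$replicate)
}

#' Inter-group distance time series
#'
#' Frame-internal distance between two residue groups (no superposition).
#'
#' @param traj a [trajectory()].
#' @param a,b [residue_selection()]s.
#' @param mode `"com"` (mass-weighted heavy-atom centroids) or `"ca"`.
#' @return a [time_series()] in angstrom.
#' @export
group_distance_series <- function(traj, a, b, mode = c("com", "ca")) {
  mode <- match.arg(mode)
  s <- list(atoms = traj$topology)
  ia <- selection_atoms(s, a, mode)
  ib <- selection_atoms(s, b, mode)
  if (!length(ia) || !length(ib)) {
    stop("selection resolves to zero atoms under mode '", mode, "'")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    group_distance_xyz(frame_xyz(traj, t), ia, ib, mode,
                       traj$topology$mass)
  }, numeric(1))
  time_series(paste0("dist_", mode), vals, "A", traj$replicate)
}

#' Dynamic cross-correlation matrix
#'
#' After superposing all frames to the iteratively refined mean structure,
#' DCC_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>) where dr is the
#' deviation from the time-mean position. Atoms with zero variance get
#' zero rows/columns with a warning.
#'
#' @param traj a [trajectory()] or list of replicate trajectories (frames
#'   pooled after per-replicate superposition to a common mean is not
#'   attempted; pooled frames are superposed together).
#' @param selection atom selection; default `"ca"`.
#' @return list with `dcc` (symmetric matrix in \[-1, 1\], unit diagonal
#'   for mobile atoms), `resno`.
#' @export
dcc_matrix <- function(traj, selection = "ca") {
  if (!inherits(traj, "trajectory") && is.list(traj)) {
    traj <- pool_trajectories(traj)
  }
  if (n_frames(traj) < 2) stop("DCC needs at least 2 frames")
  idx <- resolve_selection(traj$topology, selection)
  sel <- superposed_selection(traj, idx)
  nf <- dim(sel)[1]; na <- dim(sel)[2]
  C <- matrix(0, na, na)
  for (ax in 1:3) {
    X <- sel[, , ax]
    X <- sweep(X, 2, colMeans(X))
    C <- C + crossprod(X) / nf
  }
  v <- diag(C)
  zero <- v <= 1e-12
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s); rows/columns set to 0")
    v[zero] <- 1
  }
  dcc <- C / sqrt(outer(v, v))
  dcc[zero, ] <- 0; dcc[, zero] <- 0
  diag(dcc)[!zero] <- 1
  list(dcc = dcc, resno = traj$topology$resno[idx])
}

#' Pool replicate trajectories by frame concatenation
#' @param trajs list of [trajectory()]s sharing one topology.
#' @return a single [trajectory()].
#' @export
pool_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  na <- dim(trajs[[1]]$coords)[2]
  for (tr in trajs) {
    if (dim(tr$coords)[2] != na) stop("replicates differ in atom count")
  }
  nf <- sum(vapply(trajs, n_frames, integer(1)))
  coords <- array(NA_real_, c(nf, na, 3))
  at <- 0
  for (tr in trajs) {
    k <- n_frames(tr)
    coords[at + seq_len(k), , ] <- tr$coords
    at <- at + k
  }
  trajectory(trajs[[1]]$topology, coords, replicate = "pooled")
}

#' Write a time series as TSV (frame, time_ns, value)
#' @param ts a [time_series()].
#' @param path output path.
#' @param times optional time stamps (ns).
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path, times = NULL) {
  n <- length(ts$values)
  out <- data.frame(frame = seq_len(n),
                    time_ns = if (is.null(times)) NA else times,
                    value = ts$values)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
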