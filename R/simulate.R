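# Seeded synthetic-data generators with planted ground truth: coupled
# MSAs for SCA recovery, Gaussian trajectories for the dynamics metrics,
# and noisy curve tables for the biosensor fits.

#' Generate an MSA with a planted set of covarying positions
#'
#' Each sequence draws a hidden class `k` from `class_prob`; every planted
#' position emits its class-specific residue with probability `p` (else
#' uniformly one of the other 19), while non-planted positions emit
#' i.i.d. from the background. At `p = 1` the planted columns covary
#' perfectly; at `p = 1/20` they are indistinguishable from background.
#'
#' @param n_seq number of sequences.
#' @param L alignment length.
#' @param planted_set positions (1..L) of the covarying set.
#' @param p emission fidelity in \[1/20, 1\]; default 0.9.
#' @param n_classes number of hidden classes; default 2.
#' @param class_prob class probabilities; default uniform.
#' @param background length-20 background frequencies; default uniform.
#' @param seed RNG seed (one local generator; global state untouched).
#' @return list with `alignment` (an [alignment()]) and `ground_truth`
#'   (planted set, class residues, classes per sequence).
#' @export
make_coupled_msa <- function(n_seq, L, planted_set, p = 0.9, n_classes = 2,
                             class_prob = rep(1 / n_classes, n_classes),
                             background = rep(1 / 20, 20), seed = 1) {
  if (length(planted_set) > L || any(planted_set < 1 | planted_set > L)) {
    stop("planted_set must be a subset of 1..L")
  }
  if (p < 1 / 20 || p > 1) stop("p must be in [1/20, 1]")
  if (abs(sum(class_prob) - 1) > 1e-9) stop("class_prob must sum to 1")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  # class-specific residues per planted position: distinct across classes
  class_res <- t(vapply(planted_set, function(i)
    sample.int(20, n_classes), integer(n_classes)))
  if (n_classes == 1) class_res <- matrix(class_res, ncol = 1)
  classes <- sample.int(n_classes, n_seq, replace = TRUE, prob = class_prob)
  m <- matrix(sample.int(20, n_seq * L, replace = TRUE, prob = background),
              n_seq, L)
  for (s in seq_len(n_seq)) {
    for (jj in seq_along(planted_set)) {
      j <- planted_set[jj]
      target <- class_res[jj, classes[s]]
      if (stats::runif(1) <= p) {
        m[s, j] <- target
      } else {
        m[s, j] <- sample(setdiff(seq_len(20), target), 1)
      }
    }
  }
  seqs <- apply(m, 1, function(r) paste(AA_ALPHABET[r], collapse = ""))
  aln <- alignment(sprintf("seq%04d", seq_len(n_seq)), seqs)
  list(alignment = aln,
       ground_truth = list(planted_set = sort(planted_set), p = p,
                           classes = classes,
                           class_residues = class_res, seed = seed))
}

# seeded local RNG helper: isolates generator calls from global state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}

# CA pseudo-atom chain topology (one atom per residue) on an idealized
# alpha-helical path (radius 2.3 A, 100 deg/residue, 1.5 A rise, giving
# ~3.8 A consecutive-CA spacing). A non-collinear mean geometry keeps
# the rigid-body superposition well conditioned.
chain_topology <- function(n_residues, spacing = 3.8) {
  i <- seq_len(n_residues)
  scl <- spacing / 3.8
  data.frame(eleno = i, elety = "CA", resid = "ALA",
             chain = "A", resno = i,
             x = scl * 2.3 * cos(i * 100 * pi / 180),
             y = scl * 2.3 * sin(i * 100 * pi / 180),
             z = scl * 1.5 * i, o = 1,
             het = FALSE, elem = "C", mass = 12.011, radius = 1.7,
             stringsAsFactors = FALSE)
}

#' Generate a Gaussian-fluctuation trajectory with planted structure
#'
#' Frames are `x_i(t) = mu_i + eps_i(t)` on a helical CA pseudo-atom
#' chain (~3.8 A consecutive spacing): per Cartesian axis,
#' `eps ~ N(0, Sigma)` with
#' `Sigma_ij = rho_ij sigma_i sigma_j` (axes independent, so the expected
#' DCC equals `rho`). Optionally each frame is contaminated with a random
#' rigid-body transform, which superposition-based metrics must remove.
#'
#' @param n_residues chain length.
#' @param n_frames number of frames.
#' @param sigma per-residue fluctuation SD per axis (angstrom); scalar or
#'   vector.
#' @param rho either `NULL` (independent), a full correlation matrix, or
#'   a data frame with columns `i`, `j`, `rho` for chosen pairs.
#' @param rigid_contamination apply a random rotation + translation per
#'   frame; default `FALSE`.
#' @param spacing CA spacing (angstrom); default 3.8.
#' @param seed RNG seed.
#' @return list with `trajectory` (a [trajectory()]) and `ground_truth`
#'   (`sigma`, correlation matrix, contamination flag, seed).
#' @export
make_gaussian_trajectory <- function(n_residues, n_frames, sigma = 0.5,
                                     rho = NULL,
                                     rigid_contamination = FALSE,
                                     spacing = 3.8, seed = 1) {
  sig <- rep_len(sigma, n_residues)
  if (any(sig <= 0)) stop("sigma must be positive")
  R <- diag(n_residues)
  if (!is.null(rho)) {
    if (is.data.frame(rho)) {
      for (r in seq_len(nrow(rho))) {
        R[rho$i[r], rho$j[r]] <- R[rho$j[r], rho$i[r]] <- rho$rho[r]
      }
    } else R <- rho
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  }
  Sigma <- R * tcrossprod(sig)
  Lc <- t(chol(Sigma + diag(1e-12, n_residues)))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  top <- chain_topology(n_residues, spacing)
  mu <- as.matrix(top[, c("x", "y", "z")])
  coords <- array(NA_real_, c(n_frames, n_residues, 3))
  for (ax in 1:3) {
    eps <- Lc %*% matrix(stats::rnorm(n_residues * n_frames), n_residues)
    coords[, , ax] <- t(eps) + matrix(mu[, ax], n_frames, n_residues,
                                      byrow = TRUE)
  }
  if (rigid_contamination) {
    for (t in seq_len(n_frames)) {
      Rm <- random_rotation()
      shift <- stats::runif(3, -20, 20)
      coords[t, , ] <- sweep(coords[t, , ] %*% t(Rm), 2, shift, `+`)
    }
  }
  list(trajectory = trajectory(top, coords),
       ground_truth = list(sigma = sig, rho = R,
                           rigid_contamination = rigid_contamination,
                           seed = seed))
}

# uniform random proper rotation (QR of a Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a trajectory whose element-distance pair follows a mixture
#'
#' Builds a chain topology with four named elements (`beta3`, `alpha4`,
#' `alpha2`, `alpha5`) arranged so that per frame the
#' (beta3-alpha4, alpha2-alpha5) Calpha-centroid distance pair equals a
#' draw from the given Gaussian mixture: components `(x, y, weight, sd)`.
#'
#' @param n_frames number of frames.
#' @param modes data frame with columns `x`, `y`, `weight`, `sd` (one row
#'   per mixture component, distances in angstrom).
#' @param residues_per_element residues per element; default 4.
#' @param seed RNG seed.
#' @return list with `trajectory`, `elements` (an [element_def()]) and
#'   `ground_truth` (the mode table).
#' @export
make_landscape_trajectory <- function(n_frames, modes,
                                      residues_per_element = 4, seed = 1) {
  stopifnot(all(c("x", "y", "weight", "sd") %in% names(modes)))
  k <- residues_per_element
  n_res <- 4 * k
  top <- chain_topology(n_res)
  # rigid per-element geometry: elements stacked along z, centred at zero
  zoff <- (seq_len(k) - (k + 1) / 2) * 3.8
  idx <- split(seq_len(n_res), rep(1:4, each = k))  # b3, a4, a2, a5
  base <- matrix(0, n_res, 3)
  base[idx[[1]], 3] <- zoff                 # beta3 at origin, z spread
  base[idx[[2]], 3] <- zoff                 # alpha4: translated along x
  base[idx[[3]], 3] <- zoff + 40            # alpha2 plane at z = 40
  base[idx[[4]], 3] <- zoff + 40            # alpha5: translated along y
  rng <- local_rng(seed)
  on.exit(rng$restore())
  wts <- modes$weight / sum(modes$weight)
  comp <- sample.int(nrow(modes), n_frames, replace = TRUE, prob = wts)
  dx <- stats::rnorm(n_frames, modes$x[comp], modes$sd[comp])
  dy <- stats::rnorm(n_frames, modes$y[comp], modes$sd[comp])
  coords <- array(NA_real_, c(n_frames, n_res, 3))
  for (t in seq_len(n_frames)) {
    fr <- base
    fr[idx[[2]], 1] <- dx[t]
    fr[idx[[4]], 2] <- dy[t]
    coords[t, , ] <- fr
  }
  el <- element_def(beta3 = idx[[1]], alpha4 = idx[[2]],
                    alpha2 = idx[[3]], alpha5 = idx[[4]])
  list(trajectory = trajectory(top, coords), elements = el,
       ground_truth = list(modes = modes, seed = seed,
                           distances = data.frame(x = dx, y = dy)))
}

# default melt temperature grid (degrees C) used by the thermal assay
MELT_TEMPERATURES <- c(30.0, 31.4, 34.3, 38.9, 44.5, 49.3, 52.4, 60.0,
                       61.4, 63.9, 67.8, 72.3, 76.1, 78.8, 80.0)

#' Generate synthetic dose-response data
#'
#' 4-parameter logistic model values plus i.i.d. Gaussian noise.
#'
#' @param logec50 log10 molar EC50.
#' @param hill Hill slope.
#' @param bottom,top response plateaus.
#' @param conc concentrations (molar); default a 10-point half-log grid
#'   bracketing the EC50.
#' @param noise_sd Gaussian noise SD (response units); default 0.
#' @param n_replicates replicate measurements per concentration.
#' @param seed RNG seed.
#' @return data frame with columns `conc`, `response`, `replicate`;
#'   attribute `ground_truth`.
#' @export
make_dose_response_data <- function(logec50, hill = 1, bottom = 0,
                                    top = 100, conc = NULL, noise_sd = 0,
                                    n_replicates = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(conc)) conc <- 10^seq(logec50 - 2.5, logec50 + 2.5,
                                    length.out = 10)
  rng <- local_rng(seed)
  on.exit(rng$restore())
  grid <- expand.grid(conc = conc, replicate = seq_len(n_replicates))
  mu <- fourpl(log10(grid$conc), bottom, top, logec50, hill)
  out <- data.frame(conc = grid$conc,
                    response = mu + stats::rnorm(nrow(grid), 0, noise_sd),
                    replicate = grid$replicate)
  attr(out, "ground_truth") <- list(logec50 = logec50, hill = hill,
                                    bottom = bottom, top = top,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate synthetic thermal-melt data
#'
#' Boltzmann sigmoid values plus Gaussian noise on the standard
#' 15-temperature assay grid (30-80 degrees C) unless another grid is
#' given.
#'
#' @param tm melting temperature (degrees C).
#' @param slope signed Boltzmann slope (degrees C).
#' @param bottom,top response plateaus; defaults 0 and 1.
#' @param temperature temperature grid; default `MELT_TEMPERATURES`.
#' @param noise_sd,n_replicates,seed as in [make_dose_response_data()].
#' @return data frame `temperature`, `bret_ratio`, `replicate` with a
#'   `ground_truth` attribute.
#' @export
make_melt_data <- function(tm, slope, bottom = 0, top = 1,
                           temperature = MELT_TEMPERATURES, noise_sd = 0,
                           n_replicates = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  grid <- expand.grid(temperature = temperature,
                      replicate = seq_len(n_replicates))
  mu <- boltzmann(grid$temperature, bottom, top, tm, slope)
  out <- data.frame(temperature = grid$temperature,
                    bret_ratio = mu + stats::rnorm(nrow(grid), 0, noise_sd),
                    replicate = grid$replicate)
  attr(out, "ground_truth") <- list(tm = tm, slope = slope,
                                    bottom = bottom, top = top,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic bioluminescence spectrum
#'
#' @param components data frame with `amplitude`, `center`, `width` (nm).
#' @param wavelengths sampling grid (nm); default 385-665 nm in 15 nm
#'   steps.
#' @param noise_sd,seed as in [make_dose_response_data()].
#' @return data frame `wavelength`, `intensity` with `ground_truth`.
#' @export
make_spectrum_data <- function(components,
                               wavelengths = seq(385, 665, by = 15),
                               noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  mu <- rep(0, length(wavelengths))
  for (i in seq_len(nrow(components))) {
    mu <- mu + components$amplitude[i] *
      exp(-(wavelengths - components$center[i])^2 /
            (2 * components$width[i]^2))
  }
  out <- data.frame(wavelength = wavelengths,
                    intensity = mu + stats::rnorm(length(mu), 0, noise_sd))
  attr(out, "ground_truth") <- list(components = components,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    x <- frame_xyz(traj, t)
    rec <- ifelse(top$het, "HETATM", "ATOM  ")
    lines <- sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, top$eleno, formatC(top$elety, width = 4, flag = "-"), "",
      top$resid, top$chain, top$resno, "", x[, 1], x[, 2], x[, 3],
      top$o, 0, top$elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
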