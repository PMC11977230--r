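# Conformational landscape: 2D kernel density over two element-distance
# coordinates, with mode extraction.

#' Define secondary-structure elements as residue ranges
#'
#' @param ... named integer vectors / ranges, e.g.
#'   `element_def(beta3 = 58:63, alpha4 = 75:85)`.
#' @param atoms atom-subset rule for distance evaluation; default `"ca"`.
#' @return an `element_def`: named list of residue-number vectors.
#' @export
element_def <- function(..., atoms = "ca") {
  el <- list(...)
  if (length(el) == 1 && is.list(el[[1]]) && is.null(names(el))) {
    el <- el[[1]]
  }
  if (is.null(names(el)) || any(names(el) == "")) {
    stop("every element needs a name")
  }
  if (any(vapply(el, length, integer(1)) == 0)) {
    stop("element residue ranges must be non-empty")
  }
  structure(lapply(el, as.integer), class = "element_def", atoms = atoms)
}

#' Read element ranges from a two-column text file
#'
#' File format: `name<TAB>start-end` (or `start:end`), one per line,
#' `#` comments allowed.
#'
#' @param path file path.
#' @return an [element_def()].
#' @export
read_element_def <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[\t ]+")
  el <- lapply(parts, function(p) {
    rng <- as.integer(strsplit(p[2], "[-:]")[[1]])
    seq(rng[1], rng[length(rng)])
  })
  names(el) <- vapply(parts, `[`, "", 1)
  element_def(el)
}

element_selection <- function(traj, el, name) {
  if (!name %in% names(el)) {
    stop("element ranges missing required element '", name, "'")
  }
  resno <- el[[name]]
  top <- traj$topology
  present <- intersect(resno, top$resno[!top$het])
  if (!length(present)) stop("element '", name, "' matches no residues")
  ch <- top$chain[match(present, top$resno)]
  residue_selection(ch, present, atoms = "ca")
}

#' Distance-pair coordinates of each frame
#'
#' For each frame computes x = Calpha-centroid distance(el1a, el1b) and
#' y = Calpha-centroid distance(el2a, el2b).
#'
#' @param traj a [trajectory()].
#' @param elements an [element_def()] containing the four named elements.
#' @param pair_x,pair_y length-2 character vectors naming the element
#'   pairs; defaults `c("beta3", "alpha4")` and `c("alpha2", "alpha5")`.
#' @return data frame with columns `x`, `y` (angstrom).
#' @export
element_distance_pairs <- function(traj, elements,
                                   pair_x = c("beta3", "alpha4"),
                                   pair_y = c("alpha2", "alpha5")) {
  a1 <- element_selection(traj, elements, pair_x[1])
  b1 <- element_selection(traj, elements, pair_x[2])
  a2 <- element_selection(traj, elements, pair_y[1])
  b2 <- element_selection(traj, elements, pair_y[2])
  x <- group_distance_series(traj, a1, b1, mode = "ca")$values
  y <- group_distance_series(traj, a2, b2, mode = "ca")$values
  data.frame(x = x, y = y)
}

scott_bandwidth <- function(v) {
  n <- length(v)
  stats::sd(v) * n^(-1 / 6)   # Scott's rule per axis for 2D KDE
}

#' 2D conformational landscape from pooled trajectories
#'
#' Pools the per-frame (x, y) element-distance pairs across replicate
#' trajectories, estimates a 2D Gaussian-kernel probability density on a
#' regular grid (Scott's-rule bandwidth per axis), normalizes it over the
#' grid, and extracts modes as strict grid local maxima above a floor of
#' 10% of the global maximum, sorted by density.
#'
#' @param trajs a [trajectory()] or list of replicates.
#' @param elements an [element_def()] with elements `beta3`, `alpha4`,
#'   `alpha2`, `alpha5` (or those named in `pair_x`/`pair_y`).
#' @param grid_step grid spacing (angstrom); default 0.1.
#' @param bandwidth `"scott"` or a numeric length-2 vector of kernel SDs.
#' @param pad grid padding beyond the data range, in bandwidths; default 3.
#' @param mode_floor modes must exceed this fraction of the global
#'   density maximum; default 0.10.
#' @param pair_x,pair_y see [element_distance_pairs()].
#' @return a `landscape_density`: list with `x`, `y` (axes), `density`
#'   (matrix, integrates to 1 over the grid), `bandwidth`, `modes`
#'   (data frame x, y, density), `points` (the pooled distance pairs).
#' @export
distance_landscape <- function(trajs, elements, grid_step = 0.1,
                               bandwidth = "scott", pad = 3,
                               mode_floor = 0.10,
                               pair_x = c("beta3", "alpha4"),
                               pair_y = c("alpha2", "alpha5")) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  pts <- do.call(rbind, lapply(trajs, element_distance_pairs,
                               elements = elements,
                               pair_x = pair_x, pair_y = pair_y))
  if (nrow(pts) < 2) stop("need at least 2 pooled frames")
  degenerate <- stats::sd(pts$x) < 1e-9 && stats::sd(pts$y) < 1e-9
  if (is.character(bandwidth)) {
    bw <- c(scott_bandwidth(pts$x), scott_bandwidth(pts$y))
  } else bw <- rep_len(bandwidth, 2)
  if (degenerate || any(bw <= 0)) {
    warning("degenerate landscape: all frames give (near-)identical ",
            "distances; reporting a single delta-like mode")
    bw[bw <= 0 | !is.finite(bw)] <- grid_step
  }
  xr <- range(pts$x) + c(-1, 1) * pad * bw[1]
  yr <- range(pts$y) + c(-1, 1) * pad * bw[2]
  gx <- seq(xr[1], xr[2], by = grid_step)
  gy <- seq(yr[1], yr[2], by = grid_step)
  # MASS::kde2d uses kernel sd = h/4
  dens <- MASS::kde2d(pts$x, pts$y, h = 4 * bw, n = c(length(gx),
                      length(gy)), lims = c(xr[1], xr[2], yr[1], yr[2]))
  z <- dens$z
  # normalize over the actual grid spacings (kde2d respacing of lims)
  dx <- dens$x[2] - dens$x[1]
  dy <- dens$y[2] - dens$y[1]
  z <- z / (sum(z) * dx * dy)
  modes <- find_grid_modes(dens$x, dens$y, z, mode_floor)
  structure(list(x = dens$x, y = dens$y, density = z, bandwidth = bw,
                 modes = modes, points = pts),
            class = "landscape_density")
}

# strict local maxima of a gridded density above floor_frac * max
find_grid_modes <- function(gx, gy, z, floor_frac = 0.10) {
  nx <- length(gx); ny <- length(gy)
  floor_val <- floor_frac * max(z)
  hits <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      v <- z[i, j]
      if (v <= floor_val) next
      ii <- max(1, i - 1):min(nx, i + 1)
      jj <- max(1, j - 1):min(ny, j + 1)
      nb <- z[ii, jj, drop = FALSE]
      nb[match(i, ii), match(j, jj)] <- -Inf   # exclude the centre cell
      if (v > max(nb)) {
        hits[[length(hits) + 1]] <- c(gx[i], gy[j], v)
      }
    }
  }
  if (!length(hits)) {
    ij <- which(z == max(z), arr.ind = TRUE)[1, ]
    hits[[1]] <- c(gx[ij[1]], gy[ij[2]], max(z))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(x = m[, 1], y = m[, 2], density = m[, 3])
  out[order(-out$density), , drop = FALSE]
}

#' @export
print.landscape_density <- function(x, ...) {
  cat("landscape_density:", length(x$x), "x", length(x$y), "grid,",
      nrow(x$modes), "mode(s); top mode at (",
      sprintf("%.2f, %.2f", x$modes$x[1], x$modes$y[1]), ") A\n")
  invisible(x)
}

#' Write a landscape as gridded TSV plus modes JSON
#' @param ld a `landscape_density`.
#' @param prefix path prefix; writes `<prefix>_density.tsv` (x, y,
#'   density long format) and `<prefix>_modes.json`.
#' @return paths, invisibly.
#' @export
write_landscape <- function(ld, prefix) {
  grid <- expand.grid(x = ld$x, y = ld$y)
  grid$density <- as.numeric(ld$density)
  p1 <- paste0(prefix, "_density.tsv")
  utils::write.table(grid, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(prefix, "_modes.json")
  jsonlite::write_json(ld$modes, p2, digits = NA, dataframe = "rows")
  invisible(c(p1, p2))
}
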