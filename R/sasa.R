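# Shrake-Rupley solvent-accessible surface area and hydrogen-bond
# counting over trajectories.

# Quasi-uniform points on the unit sphere (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each target atom, test points are placed quasi-uniformly on the
#' sphere of radius `r_atom + probe`; points strictly inside any other
#' atom's expanded sphere are buried (boundary points count as exposed).
#' The atom's SASA is the exposed fraction times the full sphere area
#' `4 pi (r_atom + probe)^2`. Hydrogens are ignored entirely.
#'
#' @param xyz n x 3 coordinate matrix (angstrom) of the context atoms.
#' @param radius per-atom radii (angstrom); `NA` for atoms to skip.
#' @param target indices of atoms whose SASA is wanted (default all).
#' @param probe probe radius in angstrom; default 1.4.
#' @param n_sphere_points test points per atom; default 960.
#' @return numeric vector of per-target-atom SASA values (angstrom^2).
#' @export
shrake_rupley <- function(xyz, radius, target = seq_len(nrow(xyz)),
                          probe = 1.4, n_sphere_points = 960) {
  if (any(is.na(radius))) {
    stop("missing radius for atom(s): ",
         paste(utils::head(which(is.na(radius)), 5), collapse = ","))
  }
  pts <- golden_spiral_points(n_sphere_points)
  rexp <- radius + probe
  out <- numeric(length(target))
  for (k in seq_along(target)) {
    i <- target[k]
    ri <- rexp[i]
    # candidate occluders: expanded spheres that can reach atom i's shell
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d < ri + rexp & seq_len(nrow(xyz)) != i)
    if (!length(nb)) {
      out[k] <- 4 * pi * ri^2
      next
    }
    surf <- sweep(pts * ri, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      d2 <- rowSums(sweep(surf[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- d2 >= rexp[j]^2   # strictly inside is buried
    }
    out[k] <- 4 * pi * ri^2 * sum(exposed) / n_sphere_points
  }
  out
}

#' Ligand SASA time series
#'
#' Total Shrake-Rupley SASA of the named ligand's heavy atoms per frame,
#' in the context of all heavy atoms of protein plus ligand.
#'
#' @param traj a [trajectory()].
#' @param ligand hetero residue name.
#' @param probe probe radius (angstrom); default 1.4.
#' @param n_sphere_points test points per atom; default 960.
#' @return a [time_series()] in angstrom^2.
#' @export
ligand_sasa_series <- function(traj, ligand, probe = 1.4,
                               n_sphere_points = 960) {
  top <- traj$topology
  heavy <- which(!(top$elem %in% c("H", "D")))
  lig <- which(top$het & top$resid == ligand & !(top$elem %in% c("H", "D")))
  if (!length(lig)) stop("ligand '", ligand, "' not found in topology")
  ctx <- union(heavy, lig)
  lig_in_ctx <- match(lig, ctx)
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_xyz(traj, t)[ctx, , drop = FALSE]
    sum(shrake_rupley(x, top$radius[ctx], target = lig_in_ctx,
                      probe = probe, n_sphere_points = n_sphere_points))
  }, numeric(1))
  time_series("ligand_sasa", vals, "A^2", traj$replicate)
}

#' Frequency distribution of a time series
#' @param ts a [time_series()].
#' @param breaks passed to [graphics::hist()] logic via [base::cut()];
#'   default 30 equal bins.
#' @return data frame with `mid`, `count`, `frequency`.
#' @export
series_histogram <- function(ts, breaks = 30) {
  h <- graphics::hist(ts$values, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts,
             frequency = h$counts / sum(h$counts))
}

#' Hydrogen-bond count between ligand and protein per frame
#'
#' Donor/acceptor candidates are nitrogen and oxygen atoms. A pair (one
#' atom in the ligand, one in the protein) is counted when the heavy-atom
#' distance is at most `d_cut`; when hydrogens are present in the
#' topology, a donor hydrogen within 1.25 A of either heavy atom must
#' additionally make a D-H...A angle of at least `angle_cut` degrees.
#' Without hydrogens the criterion is distance-only (a notice is given
#' once).
#'
#' @param traj a [trajectory()].
#' @param ligand hetero residue name.
#' @param d_cut donor-acceptor heavy-atom distance cutoff (angstrom);
#'   default 3.5.
#' @param angle_cut D-H...A angle cutoff in degrees; default 150.
#' @return a [time_series()] of counts.
#' @export
hbond_count_series <- function(traj, ligand, d_cut = 3.5, angle_cut = 150) {
  top <- traj$topology
  lig_no <- which(top$het & top$resid == ligand & top$elem %in% c("N", "O"))
  prot_no <- which(!top$het & top$elem %in% c("N", "O"))
  if (!length(lig_no)) {
    return(time_series("hbonds", rep(0, n_frames(traj)), "count",
                       traj$replicate))
  }
  hyd <- which(top$elem %in% c("H", "D"))
  if (!length(hyd)) {
    message("no hydrogens in topology: H-bond count uses the ",
            "distance-only criterion")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(t) {
    x <- frame_xyz(traj, t)
    cnt <- 0L
    for (i in lig_no) {
      d <- sqrt(rowSums(sweep(x[prot_no, , drop = FALSE], 2, x[i, ])^2))
      close <- prot_no[d <= d_cut & d > 1e-6]
      for (j in close) {
        if (!length(hyd)) {
          cnt <- cnt + 1L
        } else {
          # hydrogen attached to either partner plays the donor H
          ok <- FALSE
          for (dn in c(i, j)) {
            acc <- if (dn == i) j else i
            dh <- sqrt(rowSums(sweep(x[hyd, , drop = FALSE], 2, x[dn, ])^2))
            hs <- hyd[dh <= 1.25]
            for (h in hs) {
              v1 <- x[dn, ] - x[h, ]
              v2 <- x[acc, ] - x[h, ]
              ang <- acos(pmin(pmax(sum(v1 * v2) /
                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
              if (ang >= angle_cut) { ok <- TRUE; break }
            }
            if (ok) break
          }
          if (ok) cnt <- cnt + 1L
        }
      }
    }
    as.numeric(cnt)
  }, numeric(1))
  time_series("hbonds", vals, "count", traj$replicate)
}
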