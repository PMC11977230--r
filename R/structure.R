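# Structure handling: PDB parsing (via bio3d) with altloc/element
# resolution, ligand-proximity classification and static inter-residue
# distances.

# standard atomic masses (amu) and SASA radii (Angstrom) by element
ELEMENT_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, F = 18.998,
                  CL = 35.45, BR = 79.904, I = 126.904, FE = 55.845,
                  ZN = 65.38, MG = 24.305, CA = 40.078, "NA" = 22.99,
                  K = 39.098, MN = 54.938)
ELEMENT_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                    SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                    FE = 1.80, ZN = 1.39, MG = 1.73, CA = 2.31,
                    "NA" = 2.27, K = 2.75, MN = 1.80)

# Infer element from PDB element column when present, else from atom name.
infer_element <- function(elety, elesy = NULL) {
  out <- rep(NA_character_, length(elety))
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    out[e != "" & !is.na(e)] <- e[e != "" & !is.na(e)]
  }
  miss <- which(is.na(out) | out == "")
  if (length(miss)) {
    nm <- toupper(gsub("[0-9' ]", "", elety[miss]))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    guess <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA",
                               "MN"), two, one)
    # names like "HG1" on protein atoms are hydrogens, not mercury
    guess[grepl("^[0-9]*H", toupper(elety[miss]))] <- "H"
    out[miss] <- guess
  }
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records, materializes one model of a (possibly
#' multi-model NMR) file, resolves alternate locations by keeping the
#' highest-occupancy conformer (ties broken toward altloc `A`), and infers
#' elements, masses and SASA radii.
#'
#' @param path PDB file path.
#' @param model 1-based model index; default 1 (first model).
#' @return a `structure3d`: list with `atoms` (data frame: eleno, elety,
#'   resid, chain, resno, x, y, z, o, het, elem, mass, radius) and
#'   `model`.
#' @export
read_structure <- function(path, model = 1L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  if (nrow(pdb$atom) == 0L) stop("no ATOM/HETATM records in ", path)
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models) {
    stop("requested model ", model, " but file has ", n_models, " model(s)")
  }
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$o[is.na(at$o)] <- 1
  # altloc resolution within (chain, resno, resid, atom name)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
    ord <- order(key, -at$o, alt)   # highest occupancy first, then altloc A
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety,
                               sep = "|")), ]
    at <- at[order(at$eleno), ]
  }
  elem <- infer_element(at$elety, at$elesy)
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      resid = at$resid, chain = at$chain, resno = at$resno,
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      het = at$type == "HETATM", elem = elem,
                      mass = unname(ELEMENT_MASS[elem]),
                      radius = unname(ELEMENT_RADIUS[elem]),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  structure(list(atoms = atoms, model = model, n_models = n_models),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d: ", nrow(x$atoms), " atoms (",
      sum(x$atoms$het), " hetero), model ", x$model, "/", x$n_models,
      "\n", sep = "")
  invisible(x)
}

is_heavy <- function(atoms) !(atoms$elem %in% c("H", "D"))

#' Build a residue selection
#'
#' @param chain chain identifiers (recycled against `resno`).
#' @param resno residue numbers.
#' @param atoms atom-subset rule: `"heavy"` (all heavy atoms),
#'   `"sidechain"` (heavy atoms outside N/CA/C/O), or `"ca"`.
#' @return a `residue_selection` data frame with attribute `atom_rule`.
#' @export
residue_selection <- function(chain, resno,
                              atoms = c("heavy", "sidechain", "ca")) {
  atoms <- match.arg(atoms)
  sel <- data.frame(chain = rep_len(as.character(chain), length(resno)),
                    resno = as.integer(resno))
  attr(sel, "atom_rule") <- atoms
  class(sel) <- c("residue_selection", "data.frame")
  sel
}

# Indices of structure atoms matching a selection under a mode.
selection_atoms <- function(s, sel, mode = NULL) {
  if (is.null(mode)) mode <- attr(sel, "atom_rule")
  if (is.null(mode)) mode <- "heavy"
  atoms <- s$atoms
  key <- paste(atoms$chain, atoms$resno)
  want <- paste(sel$chain, sel$resno)
  idx <- which(key %in% want)
  idx <- switch(mode,
    ca = idx[atoms$elety[idx] == "CA"],
    sidechain = idx[is_heavy(atoms[idx, , drop = FALSE]) &
                      !(atoms$elety[idx] %in% c("N", "CA", "C", "O"))],
    heavy = ,
    com = ,
    min_heavy = idx[is_heavy(atoms[idx, , drop = FALSE])],
    idx)
  idx
}

#' Protein residues near a ligand
#'
#' Returns protein residues with at least one heavy atom within `cutoff`
#' angstroms (minimum heavy-atom distance, inclusive) of any heavy atom of
#' the named hetero residue. Hydrogens are ignored on both sides.
#'
#' @param s a `structure3d`.
#' @param ligand hetero residue name (e.g. `"PCG"` for cGMP).
#' @param cutoff distance cutoff in angstrom; default 5.0.
#' @return a [residue_selection()] of the proximal protein residues, with
#'   a `min_dist` column giving each residue's minimum heavy-atom distance
#'   to the ligand.
#' @export
ligand_proximal_residues <- function(s, ligand, cutoff = 5.0) {
  stopifnot(inherits(s, "structure3d"))
  atoms <- s$atoms
  lig <- atoms$het & atoms$resid == ligand & is_heavy(atoms)
  if (!any(lig)) {
    avail <- unique(atoms$resid[atoms$het])
    stop("ligand '", ligand, "' not found; hetero residues present: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  prot <- !atoms$het & is_heavy(atoms)
  lg <- as.matrix(atoms[lig, c("x", "y", "z")])
  pr <- as.matrix(atoms[prot, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pr^2), rep(1, nrow(lg))) +
    outer(rep(1, nrow(pr)), rowSums(lg^2)) - 2 * pr %*% t(lg)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  pa <- atoms[prot, ]
  keyfac <- factor(paste(pa$chain, pa$resno, sep = "|"),
                   levels = unique(paste(pa$chain, pa$resno, sep = "|")))
  res_min <- tapply(dmin, keyfac, min)
  near <- names(res_min)[res_min <= cutoff]
  parts <- strsplit(near, "|", fixed = TRUE)
  sel <- residue_selection(vapply(parts, `[`, "", 1),
                           as.integer(vapply(parts, `[`, "", 2)))
  sel$min_dist <- as.numeric(res_min[near])
  out <- sel[order(sel$resno), ]
  attr(out, "atom_rule") <- "heavy"
  class(out) <- c("residue_selection", "data.frame")
  rownames(out) <- NULL
  out
}

#' Map reference-numbered positions onto a structure
#'
#' Translates residue numbers given in a reference numbering (e.g. human
#' PDE5A1) to the structure's numbering via a constant offset, and reports
#' positions absent from the structure instead of dropping them silently.
#'
#' @param positions residue numbers in the reference numbering.
#' @param s a `structure3d`.
#' @param offset number added to reference numbers to obtain structure
#'   numbers (e.g. -10 to go from human PDE5A1 to the mouse GAFa
#'   template).
#' @param chain optional chain restriction.
#' @return list with `selection` (a [residue_selection()] carrying a
#'   `reference_resno` column) and `unmapped` (reference numbers with no
#'   residue in the structure).
#' @export
map_positions_to_structure <- function(positions, s, offset = 0L,
                                       chain = NULL) {
  stopifnot(inherits(s, "structure3d"))
  atoms <- s$atoms[!s$atoms$het, ]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, ]
  target <- positions + offset
  present <- target %in% atoms$resno
  ch <- vapply(target[present], function(r)
    atoms$chain[match(r, atoms$resno)], character(1))
  sel <- residue_selection(ch, target[present])
  sel$reference_resno <- positions[present]
  list(selection = sel, unmapped = positions[!present])
}

#' Distance between two residue groups
#'
#' @param s a `structure3d`.
#' @param a,b [residue_selection()]s.
#' @param mode `"com"` (mass-weighted centroid over the selections' atom
#'   rule, heavy atoms by default), `"ca"` (centroid of the Calpha atoms),
#'   or `"min_heavy"` (minimum heavy-atom pair distance).
#' @return distance in angstrom.
#' @export
residue_group_distance <- function(s, a, b,
                                   mode = c("com", "ca", "min_heavy")) {
  mode <- match.arg(mode)
  ia <- selection_atoms(s, a, mode)
  ib <- selection_atoms(s, b, mode)
  if (!length(ia) || !length(ib)) {
    stop("selection resolves to zero atoms under mode '", mode, "'")
  }
  group_distance_xyz(as.matrix(s$atoms[, c("x", "y", "z")]),
                     ia, ib, mode, s$atoms$mass)
}

# shared by static and per-frame paths
group_distance_xyz <- function(xyz, ia, ib, mode, mass) {
  if (mode == "min_heavy") {
    A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
    return(sqrt(max(min(d2), 0)))
  }
  w_a <- if (mode == "com") mass[ia] else rep(1, length(ia))
  w_b <- if (mode == "com") mass[ib] else rep(1, length(ib))
  if (any(is.na(w_a)) || any(is.na(w_b))) stop("missing atomic masses")
  ca <- colSums(xyz[ia, , drop = FALSE] * w_a) / sum(w_a)
  cb <- colSums(xyz[ib, , drop = FALSE] * w_b) / sum(w_b)
  sqrt(sum((ca - cb)^2))
}

#' Write a residue-selection report as TSV
#' @param sel a [residue_selection()] (optionally with `min_dist`).
#' @param s the source `structure3d` (for residue names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, s, path) {
  resname <- vapply(seq_len(nrow(sel)), function(i) {
    hit <- s$atoms$chain == sel$chain[i] & s$atoms$resno == sel$resno[i]
    if (any(hit)) s$atoms$resid[which(hit)[1]] else NA_character_
  }, character(1))
  out <- data.frame(chain = sel$chain, resnum = sel$resno, resname = resname)
  if (!is.null(sel$min_dist)) out$min_dist_to_ligand <- sel$min_dist
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
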