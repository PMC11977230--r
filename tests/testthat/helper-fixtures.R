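# Shared fixture builders and independent oracles, all constructed in
# code at test time.

# write a FASTA string set to a temp file
write_temp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# minimal PDB text from an atom table (list of lists with elety, resid,
# resno, x, y, z, elem, het, and optional occ/alt/chain)
write_temp_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                           models = 1) {
  fmt_atom <- function(a, serial, xyz) {
    sprintf("%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (isTRUE(a$het)) "HETATM" else "ATOM  ", serial, a$elety,
            if (is.null(a$alt)) "" else a$alt, a$resid,
            if (is.null(a$chain)) "A" else a$chain, a$resno,
            xyz[1], xyz[2], xyz[3],
            if (is.null(a$occ)) 1 else a$occ, 0, a$elem)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(models)) {
    if (models > 1) writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_along(atoms)) {
      a <- atoms[[i]]
      xyz <- c(a$x, a$y, a$z)
      if (models > 1 && !is.null(a$shift_per_model)) {
        xyz <- xyz + (m - 1) * a$shift_per_model
      }
      writeLines(fmt_atom(a, i, xyz), con)
    }
    if (models > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

atomrec <- function(elety, resid, resno, x, y, z, elem, het = FALSE, ...) {
  c(list(elety = elety, resid = resid, resno = resno, x = x, y = y, z = z,
         elem = elem, het = het), list(...))
}

# trajectory from an explicit list of n_atoms x 3 frame matrices on a
# CA-pseudo-atom topology
toy_trajectory <- function(frames, het = rep(FALSE, nrow(frames[[1]])),
                           resid = ifelse(het, "LIG", "ALA"),
                           elem = rep("C", nrow(frames[[1]])),
                           elety = ifelse(het, "C1", "CA")) {
  na <- nrow(frames[[1]])
  top <- data.frame(eleno = seq_len(na), elety = elety, resid = resid,
                    chain = "A", resno = seq_len(na),
                    x = frames[[1]][, 1], y = frames[[1]][, 2],
                    z = frames[[1]][, 3], o = 1, het = het, elem = elem,
                    mass = ifelse(elem == "H", 1.008, 12.011),
                    radius = ifelse(elem == "H", NA, 1.7),
                    stringsAsFactors = FALSE)
  coords <- array(NA_real_, c(length(frames), na, 3))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]
  trajectory(top, coords)
}

# random rigid transform applied to an n x 3 matrix
apply_random_rigid <- function(x, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(x %*% t(q), 2, runif(3, -10, 10), `+`)
}

# --- independent oracles ---------------------------------------------

# quadruple-loop SCA coupling oracle (no vectorization shared with the
# implementation); equal or supplied weights, uniform background
naive_coupling <- function(seqs, weights = rep(1, length(seqs)),
                           lambda = 0.03) {
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- length(seqs)
  L <- nchar(seqs[1])
  ch <- do.call(rbind, strsplit(seqs, ""))
  w <- weights / sum(weights)
  q <- 1 / 20
  f1 <- array(0, c(L, 20))
  for (i in 1:L) for (a in 1:20) {
    f1[i, a] <- (1 - lambda) * sum(w * (ch[, i] == alpha[a])) + lambda * q
  }
  f2 <- array(0, c(L, L, 20, 20))
  for (i in 1:L) for (j in 1:L) for (a in 1:20) for (b in 1:20) {
    f2[i, j, a, b] <- (1 - lambda) *
      sum(w * (ch[, i] == alpha[a]) * (ch[, j] == alpha[b])) +
      lambda * q * q
  }
  phi <- matrix(0, L, 20)
  for (i in 1:L) for (a in 1:20) {
    phi[i, a] <- min(max(log(f1[i, a] * (1 - q) / ((1 - f1[i, a]) * q)),
                         -50), 50)
  }
  sc <- matrix(0, L, L)
  for (i in 1:L) for (j in 1:L) {
    if (i == j) next
    acc <- 0
    for (a in 1:20) for (b in 1:20) {
      cab <- phi[i, a] * phi[j, b] *
        (f2[i, j, a, b] - f1[i, a] * f1[j, b])
      acc <- acc + cab^2
    }
    sc[i, j] <- sqrt(acc)
  }
  sc
}

# two-pass loop-based DCC oracle on an already-superposed coordinate
# array (n_frames x n_atoms x 3)
naive_dcc <- function(sel) {
  nf <- dim(sel)[1]; na <- dim(sel)[2]
  mu <- matrix(0, na, 3)
  for (t in 1:nf) mu <- mu + sel[t, , ] / nf
  C <- matrix(0, na, na)
  for (i in 1:na) for (j in i:na) {
    acc <- 0
    for (t in 1:nf) {
      acc <- acc + sum((sel[t, i, ] - mu[i, ]) * (sel[t, j, ] - mu[j, ]))
    }
    C[i, j] <- C[j, i] <- acc / nf
  }
  v <- diag(C)
  C / sqrt(outer(v, v))
}

# reference 4PL evaluated independently of the package
fourpl_ref <- function(logc, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logc) * hill))
}

# Monte-Carlo SASA oracle for one atom in a context of spheres
mc_sasa_atom <- function(i, xyz, radius, probe = 1.4, n = 1e5, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n)
  u <- u / sqrt(rowSums(u^2))
  ri <- radius[i] + probe
  pts <- sweep(u * ri, 2, xyz[i, ], `+`)
  buried <- rep(FALSE, n)
  for (j in seq_len(nrow(xyz))) {
    if (j == i) next
    d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
    buried <- buried | d2 < (radius[j] + probe)^2
  }
  4 * pi * ri^2 * mean(!buried)
}
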