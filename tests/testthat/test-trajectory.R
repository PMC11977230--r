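test_that("Kabsch superposition removes rigid motion, never reflects", {
  set.seed(41)
  ref <- matrix(rnorm(30, sd = 3), 10)
  # rotate 90 degrees about z + translate
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  frame <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), `+`)
  sp <- superpose(frame, ref)
  expect_lt(sp$rmsd_fit, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  sp_id <- superpose(ref, ref)
  expect_equal(sp_id$rotation, diag(3), tolerance = 1e-9)
  expect_lt(sp_id$rmsd_fit, 1e-12)

  # mirrored frame: proper rotation enforced, nonzero residual
  mir <- ref %*% diag(c(-1, 1, 1))
  sp_m <- superpose(mir, ref)
  expect_equal(det(sp_m$rotation), 1, tolerance = 1e-9)
  expect_gt(sp_m$rmsd_fit, 0.1)
  # brute-force check: no sampled proper rotation beats the Kabsch fit
  set.seed(42)
  cm <- colMeans(mir); cr <- colMeans(ref)
  best <- Inf
  for (k in 1:500) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    dev <- sweep(sweep(mir, 2, cm) %*% t(q), 2, cr, `+`) - ref
    best <- min(best, sqrt(mean(rowSums(dev^2))))
  }
  expect_lte(sp_m$rmsd_fit, best + 1e-9)

  expect_error(superpose(frame[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("RMSD series: zeros on self, hand case, contamination-proof", {
  set.seed(43)
  base <- matrix(rnorm(24, sd = 2), 8)
  tr <- toy_trajectory(list(base, base, base))
  expect_equal(rmsd_series(tr, ref = 1, selection = NULL)$values,
               rep(0, 3), tolerance = 1e-9)

  # 2-atom hand case: ref x = 0,1; frame x = 0,3 -> centered RMSD 1.0
  f1 <- cbind(c(0, 1), 0, 0)
  f2 <- cbind(c(0, 3), 0, 0)
  tr2 <- toy_trajectory(list(f1, f2))
  expect_equal(rmsd_series(tr2, ref = 1, selection = NULL)$values[2], 1.0)

  # rigid-motion contamination leaves superposed RMSD unchanged
  g_clean <- make_gaussian_trajectory(30, 50, sigma = 0.4, seed = 44)
  g_cont <- make_gaussian_trajectory(30, 50, sigma = 0.4,
                                     rigid_contamination = TRUE,
                                     seed = 44)
  r_clean <- rmsd_series(g_clean$trajectory, ref = 1)
  r_cont <- rmsd_series(g_cont$trajectory, ref = 1)
  expect_equal(r_cont$values, r_clean$values, tolerance = 1e-6)
})

test_that("RMSF: static zero, planted oscillation, sigma sqrt(3) law", {
  base <- matrix(rnorm(90, sd = 5), 30)
  tr <- toy_trajectory(list(base, base, base))
  expect_equal(rmsf_profile(tr, selection = NULL)$rmsf, rep(0, 30),
               tolerance = 1e-9)
  expect_error(rmsf_profile(toy_trajectory(list(base)), NULL), "single")

  # one atom oscillating +/-1 A along x among 40 pinned atoms
  set.seed(45)
  pin <- matrix(rnorm(120, sd = 6), 40)
  fplus <- rbind(pin, c(1, 0, 0))
  fminus <- rbind(pin, c(-1, 0, 0))
  tro <- toy_trajectory(rep(list(fplus, fminus), 25))
  prof <- rmsf_profile(tro, selection = NULL)
  expect_equal(prof$rmsf[41], 1.0, tolerance = 0.05)
  expect_lt(max(prof$rmsf[1:40]), 0.05)

  # isotropic Gaussian sigma: RMSF -> sigma * sqrt(3)
  g <- make_gaussian_trajectory(100, 4000, sigma = 0.5, seed = 46)
  prof2 <- rmsf_profile(g$trajectory)
  expect_equal(mean(prof2$rmsf), 0.5 * sqrt(3), tolerance = 0.03)
})

test_that("radius of gyration matches closed forms", {
  # two equal-mass atoms 2 A apart
  tr <- toy_trajectory(list(cbind(c(0, 2), 0, 0)))
  expect_equal(rg_series(tr, selection = NULL)$values, 1.0)
  # single atom
  tr1 <- toy_trajectory(list(matrix(c(5, 5, 5), 1)))
  expect_equal(rg_series(tr1, selection = NULL)$values, 0.0)
  # four equal masses at (+-1,0,0),(0,+-1,0)
  tr4 <- toy_trajectory(list(rbind(c(1, 0, 0), c(-1, 0, 0),
                                   c(0, 1, 0), c(0, -1, 0))))
  expect_equal(rg_series(tr4, selection = NULL)$values, 1.0)
})

test_that("group distances are frame-internal and rigid-invariant", {
  # static trajectory: constant series equal to the static distance
  f <- rbind(c(0, 0, 0), c(3, 4, 0))
  tr <- toy_trajectory(list(f, f, f))
  a <- residue_selection("A", 1); b <- residue_selection("A", 2)
  expect_equal(group_distance_series(tr, a, b, "com")$values, rep(5, 3))

  # linear separation 1 A per frame from 5 A
  frames <- lapply(0:4, function(k) rbind(c(0, 0, 0), c(5 + k, 0, 0)))
  tr2 <- toy_trajectory(frames)
  expect_equal(group_distance_series(tr2, a, b, "ca")$values, 5:9)

  # per-frame random rigid transforms leave the series unchanged
  frames_t <- lapply(seq_along(frames), function(t)
    apply_random_rigid(frames[[t]], 50 + t))
  tr3 <- toy_trajectory(frames_t)
  expect_equal(group_distance_series(tr3, a, b, "ca")$values,
               group_distance_series(tr2, a, b, "ca")$values,
               tolerance = 1e-9)
})

test_that("pooled replicates equal concatenated frames", {
  g1 <- make_gaussian_trajectory(10, 30, sigma = 0.5, seed = 61)
  g2 <- make_gaussian_trajectory(10, 40, sigma = 0.5, seed = 62)
  pooled <- pool_trajectories(list(g1$trajectory, g2$trajectory))
  expect_equal(n_frames(pooled), 70)
  a <- residue_selection("A", 2); b <- residue_selection("A", 9)
  d1 <- group_distance_series(g1$trajectory, a, b, "ca")$values
  d2 <- group_distance_series(g2$trajectory, a, b, "ca")$values
  dp <- group_distance_series(pooled, a, b, "ca")$values
  expect_equal(dp, c(d1, d2))
  s <- series_summary(list(time_series("d", d1), time_series("d", d2)))
  expect_equal(s$mean, mean(c(d1, d2)))
})

test_that("multi-model PDB trajectory round-trips through write/read", {
  g <- make_gaussian_trajectory(6, 5, sigma = 0.3, seed = 63)
  p <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g$trajectory, p)
  back <- read_trajectory(p)
  expect_equal(n_frames(back), 5)
  expect_equal(back$topology$resno, 1:6)
  expect_equal(back$coords, g$trajectory$coords, tolerance = 1e-3)
})
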