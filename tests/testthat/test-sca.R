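test_that("sequence weights count identity neighbourhoods", {
  # three mutually dissimilar sequences
  aln <- alignment(c("a", "b", "c"), c("AAAAA", "CCCCC", "DDDDD"))
  sw <- sequence_weights(aln)
  expect_equal(sw$weights, c(1, 1, 1))
  expect_equal(sw$Meff, 3)

  # two identical + one distinct
  aln2 <- alignment(c("a", "b", "c"), c("AAAAA", "AAAAA", "CCCCC"))
  sw2 <- sequence_weights(aln2)
  expect_equal(sw2$weights, c(0.5, 0.5, 1))

  # n copies of one sequence
  aln3 <- alignment(sprintf("s%d", 1:5), rep("ACDEF", 5))
  sw3 <- sequence_weights(aln3)
  expect_equal(sw3$Meff, 1)
})

test_that("regularized frequencies match the closed form", {
  # single sequence, lambda 0: delta distribution
  fm0 <- suppressWarnings(weighted_frequencies(alignment("s", "AA"),
                                               lambda = 0))
  expect_equal(fm0$f1[1, 1], 1)
  expect_equal(sum(fm0$f1[1, -1]), 0)

  # single sequence, lambda 0.03: 0.97 + 0.03/20
  fm <- weighted_frequencies(alignment("s", "AA"), lambda = 0.03)
  expect_equal(fm$f1[1, 1], 0.9715)
  expect_equal(fm$f1[1, 2], 0.03 / 20)

  # two equal-weight sequences A/C at one column
  fm2 <- weighted_frequencies(alignment(c("a", "b"), c("A", "C")),
                              lambda = 0)
  expect_equal(fm2$f1[1, 1], 0.5)
  expect_equal(fm2$f1[1, 2], 0.5)

  # frequency + gap mass sums to 1 per position
  aln <- alignment(c("a", "b", "c"), c("A-D", "ACD", "AC-"))
  fm3 <- weighted_frequencies(aln, lambda = 0.03)
  gapmass <- (1 - 0.03) * c(0, 1 / 3, 1 / 3)
  expect_equal(rowSums(fm3$f1) + gapmass, rep(1, 3), tolerance = 1e-9)

  # pairwise joint marginalizes to f1 at gap-free columns (lambda 0)
  fm4 <- suppressWarnings(weighted_frequencies(
    alignment(c("a", "b"), c("AC", "AD")), lambda = 0))
  blk <- fm4$f2[1:20, 21:40]
  expect_equal(rowSums(blk), fm4$f1[1, ], tolerance = 1e-9)

  expect_warning(weighted_frequencies(alignment(c("a", "b"), c("A", "A")),
                                      lambda = 0), "conserved")
})

test_that("coupling matrix equals the quadruple-loop oracle (L <= 4)", {
  # 3-residue alphabet, several small alignments
  set.seed(7)
  for (L in 2:4) {
    seqs <- vapply(1:12, function(i)
      paste(sample(c("A", "C", "D"), L, replace = TRUE), collapse = ""),
      character(1))
    aln <- alignment(sprintf("s%02d", 1:12), seqs)
    cm <- coupling_matrix(weighted_frequencies(aln, lambda = 0.03))
    oracle <- naive_coupling(seqs, lambda = 0.03)
    diag(oracle) <- 0
    expect_lt(max(abs(cm$scores - oracle)), 1e-10)
  }
})

test_that("coupling detects covariation and respects invariances", {
  # two perfectly covarying binary columns beat independent pairs
  set.seed(11)
  n <- 400
  cls <- sample(c(TRUE, FALSE), n, replace = TRUE)
  cov2 <- ifelse(cls, "AA", "CC")
  indep <- vapply(1:n, function(i)
    paste(sample(c("D", "E", "F", "G"), 2, replace = TRUE), collapse = ""),
    character(1))
  aln <- alignment(sprintf("s%d", 1:n), paste0(cov2, indep))
  cm <- coupling_matrix(weighted_frequencies(aln, rep(1, n)))
  expect_gt(cm$scores[1, 2], max(cm$scores[3, 4], cm$scores[1, 3],
                                 cm$scores[2, 4]))
  expect_true(isSymmetric(cm$scores))
  expect_true(all(diag(cm$scores) == 0))
  expect_true(all(cm$scores >= 0))

  # permuting sequences leaves scores unchanged
  set.seed(12)
  perm <- sample(n)
  aln_p <- alignment(aln$ids[perm], aln$seqs[perm])
  cm_p <- coupling_matrix(weighted_frequencies(aln_p, rep(1, n)))
  expect_equal(cm_p$scores, cm$scores, tolerance = 1e-12)

  # permuting columns permutes scores identically
  colperm <- c(3, 1, 4, 2)
  seqs_cp <- vapply(strsplit(aln$seqs, ""), function(ch)
    paste(ch[colperm], collapse = ""), character(1))
  aln_cp <- alignment(aln$ids, seqs_cp)
  cm_cp <- coupling_matrix(weighted_frequencies(aln_cp, rep(1, n)))
  expect_equal(cm_cp$scores, cm$scores[colperm, colperm],
               tolerance = 1e-12)

  # independent columns at large n: couplings shrink toward 0
  set.seed(13)
  n2 <- 4000
  seqs_ind <- vapply(1:n2, function(i)
    paste(sample(c("A", "C", "D", "E"), 4, replace = TRUE), collapse = ""),
    character(1))
  cmi <- coupling_matrix(weighted_frequencies(
    alignment(sprintf("s%d", 1:n2), seqs_ind), rep(1, n2)))
  expect_lt(max(cmi$scores), 0.5 * cm$scores[1, 2])
})

test_that("column shuffling destroys the planted coupling signal", {
  sim <- make_coupled_msa(300, 30, planted_set = c(5, 15, 25), p = 0.95,
                          seed = 3)
  aln <- sim$alignment
  cm <- coupling_matrix(weighted_frequencies(aln, rep(1, 300)))
  pre <- cluster_coupling_matrix(cm)$top_cluster_score
  drops <- 0L
  n_shuffles <- 20
  for (s in seq_len(n_shuffles)) {
    set.seed(100 + s)
    ch <- do.call(rbind, strsplit(aln$seqs, ""))
    for (j in seq_len(ncol(ch))) ch[, j] <- ch[sample(nrow(ch)), j]
    shuf <- alignment(aln$ids, apply(ch, 1, paste, collapse = ""))
    cms <- coupling_matrix(weighted_frequencies(shuf, rep(1, 300)))
    top <- tryCatch(cluster_coupling_matrix(cms)$top_cluster_score,
                    error = function(e) 0)
    if (top < pre) drops <- drops + 1L
  }
  expect_gte(drops, 0.95 * n_shuffles)
})

test_that("fraction_above counts strict exceedances over all pairs", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 0.3
  sc[1, 3] <- sc[3, 1] <- 0.1
  sc[2, 3] <- sc[3, 2] <- 0.2
  cm <- structure(list(scores = sc, column_labels = 1:3),
                  class = "coupling_matrix")
  expect_equal(fraction_above(cm, 0.25), 1 / 3)
  expect_equal(fraction_above(cm, 0.05), 1.0)
  cm0 <- structure(list(scores = matrix(0, 4, 4), column_labels = 1:4),
                   class = "coupling_matrix")
  expect_equal(fraction_above(cm0, 0.25), 0.0)
})

test_that("clustering extracts a planted block and labels via posmap", {
  # block-diagonal coupling: a 5-position block of 1.0 and a weakly
  # self-coupled background (~0.1), zero across -- two diagonal blocks,
  # so the 2-cluster cut is tie-free
  L <- 12
  set.seed(14)
  blk <- 3:7
  bg <- setdiff(seq_len(L), blk)
  sc <- matrix(0, L, L)
  noise <- matrix(runif(length(bg)^2, 0.05, 0.15), length(bg))
  sc[bg, bg] <- (noise + t(noise)) / 2
  sc[blk, blk] <- 1
  diag(sc) <- 0
  cm <- structure(list(scores = sc, column_labels = seq_len(L)),
                  class = "coupling_matrix")
  cl <- cluster_coupling_matrix(cm, n_clusters = 2)
  expect_equal(sort(cl$top_cluster), blk)
  expect_equal(cl$top_cluster_score, 1)
  # brute force: no other contiguous or random subset beats the block
  set.seed(15)
  for (r in 1:50) {
    sub <- sample(L, sample(2:6, 1))
    expect_lte(coevdyn:::cluster_mean_coupling(sc, sub),
               cl$top_cluster_score)
  }

  # default gap cut finds the same block, also on an exact-zero
  # background
  sc0 <- matrix(0, L, L)
  sc0[blk, blk] <- 1
  diag(sc0) <- 0
  cm0 <- structure(list(scores = sc0, column_labels = seq_len(L)),
                   class = "coupling_matrix")
  cl2 <- cluster_coupling_matrix(cm0)
  expect_equal(sort(cl2$top_cluster), blk)

  # L = 2: single merge, top cluster is the pair
  sc2 <- matrix(c(0, 0.4, 0.4, 0), 2)
  cm2 <- structure(list(scores = sc2, column_labels = 1:2),
                   class = "coupling_matrix")
  cl3 <- cluster_coupling_matrix(cm2)
  expect_equal(sort(cl3$top_cluster), 1:2)

  expect_error(cluster_coupling_matrix(
    structure(list(scores = matrix(0, 3, 3), column_labels = 1:3),
              class = "coupling_matrix")), "no coupling signal")

  # planted-coupling MSA: top cluster equals the planted set, and a
  # posmap reports it in reference numbering
  sim <- make_coupled_msa(1000, 100, planted_set = c(10, 30, 50, 70, 90),
                          p = 0.9, seed = 1)
  sw <- sequence_weights(sim$alignment)
  cmp <- coupling_matrix(weighted_frequencies(sim$alignment, sw$weights))
  pm <- map_to_reference(sim$alignment, sim$alignment$ids[1], 201)
  clp <- cluster_coupling_matrix(cmp, posmap = pm)
  expect_equal(sort(clp$top_cluster), c(10L, 30L, 50L, 70L, 90L))
  expect_equal(sort(clp$top_cluster_labels),
               c(210L, 230L, 250L, 270L, 290L))
})
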