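# Statistical coupling analysis: conservation-weighted covariance of the
# positional amino-acid distributions in a filtered alignment.

#' Sequence weights for redundancy down-weighting
#'
#' Weight of a sequence is 1 / (number of sequences, including itself, with
#' pairwise identity >= `identity_cutoff` to it). The sum of weights is the
#' effective sequence count Meff.
#'
#' @param aln an [alignment].
#' @param identity_cutoff neighbourhood identity threshold; default 0.8.
#' @return list with `weights` (numeric vector) and `Meff`.
#' @export
sequence_weights <- function(aln, identity_cutoff = 0.8) {
  stopifnot(inherits(aln, "alignment"))
  id <- identity_matrix(aln)
  counts <- rowSums(id >= identity_cutoff)
  w <- 1 / counts
  list(weights = w, Meff = sum(w))
}

#' Regularized weighted positional frequencies
#'
#' Computes per-position residue frequencies and per-position-pair joint
#' frequencies from a weighted alignment, shrunk toward background
#' frequencies with a pseudocount:
#' \deqn{f_i^a = (1-\lambda)\,\hat f_i^a + \lambda q^a,\qquad
#'       f_{ij}^{ab} = (1-\lambda)\,\hat f_{ij}^{ab} + \lambda q^a q^b.}
#' Gaps contribute no residue mass (frequencies are over the 20 residues
#' only), so column sums can fall below 1 by the gap mass.
#'
#' @param aln an [alignment].
#' @param weights per-sequence weights (e.g. from [sequence_weights()]);
#'   default the alignment's stored weights.
#' @param lambda pseudocount weight in \[0, 1); default 0.03.
#' @param background `"uniform"` (1/20 each) or a length-20 numeric vector
#'   of background frequencies summing to 1, named or ordered as
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @return a `frequency_model`: list with `f1` (L x 20), `f2`
#'   ((20L) x (20L), block (i,j) holding the 20 x 20 joint table),
#'   `q`, `lambda`, `weights`, `Meff`, `column_labels`, and
#'   `conserved` (columns with an absolutely conserved residue, which make
#'   the positional weight undefined at `lambda = 0`).
#' @export
weighted_frequencies <- function(aln, weights = aln$weights, lambda = 0.03,
                                 background = "uniform") {
  stopifnot(inherits(aln, "alignment"))
  if (length(weights) != length(aln$seqs)) {
    stop("weights length must match number of sequences")
  }
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  q <- if (identical(background, "uniform")) rep(1 / 20, 20)
       else {
         if (length(background) != 20) stop("background must have length 20")
         as.numeric(background) / sum(background)
       }
  m <- aln_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  wn <- weights / sum(weights)
  # one-hot over (position, residue), column block of 20 per position
  X <- matrix(0, n, 20L * L)
  pos_of <- rep(seq_len(L), each = 20L)
  aa_of <- rep(seq_len(20L), times = L)
  nz <- which(m != 0L, arr.ind = TRUE)
  X[cbind(nz[, 1], (nz[, 2] - 1L) * 20L + m[nz])] <- 1
  f1_raw <- as.numeric(crossprod(X, wn))            # length 20L
  f2_raw <- crossprod(X, X * wn)                    # (20L) x (20L)
  qvec <- q[aa_of]
  f1 <- (1 - lambda) * f1_raw + lambda * qvec
  f2 <- (1 - lambda) * f2_raw + lambda * tcrossprod(qvec)
  f1_mat <- matrix(f1, nrow = L, ncol = 20, byrow = TRUE)
  conserved <- which(apply(matrix(f1_raw, L, 20, byrow = TRUE), 1,
                           function(r) any(r >= 1 - 1e-12)))
  if (lambda == 0 && length(conserved)) {
    warning("absolutely conserved position(s) with lambda = 0: positional ",
            "weights are undefined downstream (columns ",
            paste(conserved, collapse = ","), ")")
  }
  structure(list(f1 = f1_mat, f2 = f2, q = q, lambda = lambda,
                 weights = weights, Meff = sum(weights),
                 column_labels = aln$column_labels, conserved = conserved,
                 pos_of = pos_of, aa_of = aa_of),
            class = "frequency_model")
}

#' SCA positional coupling matrix
#'
#' From a [weighted_frequencies()] model, computes the conservation weight
#' \eqn{\phi_i^a = \ln[f_i^a(1-q^a) / ((1-f_i^a) q^a)]} (the derivative of
#' the positional relative entropy), the weighted covariance tensor
#' \eqn{\tilde C_{ij}^{ab} = \phi_i^a \phi_j^b (f_{ij}^{ab} -
#' f_i^a f_j^b)}, and reduces it to one non-negative score per position
#' pair by the Frobenius norm over the residue indices. The diagonal is
#' set to zero by convention. \eqn{\phi} is clipped to \eqn{\pm 50}.
#'
#' @param freqs a `frequency_model` with `lambda > 0`.
#' @return a `coupling_matrix`: list with `scores` (L x L symmetric,
#'   non-negative, zero diagonal), `phi` (L x 20), `column_labels`.
#' @export
coupling_matrix <- function(freqs) {
  stopifnot(inherits(freqs, "frequency_model"))
  f1 <- freqs$f1; q <- freqs$q
  if (freqs$lambda <= 0 &&
      (any(f1 <= 0) || any(f1 >= 1))) {
    stop("frequencies at 0 or 1 make the positional weight undefined; ",
         "use a pseudocount lambda > 0")
  }
  L <- nrow(f1)
  phi <- log(f1 * (1 - rep(q, each = L)) /
             ((1 - f1) * rep(q, each = L)))
  phi <- pmin(pmax(phi, -50), 50)
  f1_vec <- as.numeric(t(f1))                       # (i,a) flattened, 20 fast
  phi_vec <- as.numeric(t(phi))
  Cab <- freqs$f2 - tcrossprod(f1_vec)
  Wab <- Cab * tcrossprod(phi_vec)
  S <- Wab * Wab
  # Frobenius norm per 20x20 block: group rows then columns by position
  g <- rep(seq_len(L), each = 20L)
  Srow <- rowsum(S, g)                              # L x (20L)
  Ssum <- t(rowsum(t(Srow), g))                     # L x L
  scores <- sqrt(pmax(Ssum, 0))
  dimnames(scores) <- NULL
  diag(scores) <- 0
  scores <- (scores + t(scores)) / 2                # enforce exact symmetry
  structure(list(scores = scores, phi = phi,
                 column_labels = freqs$column_labels),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  L <- nrow(x$scores)
  off <- x$scores[upper.tri(x$scores)]
  cat("coupling_matrix:", L, "x", L, "; off-diagonal score range [",
      format(min(off), digits = 4), ",", format(max(off), digits = 4),
      "]\n")
  invisible(x)
}

#' Fraction of position pairs above a coupling threshold
#'
#' @param cm a `coupling_matrix`.
#' @param threshold score threshold (strict `>`).
#' @param normalized if `TRUE`, scores are first divided by the maximum
#'   off-diagonal score.
#' @return fraction of the L(L-1)/2 unordered off-diagonal pairs with
#'   score above `threshold`.
#' @export
fraction_above <- function(cm, threshold, normalized = FALSE) {
  stopifnot(inherits(cm, "coupling_matrix"))
  L <- nrow(cm$scores)
  if (L < 2) stop("need at least 2 positions")
  off <- cm$scores[upper.tri(cm$scores)]
  if (normalized) off <- off / max(off)
  sum(off > threshold) / (L * (L - 1) / 2)
}

# mean intra-cluster off-diagonal coupling for a member index set
cluster_mean_coupling <- function(scores, members) {
  if (length(members) < 2) return(-Inf)
  sub <- scores[members, members]
  mean(sub[upper.tri(sub)])
}

#' Extract the top coevolving cluster from a coupling matrix
#'
#' Average-linkage hierarchical clustering of the distance
#' `1 - score / max(score)` (max over off-diagonal entries). The tree is
#' cut either at a requested `n_clusters`/`height`, or (default) at the
#' midpoint of the largest gap in the sorted merge heights, which
#' separates the tightly coupled core (low merge heights) from the
#' weakly coupled background. The top cluster is the cluster of size
#' `>= min_size` with maximal mean intra-cluster off-diagonal coupling.
#'
#' @param cm a `coupling_matrix`.
#' @param n_clusters optional fixed number of clusters.
#' @param height optional dendrogram cut height (overrides the automatic
#'   rule, ignored if `n_clusters` given).
#' @param min_size minimum cluster size considered for the top cluster;
#'   default 2.
#' @param posmap optional `position_map`; when given, cluster members are
#'   reported as reference residue numbers.
#' @return a `cluster_result`: list with `linkage` (the `hclust` object),
#'   `k`, `membership` (integer vector), `top_cluster` (column indices),
#'   `top_cluster_labels` (residue numbers via `posmap`, or original
#'   column labels), `top_cluster_score`.
#' @export
cluster_coupling_matrix <- function(cm, n_clusters = NULL, height = NULL,
                                    min_size = 2, posmap = NULL) {
  stopifnot(inherits(cm, "coupling_matrix"))
  scores <- cm$scores
  L <- nrow(scores)
  if (L < 2) stop("need at least 2 positions to cluster")
  mx <- max(scores[upper.tri(scores)])
  if (mx <= 0) stop("no coupling signal: all off-diagonal scores are zero")
  d <- 1 - scores / mx
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  best_of <- function(mem) {
    sizes <- table(mem)
    cand <- as.integer(names(sizes)[sizes >= min_size])
    if (!length(cand)) return(list(score = -Inf, mem = mem, top = integer(0)))
    sc <- vapply(cand, function(cl)
      cluster_mean_coupling(scores, which(mem == cl)), numeric(1))
    b <- cand[which.max(sc)]
    list(score = max(sc), mem = mem, top = which(mem == b))
  }
  if (!is.null(n_clusters)) {
    res <- best_of(stats::cutree(hc, k = n_clusters))
  } else if (!is.null(height)) {
    res <- best_of(stats::cutree(hc, h = height))
  } else {
    hts <- sort(hc$height)
    if (length(hts) < 2) {
      res <- best_of(rep(1L, L))      # single merge: one cluster
    } else {
      g <- which.max(diff(hts))
      res <- best_of(stats::cutree(hc, h = (hts[g] + hts[g + 1]) / 2))
    }
  }
  k <- length(unique(res$mem))
  top <- unname(res$top)
  labels <- cm$column_labels[top]
  if (!is.null(posmap)) {
    idx <- match(top, posmap$column)
    labels <- posmap$residue[idx]
  }
  structure(list(linkage = hc, k = k, membership = res$mem,
                 top_cluster = top, top_cluster_labels = labels,
                 top_cluster_score = res$score),
            class = "cluster_result")
}

#' Write a coupling matrix as TSV and edge list
#'
#' @param cm a `coupling_matrix`.
#' @param prefix output path prefix; writes `<prefix>_matrix.tsv` (dense,
#'   with column labels as headers) and `<prefix>_edges.tsv`
#'   (pos_i, pos_j, score for the upper triangle).
#' @return the two paths, invisibly.
#' @export
write_coupling_matrix <- function(cm, prefix) {
  m <- cm$scores
  dimnames(m) <- list(cm$column_labels, cm$column_labels)
  p1 <- paste0(prefix, "_matrix.tsv")
  utils::write.table(m, p1, sep = "\t", quote = FALSE)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  edges <- data.frame(pos_i = cm$column_labels[ut[, 1]],
                      pos_j = cm$column_labels[ut[, 2]],
                      score = m[ut])
  p2 <- paste0(prefix, "_edges.tsv")
  utils::write.table(edges, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
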