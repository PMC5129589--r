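# Independent oracles used by the tests.  Each re-derives the quantity the
# package computes through a different algorithm, so agreement is a real
# cross-check rather than a re-run of the implementation.

# Horn quaternion method: best-fit RMSD from the largest eigenvalue of the
# 4x4 key matrix (independent of the SVD-based Kabsch path).
quaternionRmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lmax)) / nrow(A))
}

# Naive O(n^3) agglomerative average linkage with an epsilon stop:
# repeatedly merge the closest pair of clusters while their average
# inter-cluster distance is at most eps.
naiveAverageLinkage <- function(D, eps) {
  clusters <- as.list(seq_len(nrow(D)))
  while (length(clusters) > 1) {
    bestd <- Inf; best <- c(NA, NA)
    for (a in seq_len(length(clusters) - 1))
      for (b in seq.int(a + 1, length(clusters))) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestd) { bestd <- d; best <- c(a, b) }
      }
    if (bestd > eps) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  assign <- integer(nrow(D))
  for (k in seq_along(clusters)) assign[clusters[[k]]] <- k
  assign
}

# two partitions identical up to label permutation?
samePartition <- function(a, b) {
  all(rowSums(table(a, b) > 0) == 1) && all(colSums(table(a, b) > 0) == 1)
}

# Kaplan-Meier survival table and restricted mean from first principles.
kmHandTable <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time[event]))
  S <- 1; curve <- data.frame(time = 0, surv = 1)
  for (t in ut) {
    atRisk <- sum(time >= t)
    d <- sum(time == t & event)
    S <- S * (1 - d / atRisk)
    curve <- rbind(curve, data.frame(time = t, surv = S))
  }
  tmax <- max(time)
  knots <- c(curve$time, tmax)
  rmean <- sum(curve$surv * pmax(0, diff(knots)))
  list(curve = curve, rmean = rmean)
}

# random rigid motion applied to an n x 3 matrix
applyRigidMotion <- function(xyz, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% R, 2, rnorm(3, 0, 10), "+")
}
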