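# Conformational and torsional clustering, and disulfide handedness.

#' Pairwise best-fit RMSD matrix of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param selection selection preset, see [selectAtoms()].
#' @return symmetric n x n matrix of best-fit RMSDs (A).
#' @export
pairwiseRmsd <- function(traj, selection = "CA+CB") {
  idx <- selectAtoms(traj, selection)
  n <- nFrames(traj)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    D[i, j] <- D[j, i] <-
      kabschSuperpose(traj@coords[idx, , i], traj@coords[idx, , j])$rmsd
  }
  D
}

#' Average-linkage conformational clustering with an epsilon stop
#'
#' Agglomerative clustering on the pairwise best-fit RMSD of the selected
#' atoms: the closest pair of clusters (average linkage) is merged while
#' the minimum average inter-cluster distance is at most `epsilon`.
#' Average linkage is monotone, so this equals cutting the
#' [stats::hclust()] dendrogram at height `epsilon`.  Clusters are ordered
#' by decreasing population (ties by lowest member frame index).  The
#' average conformation of a cluster is the coordinate mean of its members
#' after alignment onto the cluster medoid; no minimisation is applied.
#'
#' @param traj a [Trajectory-class].
#' @param selection RMSD selection, default all alpha and beta carbons.
#' @param epsilon stop distance, A.
#' @return list with `assignments` (frame to cluster id, 1 = largest),
#'   `populations` (fractions summing to 1), `medoids` (frame indices),
#'   `averages` (list of nAtoms x 3 mean-coordinate matrices) and
#'   `distances` (the RMSD matrix).
#' @export
averageLinkageCluster <- function(traj, selection = "CA+CB", epsilon = 2.0) {
  n <- nFrames(traj)
  D <- pairwiseRmsd(traj, selection)
  raw <- if (n == 1) rep(1L, 1) else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    stats::cutree(hc, h = epsilon)
  }
  sizes <- table(raw)
  firstMember <- tapply(seq_len(n), raw, min)
  ord <- order(-as.integer(sizes), as.integer(firstMember))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  assignments <- relabel[raw]
  k <- max(assignments)
  idx <- selectAtoms(traj, selection)
  medoids <- integer(k)
  averages <- vector("list", k)
  for (c in seq_len(k)) {
    members <- which(assignments == c)
    if (length(members) == 1) {
      medoids[c] <- members
      averages[[c]] <- traj@coords[, , members]
      next
    }
    within <- rowSums(D[members, members, drop = FALSE])
    medoids[c] <- members[which.min(within)]
    refSel <- traj@coords[idx, , medoids[c]]
    acc <- matrix(0, nAtoms(traj), 3)
    for (m in members) {
      fit <- kabschSuperpose(traj@coords[idx, , m], refSel)
      ctr <- colMeans(traj@coords[idx, , m])
      moved <- sweep(traj@coords[, , m], 2, ctr) %*% fit$rotation
      acc <- acc + sweep(moved, 2, colMeans(refSel), "+")
    }
    averages[[c]] <- acc / length(members)
  }
  list(assignments = assignments,
       populations = as.numeric(table(factor(assignments, seq_len(k)))) / n,
       medoids = medoids, averages = averages, distances = D)
}

#' Leader clustering of disulfide torsion sets
#'
#' Torsion sets are processed in frame order; a set joins the first
#' existing cluster whose leader differs by less than `threshold` degrees
#' (wrapped difference) in all five torsions, otherwise it founds a new
#' cluster.  Two sets are "different" when any one torsion differs by the
#' threshold or more.
#'
#' @param sets numeric matrix with five columns (degrees), one row per
#'   frame, spanning N-CA-CB-SG / CA-CB-SG-SG' / CB-SG-SG'-CB' /
#'   SG-SG'-CB'-CA' / SG'-CB'-CA'-N'.
#' @param threshold difference criterion, degrees.
#' @return list with `assignments`, `leaders` (row indices of founding
#'   sets), `occurrence` (fractions summing to 1) and `handedness` (per
#'   cluster, from the leader's central torsion).
#' @export
torsionCluster <- function(sets, threshold = 60) {
  sets <- as.matrix(sets)
  if (ncol(sets) != 5) stopUsage("torsion sets must have five columns")
  if (threshold <= 0) stopUsage("threshold must be positive")
  leaders <- integer()
  assignments <- integer(nrow(sets))
  for (i in seq_len(nrow(sets))) {
    placed <- FALSE
    for (c in seq_along(leaders)) {
      if (all(angleDiff(sets[i, ], sets[leaders[c], ]) < threshold)) {
        assignments[i] <- c; placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      assignments[i] <- length(leaders)
    }
  }
  occ <- as.numeric(table(factor(assignments, seq_along(leaders)))) / nrow(sets)
  hand <- vapply(leaders, function(l) disulfideHandedness(sets[l, ]),
                 character(1))
  list(assignments = assignments, leaders = leaders, occurrence = occ,
       handedness = hand)
}

#' Handedness of a disulfide bond
#'
#' Classified from the sign of the central CB-SG-SG'-CB' dihedral: positive
#' is a right-handed spiral, negative left-handed (standard stereochemical
#' usage).  Exactly 0 or +/-180 degrees is indeterminate.
#'
#' @param torsionSet length-5 torsion set (the third entry is the central
#'   dihedral) or a single central dihedral, degrees.
#' @return `"right"`, `"left"` or `"indeterminate"`.
#' @export
disulfideHandedness <- function(torsionSet) {
  mid <- if (length(torsionSet) >= 3) torsionSet[3] else torsionSet[1]
  mid <- wrapAngle(mid)
  if (mid == 0 || mid == 180) return("indeterminate")
  if (mid > 0) "right" else "left"
}
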