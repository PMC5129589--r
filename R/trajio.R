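# Structure/trajectory I/O and geometric primitives.

#' Read a multi-model PDB file into a Trajectory
#'
#' Models become frames; atom identity (residue number + atom name) must be
#' constant across models.  Reading is delegated to [bio3d::read.pdb()].
#'
#' @param file path to a PDB file, or its content as a character vector of
#'   lines.
#' @param saveInterval ns of standard-mass time per saved frame.
#' @param originTime ns, time of the first frame.
#' @return a [Trajectory-class].
#' @export
readMultiModelPDB <- function(file, saveInterval = 1, originTime = saveInterval) {
  if (length(file) > 1 || grepl("\n", file[1])) {
    lines <- if (length(file) > 1) file else strsplit(file, "\n")[[1]]
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(lines, file)
  } else {
    lines <- readLines(file)
  }
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stopUsage("unbalanced MODEL/ENDMDL records")
    counts <- vapply(seq_along(starts), function(k)
      sum(grepl("^(ATOM|HETATM)", lines[starts[k]:ends[k]])), integer(1))
    if (length(unique(counts)) != 1)
      stopUsage("inconsistent atom counts across models: ",
                paste(unique(counts), collapse = ", "))
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nframe <- nrow(xyz)
  natom <- ncol(xyz) / 3
  coords <- aperm(array(t(xyz), dim = c(3, natom, nframe)), c(2, 1, 3))
  atoms <- data.frame(
    name = pdb$atom$elety,
    resno = pdb$atom$resno,
    resname = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    element = ifelse(is.na(pdb$atom$elesy) | !nzchar(trimws(pdb$atom$elesy)),
                     guessElement(pdb$atom$elety), trimws(pdb$atom$elesy)),
    stringsAsFactors = FALSE)
  Trajectory(coords, atoms, saveInterval = saveInterval, originTime = originTime)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' @param traj a [Trajectory-class].
#' @param file optional output path.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
writeMultiModelPDB <- function(traj, file = NULL) {
  at <- atomData(traj)
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  sprintf("%-4s", at$name))
  out <- character()
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[, , f, drop = FALSE]
    out <- c(out, sprintf("MODEL     %4d", f),
             sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nAtoms(traj)), name4, at$resname, at$chain,
                     at$resno, xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1],
                     1, 0, at$element),
             "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Select atom indices of a Trajectory
#'
#' Presets: `"CA"` (alpha carbons), `"CA+CB"` (alpha and beta carbons;
#' glycine contributes only its CA), `"carbon"` (every carbon atom),
#' `"backbone"` (CA, C, N, O), `"all"`.
#'
#' @param traj a [Trajectory-class] (or its atom data.frame).
#' @param selection preset name, or a character vector of atom names.
#' @param residues optional residue numbers to restrict to.
#' @return integer vector of atom indices.
#' @export
selectAtoms <- function(traj, selection = "CA", residues = NULL) {
  at <- if (is(traj, "Trajectory")) atomData(traj) else traj
  idx <- switch(selection[1],
    "CA" = which(at$name == "CA"),
    "CA+CB" = which(at$name %in% c("CA", "CB")),
    "carbon" = which(at$element == "C"),
    "backbone" = which(at$name %in% c("CA", "C", "N", "O")),
    "all" = seq_len(nrow(at)),
    which(at$name %in% selection))
  if (!is.null(residues)) idx <- idx[at$resno[idx] %in% residues]
  if (!length(idx)) stopUsage("empty atom selection: ", selection[1])
  idx
}

# match selected atoms of traj to the reference by (resno, name)
matchSelection <- function(trajAtoms, refAtoms, selection, residues = NULL) {
  ti <- selectAtoms(trajAtoms, selection, residues)
  ri <- selectAtoms(refAtoms, selection, residues)
  tk <- paste(trajAtoms$resno[ti], trajAtoms$name[ti])
  rk <- paste(refAtoms$resno[ri], refAtoms$name[ri])
  common <- intersect(tk, rk)
  if (length(common) < 3)
    stopUsage("fewer than 3 matched atoms for selection ", selection[1])
  list(traj = ti[match(common, tk)], ref = ri[match(common, rk)])
}

#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` (unweighted),
#' via singular value decomposition of the covariance matrix with the
#' proper-rotation sign correction, so the returned rotation always has
#' determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices in 1:1 row
#'   correspondence, n >= 3 and not collinear.
#' @return list with `rotation` (3 x 3), `translation` (length-3; the fit
#'   is `sweep(mobile, 2, centerM) %*% rotation + centerR`), `rmsd` (A)
#'   and `fitted` (transformed mobile coordinates).
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stopUsage("coordinate sets differ in atom count")
  if (nrow(mobile) < 3) stopUsage("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2) stopUsage("degenerate (collinear) geometry")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  fitted <- sweep(A %*% R, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr - cm %*% R, rmsd = rmsd, fitted = fitted)
}

asReferenceFrame <- function(reference) {
  if (is(reference, "Trajectory"))
    list(coords = frameCoords(reference, 1), atoms = atomData(reference))
  else reference
}

#' Per-frame best-fit RMSD of a trajectory against a reference
#'
#' Every frame is rigidly fitted (unweighted) onto the reference on the
#' requested selection before the deviation is measured on that same
#' selection.  Atoms are matched by (residue number, atom name).
#'
#' @param traj a [Trajectory-class].
#' @param reference a single-frame [Trajectory-class] (or list with
#'   `coords` and `atoms`).
#' @param selection selection preset, see [selectAtoms()].
#' @return data.frame with columns `time` (ns) and `rmsd` (A); attributes
#'   `selection` and `n_atoms`.
#' @export
rmsdSeries <- function(traj, reference, selection = "CA+CB") {
  ref <- asReferenceFrame(reference)
  m <- matchSelection(atomData(traj), ref$atoms, selection)
  refXYZ <- ref$coords[m$ref, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    kabschSuperpose(traj@coords[m$traj, , f], refXYZ)$rmsd, numeric(1))
  out <- data.frame(time = frameTimes(traj), rmsd = vals)
  attr(out, "selection") <- selection
  attr(out, "n_atoms") <- length(m$traj)
  out
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: 0 for cis, 180 for trans, result in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (A).
#' @return angle in degrees.
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stopUsage("degenerate dihedral geometry")
  m1 <- n1 / sqrt(sum(n1^2)); m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(c(m1[2] * b2u[3] - m1[3] * b2u[2],
             m1[3] * b2u[1] - m1[1] * b2u[3],
             m1[1] * b2u[2] - m1[2] * b2u[1]) * m2)
  wrapAngle(atan2(y, x) * 180 / pi)
}

#' Backbone torsion specifications for a trajectory
#'
#' Builds the phi (C', N, CA, C) and psi (N, CA, C, N') quadruples for
#' every residue that has the required neighbours, plus chi1
#' (N, CA, CB, gamma atom) for residues with a gamma heavy atom.
#'
#' @param traj a [Trajectory-class].
#' @param torsions subset of `c("phi", "psi", "chi1")`.
#' @return data.frame with columns `torsion`, `residue` and `res1`,
#'   `atom1` .. `res4`, `atom4`, one row per resolvable torsion.
#' @export
backboneTorsionSpecs <- function(traj, torsions = c("phi", "psi", "chi1")) {
  at <- atomData(traj)
  res <- sort(unique(at$resno))
  has <- function(r, name) any(at$resno == r & at$name == name)
  rows <- list()
  gammaNames <- c("CG", "CG1", "OG", "OG1", "SG", "CG2")
  for (r in res) {
    if ("phi" %in% torsions && has(r - 1, "C") && has(r, "N") &&
        has(r, "CA") && has(r, "C"))
      rows[[length(rows) + 1]] <- data.frame(
        torsion = "phi", residue = r,
        res1 = r - 1, atom1 = "C", res2 = r, atom2 = "N",
        res3 = r, atom3 = "CA", res4 = r, atom4 = "C",
        stringsAsFactors = FALSE)
    if ("psi" %in% torsions && has(r, "N") && has(r, "CA") &&
        has(r, "C") && has(r + 1, "N"))
      rows[[length(rows) + 1]] <- data.frame(
        torsion = "psi", residue = r,
        res1 = r, atom1 = "N", res2 = r, atom2 = "CA",
        res3 = r, atom3 = "C", res4 = r + 1, atom4 = "N",
        stringsAsFactors = FALSE)
    if ("chi1" %in% torsions && has(r, "CB")) {
      g <- gammaNames[vapply(gammaNames, function(nm) has(r, nm), logical(1))]
      if (length(g))
        rows[[length(rows) + 1]] <- data.frame(
          torsion = "chi1", residue = r,
          res1 = r, atom1 = "N", res2 = r, atom2 = "CA",
          res3 = r, atom3 = "CB", res4 = r, atom4 = g[1],
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compute torsion angle series over a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param specs data.frame as produced by [backboneTorsionSpecs()]: one row
#'   per torsion with columns `torsion`, `residue`, `res1`, `atom1` ..
#'   `res4`, `atom4`.
#' @return data.frame with columns `frame`, `time`, `torsion`, `residue`,
#'   `angle` (degrees).
#' @export
torsionSeries <- function(traj, specs = backboneTorsionSpecs(traj)) {
  if (is.null(specs) || !nrow(specs))
    stopUsage("no resolvable torsions in this trajectory")
  at <- atomData(traj)
  key <- paste(at$resno, at$name)
  idx <- matrix(NA_integer_, nrow(specs), 4)
  for (k in 1:4) {
    want <- paste(specs[[paste0("res", k)]], specs[[paste0("atom", k)]])
    idx[, k] <- match(want, key)
    if (anyNA(idx[, k])) {
      bad <- which(is.na(idx[, k]))[1]
      stopUsage("cannot resolve atom ", want[bad], " for torsion ",
                specs$torsion[bad], " of residue ", specs$residue[bad])
    }
  }
  times <- frameTimes(traj)
  out <- vector("list", nFrames(traj))
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[, , f]
    ang <- vapply(seq_len(nrow(specs)), function(s)
      dihedralAngle(xyz[idx[s, 1], ], xyz[idx[s, 2], ],
                    xyz[idx[s, 3], ], xyz[idx[s, 4], ]), numeric(1))
    out[[f]] <- data.frame(frame = f, time = times[f],
                           torsion = specs$torsion, residue = specs$residue,
                           angle = ang, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Wide phi/psi table of a trajectory
#'
#' Convenience reshaping of [torsionSeries()] for the helicity analysis.
#' Residues missing phi or psi (chain termini) carry `NA` there.
#'
#' @param traj a [Trajectory-class].
#' @return data.frame with columns `frame`, `residue`, `phi`, `psi`.
#' @export
phiPsiTable <- function(traj) {
  ts <- torsionSeries(traj, backboneTorsionSpecs(traj, c("phi", "psi")))
  res <- sort(unique(atomData(traj)$resno))
  grid <- expand.grid(frame = unique(ts$frame), residue = res)
  for (tor in c("phi", "psi")) {
    sub <- ts[ts$torsion == tor, ]
    grid[[tor]] <- sub$angle[match(paste(grid$frame, grid$residue),
                                   paste(sub$frame, sub$residue))]
  }
  grid[order(grid$frame, grid$residue), ]
}

#' Radius of gyration of one frame
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with `rbar` the (weighted)
#' centroid.  Mass weighting uses standard atomic masses looked up from the
#' element; the unweighted variant sets all weights to 1.
#'
#' @param frame n x 3 coordinate matrix, or a [Trajectory-class] (first
#'   frame used).
#' @param selection selection preset applied when `frame` is a Trajectory.
#' @param massWeighted logical.
#' @param elements optional element vector for a bare coordinate matrix.
#' @return radius of gyration in A.
#' @export
radiusOfGyration <- function(frame, selection = "all", massWeighted = TRUE,
                             elements = NULL) {
  if (is(frame, "Trajectory")) {
    idx <- selectAtoms(frame, selection)
    elements <- atomData(frame)$element[idx]
    frame <- frameCoords(frame, 1)[idx, , drop = FALSE]
  }
  if (!nrow(frame)) stopUsage("empty selection for radius of gyration")
  w <- if (massWeighted) {
    if (is.null(elements)) rep(1, nrow(frame)) else elementMass(elements)
  } else rep(1, nrow(frame))
  ctr <- colSums(frame * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(frame, 2, ctr)^2)) / sum(w))
}

#' Ratio of total-energy to kinetic-energy RMS fluctuations
#'
#' A quality measure of integration accuracy: the root-mean-square
#' fluctuation of total energy about its mean divided by the same quantity
#' for kinetic energy.  Lower is better.
#'
#' @param E,KE numeric series of equal length >= 2.
#' @return list with `ratio` and `nSamples`.
#' @export
energyFluctuationRatio <- function(E, KE) {
  if (length(E) != length(KE) || length(E) < 2)
    stopUsage("E and KE must have equal length >= 2")
  rmsf <- function(x) sqrt(mean((x - mean(x))^2))
  den <- rmsf(KE)
  if (den == 0) stopUsage("kinetic energy series is constant; ratio undefined")
  list(ratio = rmsf(E) / den, nSamples = length(E))
}
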