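# NMR/crystallographic observables back-calculated from trajectories:
# Karplus-equation J-couplings with chi-square comparison to experiment,
# iRED Lipari-Szabo order parameters, and two-step B-factors.

#' Define a Karplus parameter set
#'
#' The generic trigonometric form
#' `J(theta) = c2 cos^2(theta + delta) + c1 cos(theta + delta) + c0 +
#'  s1 sin(theta + delta)` covers the standard three-coefficient Karplus
#' relations and their sine-augmented variants.  `delta` encodes the fixed
#' offset between the backbone/side-chain torsion and the coupling's own
#' dihedral (for example theta = phi - 60 for 3J(HN,Ha)).
#'
#' @param couplingId identifier such as `"3JHNHA"`.
#' @param c0,c1,c2 polynomial coefficients, Hz.
#' @param s1 optional sine coefficient, Hz.
#' @param delta phase offset, degrees.
#' @param source label of the coefficient lineage (e.g. `"Original"`).
#' @return list of class `karplusSet`.
#' @export
karplusSet <- function(couplingId, c0 = 0, c1 = 0, c2 = 0, s1 = 0, delta = 0,
                       source = "custom") {
  if (all(c(c0, c1, c2, s1) == 0))
    stopUsage("at least one coefficient must be nonzero")
  structure(list(couplingId = couplingId, c0 = c0, c1 = c1, c2 = c2,
                 s1 = s1, delta = delta, source = source),
            class = "karplusSet")
}

#' Load Karplus parameter sets from a JSON config
#'
#' The package ships a starter config with the standard literature
#' coefficients for the backbone 3J(HN,Ha) coupling
#' (`system.file("extdata", "karplus_sets.json", package = "ffmc")`).
#' Coupling identifiers absent from the config fail loudly rather than
#' falling back to a default.
#'
#' @param file path to a JSON file: an array of objects with fields
#'   `couplingId`, `c0`, `c1`, `c2`, optional `s1`, `delta`, `source`.
#' @return named list of `karplusSet` objects keyed by
#'   `couplingId:source`.
#' @export
loadKarplusSets <- function(file = system.file("extdata", "karplus_sets.json",
                                               package = "ffmc")) {
  raw <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  sets <- lapply(raw, function(x)
    karplusSet(x$couplingId, c0 = x$c0 %||% 0, c1 = x$c1 %||% 0,
               c2 = x$c2 %||% 0, s1 = x$s1 %||% 0, delta = x$delta %||% 0,
               source = x$source %||% "unknown"))
  names(sets) <- vapply(sets, function(s)
    paste(s$couplingId, s$source, sep = ":"), character(1))
  sets
}

#' Find a Karplus set by coupling id
#'
#' @param sets named list from [loadKarplusSets()].
#' @param couplingId coupling identifier.
#' @param source optional coefficient-set label.
#' @return a `karplusSet`; an error when the id is not configured.
#' @export
getKarplusSet <- function(sets, couplingId, source = NULL) {
  hit <- Filter(function(s) s$couplingId == couplingId &&
                  (is.null(source) || s$source == source), sets)
  if (!length(hit))
    stopUsage("no Karplus coefficients configured for coupling '", couplingId,
              "'", if (!is.null(source)) paste0(" (", source, ")"),
              "; unsourced couplings are refused")
  hit[[1]]
}

#' Evaluate a Karplus relation
#'
#' @param theta torsion angle(s), degrees.
#' @param params a `karplusSet`.
#' @return coupling constant(s), Hz.
#' @export
karplusJ <- function(theta, params) {
  a <- (theta + params$delta) * pi / 180
  params$c2 * cos(a)^2 + params$c1 * cos(a) + params$c0 + params$s1 * sin(a)
}

#' Mean coupling over a torsion series
#'
#' Arithmetic mean over frames of the instantaneous couplings (the average
#' of J, not J of the average angle).
#'
#' @param theta numeric vector of torsion angles over frames, degrees.
#' @param params a `karplusSet`.
#' @return mean coupling, Hz.
#' @export
meanCoupling <- function(theta, params) {
  if (!length(theta)) stopUsage("empty torsion series")
  mean(karplusJ(theta, params))
}

#' Chi-square and RMSD between calculated and experimental couplings
#'
#' `chi2 = mean(((Jcalc - Jexp)/sigma)^2)` and
#' `rmsd = sqrt(mean((Jcalc - Jexp)^2))` over the matched
#' (residue, coupling) pairs.  Unmatched calculated values are skipped with
#' a warning; no match at all is an error.
#'
#' @param calc data.frame with columns `residue`, `couplingId`, `J` (Hz).
#' @param observations data.frame with columns `residue`, `couplingId`,
#'   `J` (experimental, Hz), `sigma` (Hz, > 0).
#' @return list with `chi2`, `rmsd`, `n` and `pairs` (the matched table).
#' @export
chiSquareCouplings <- function(calc, observations) {
  if (any(observations$sigma <= 0)) stopUsage("sigma values must be positive")
  key <- function(d) paste(d$residue, d$couplingId)
  m <- match(key(calc), key(observations))
  if (all(is.na(m))) stopUsage("no calculated coupling matches an observation")
  if (anyNA(m))
    warning(sum(is.na(m)), " calculated coupling(s) without a matching ",
            "observation were skipped", call. = FALSE)
  keep <- !is.na(m)
  pairs <- data.frame(residue = calc$residue[keep],
                      couplingId = calc$couplingId[keep],
                      Jcalc = calc$J[keep],
                      Jexp = observations$J[m[keep]],
                      sigma = observations$sigma[m[keep]])
  d <- pairs$Jcalc - pairs$Jexp
  list(chi2 = mean((d / pairs$sigma)^2), rmsd = sqrt(mean(d^2)),
       n = nrow(pairs), pairs = pairs)
}

#' Equal-weight combination of chi-square values
#'
#' Mean of independent chi-square (or RMSD) values with the standard
#' error-propagation rule for a mean of independent quantities:
#' `se = sqrt(sum(se_i^2)) / m`.
#'
#' @param values numeric vector of per-set values.
#' @param ses their standard errors.
#' @return list with `mean` and `se`.
#' @export
combineChiSquare <- function(values, ses) {
  if (length(values) != length(ses)) stopUsage("length mismatch")
  list(mean = mean(values), se = sqrt(sum(ses^2)) / length(ses))
}

#' Align every frame onto the first frame
#'
#' First step of the order-parameter and B-factor procedures: each saved
#' conformation is rigidly fitted onto the first one using the backbone
#' CA, C, N, O atoms (unweighted).
#'
#' @param traj a [Trajectory-class].
#' @param selection fit selection preset, default `"backbone"`.
#' @return the aligned [Trajectory-class].
#' @export
twoStepAlignment <- function(traj, selection = "backbone") {
  idx <- selectAtoms(traj, selection)
  ref <- traj@coords[idx, , 1]
  out <- traj@coords
  for (f in seq_len(nFrames(traj))) {
    fit <- kabschSuperpose(traj@coords[idx, , f], ref)
    ctr <- colMeans(traj@coords[idx, , f])
    moved <- sweep(traj@coords[, , f], 2, ctr) %*% fit$rotation
    out[, , f] <- sweep(moved, 2, colMeans(ref), "+")
  }
  traj@coords <- out
  traj
}

#' iRED Lipari-Szabo order parameters
#'
#' Isotropic reorientational eigenmode dynamics: build the M x M matrix
#' `C_ij = <P2(u_i . u_j)>` over frames (`P2(x) = (3x^2 - 1)/2`),
#' eigendecompose it, and attribute the `excludedModes` largest eigenmodes
#' to overall reorientation.  The order parameter of residue i is
#' `S2_i = 1 - sum_internal lambda_m * e_mi^2` over the remaining modes.
#' Values are clamped to \[0, 1\] (clamping is recorded in the result).
#'
#' @param vectors numeric array `c(M, 3, nFrames)` of bond unit vectors
#'   (renormalised with a warning when any norm deviates from 1 by more
#'   than 1e-6).
#' @param excludedModes number of largest eigenmodes excluded as global,
#'   default 5.
#' @return list with `s2` (length-M vector), `eigenvalues`, `clamped`
#'   (indices) and `excludedModes`.
#' @export
iredS2 <- function(vectors, excludedModes = 5) {
  d <- dim(vectors)
  if (length(d) != 3 || d[2] != 3)
    stopUsage("vectors must be an M x 3 x nFrames array")
  M <- d[1]; Tn <- d[3]
  if (M <= excludedModes)
    stopUsage("need more vectors (", M, ") than excluded modes (",
              excludedModes, ")")
  if (Tn < 1) stopUsage("need at least one frame")
  nrm <- sqrt(vectors[, 1, , drop = FALSE]^2 + vectors[, 2, , drop = FALSE]^2 +
                vectors[, 3, , drop = FALSE]^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("renormalising bond vectors with |1 - norm| > 1e-6", call. = FALSE)
  }
  vx <- vectors[, 1, ] / nrm[, 1, ]; vy <- vectors[, 2, ] / nrm[, 1, ]
  vz <- vectors[, 3, ] / nrm[, 1, ]
  if (Tn == 1) { vx <- cbind(vx); vy <- cbind(vy); vz <- cbind(vz) }
  # <(u_i.u_j)^2> accumulated from the six symmetric component products
  G <- matrix(0, M, M)
  comp <- list(list(vx, vx, 1), list(vy, vy, 1), list(vz, vz, 1),
               list(vx, vy, 2), list(vx, vz, 2), list(vy, vz, 2))
  for (cc in comp) {
    P <- cc[[1]] * cc[[2]]
    G <- G + cc[[3]] * tcrossprod(P) / Tn
  }
  C <- 1.5 * G - 0.5
  eig <- eigen(C, symmetric = TRUE)   # eigenvalues descending
  keep <- seq.int(excludedModes + 1L, M)
  s2 <- 1 - colSums(eig$values[keep] * t(eig$vectors[, keep, drop = FALSE]^2))
  clamped <- which(s2 < -1e-9 | s2 > 1 + 1e-9)
  s2 <- pmin(pmax(s2, 0), 1)
  list(s2 = s2, eigenvalues = eig$values, clamped = clamped,
       excludedModes = excludedModes)
}

#' N-H bond vectors of a trajectory
#'
#' Extracts unit vectors from backbone amide N to its hydrogen (atom `H`)
#' for every residue possessing both atoms.
#'
#' @param traj a [Trajectory-class].
#' @return list with `vectors` (array `M x 3 x nFrames`) and `residues`.
#' @export
nhBondVectors <- function(traj) {
  at <- atomData(traj)
  res <- sort(unique(at$resno))
  iN <- match(paste(res, "N"), paste(at$resno, at$name))
  iH <- match(paste(res, "H"), paste(at$resno, at$name))
  ok <- !is.na(iN) & !is.na(iH)
  res <- res[ok]; iN <- iN[ok]; iH <- iH[ok]
  if (!length(res)) stopUsage("no residues with both N and H atoms")
  v <- traj@coords[iH, , , drop = FALSE] - traj@coords[iN, , , drop = FALSE]
  nrm <- sqrt(v[, 1, , drop = FALSE]^2 + v[, 2, , drop = FALSE]^2 +
                v[, 3, , drop = FALSE]^2)
  for (k in 1:3) v[, k, ] <- v[, k, ] / nrm[, 1, ]
  list(vectors = v, residues = res)
}

#' Two-step crystallographic B-factors
#'
#' First pass: align all frames onto the first on the selection and take
#' the mean coordinates of the selected atoms.  Second pass: re-fit every
#' frame onto those mean coordinates and compute
#' `B_i = (8 pi^2 / 3) <|r_i - <r_i>|^2>` about the post-fit mean.
#'
#' @param traj a [Trajectory-class] with >= 2 frames.
#' @param selection `"CA"` for alpha-carbon B-factors or `"CG"` for gamma
#'   carbons (atom names CG and CG2).
#' @return list with `B` (A^2, one per selected atom), `atoms` (their
#'   rows of the atom table) and `selection`.
#' @export
bFactors <- function(traj, selection = c("CA", "CG")) {
  selection <- match.arg(selection)
  if (nFrames(traj) < 2) stopUsage("need at least two frames")
  idx <- if (selection == "CA") selectAtoms(traj, "CA")
         else selectAtoms(traj, c("CG", "CG2"))
  nf <- nFrames(traj)
  ref <- traj@coords[idx, , 1]
  aligned <- array(NA_real_, c(length(idx), 3, nf))
  for (f in seq_len(nf))
    aligned[, , f] <- kabschSuperpose(traj@coords[idx, , f], ref)$fitted
  avg <- apply(aligned, c(1, 2), mean)
  refit <- array(NA_real_, c(length(idx), 3, nf))
  for (f in seq_len(nf))
    refit[, , f] <- kabschSuperpose(traj@coords[idx, , f], avg)$fitted
  ctr <- apply(refit, c(1, 2), mean)
  msd <- rowMeans(apply(refit, 3, function(x) rowSums((x - ctr)^2)))
  list(B = (8 * pi^2 / 3) * msd, atoms = atomData(traj)[idx, ],
       selection = selection)
}

#' RMSD between calculated and experimental observable vectors
#'
#' @param calc,exp numeric vectors of equal length.
#' @return `sqrt(mean((calc - exp)^2))`, same units as the inputs.
#' @export
observableRmsd <- function(calc, exp) {
  if (length(calc) != length(exp))
    stopUsage("vectors differ in length: ", length(calc), " vs ", length(exp))
  sqrt(mean((calc - exp)^2))
}
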