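# Seeded synthetic-fixture generators.
#
# Every generator draws from its own seeded stream and returns, alongside
# the data, a manifest recording the seed, the parameters and the ground
# truth the construction guarantees, so analysis modules can be validated
# against known answers without any molecular dynamics input.  The
# fixtures are statistical stand-ins, not physical simulations.

#' Alpha/beta-carbon helix scaffold
#'
#' Idealised helical CA trace (2.3 A radius, 1.5 A rise, 100 degrees per
#' residue) with radially displaced CB atoms: a rigid synthetic peptide
#' scaffold used by the coordinate-jitter generators.
#'
#' @param nRes number of residues.
#' @param withCB include beta carbons.
#' @return list with `coords` (matrix) and `atoms` (data.frame).
#' @export
helixScaffold <- function(nRes = 15, withCB = TRUE) {
  ang <- (seq_len(nRes) - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (seq_len(nRes) - 1))
  atoms <- data.frame(name = rep("CA", nRes), resno = seq_len(nRes),
                      resname = "ALA", chain = "A", element = "C",
                      stringsAsFactors = FALSE)
  coords <- ca
  if (withCB) {
    cb <- cbind(3.8 * cos(ang), 3.8 * sin(ang), 1.5 * (seq_len(nRes) - 1) + 0.5)
    coords <- rbind(ca, cb)
    atoms <- rbind(atoms, data.frame(name = "CB", resno = seq_len(nRes),
                                     resname = "ALA", chain = "A",
                                     element = "C", stringsAsFactors = FALSE))
    ord <- order(atoms$resno, atoms$name)
    coords <- coords[ord, ]; atoms <- atoms[ord, ]
  }
  rownames(atoms) <- NULL
  list(coords = coords, atoms = atoms)
}

randomRotation <- function() {
  # uniform random rotation from QR of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Two-state folding RMSD series
#'
#' Each simulated series starts in the nonnative state (values fluctuating
#' around `nonnativeLevel`, always above the cutoff), crosses below the
#' cutoff at a first-passage time drawn from an exponential distribution
#' with the given rate, and then fluctuates around `nativeLevel` with
#' occasional unfolding excursions back above the cutoff.  The manifest
#' records the continuous draw and the discretised (first saved time at or
#' after the draw) folding time of every simulation; series longer than
#' `simLength` are censored.
#'
#' @param rate folding rate, 1/ns.
#' @param nSims number of independent series.
#' @param simLength simulated time per series, ns.
#' @param saveInterval ns between saved values.
#' @param nativeLevel,nonnativeLevel mean RMSD of the two states, A.
#' @param cutoff native-state cutoff the construction respects, A.
#' @param excursionProb per-sample probability of a post-folding unfolding
#'   excursion.
#' @param seed integer seed.
#' @return list with `series` (list of data.frames `time`, `rmsd`),
#'   and `manifest` (parameters plus `trueTimes`, `savedTimes`, `event`).
#' @export
synthTwoStateRmsd <- function(rate, nSims = 20, simLength = 1000,
                              saveInterval = 1, nativeLevel = 1.0,
                              nonnativeLevel = 5.0, cutoff = 1.96,
                              excursionProb = 0.05, seed = 1) {
  set.seed(seed)
  times <- seq(saveInterval, simLength, by = saveInterval)
  draw <- stats::rexp(nSims, rate)
  series <- vector("list", nSims)
  savedTimes <- numeric(nSims); event <- logical(nSims)
  for (i in seq_len(nSims)) {
    n <- length(times)
    folded <- times >= draw[i]
    v <- numeric(n)
    pre <- !folded
    v[pre] <- pmax(nonnativeLevel + stats::rnorm(sum(pre), 0, 0.5),
                   cutoff + 0.2)
    if (any(folded)) {
      post <- which(folded)
      v[post] <- pmin(nativeLevel + stats::rnorm(length(post), 0, 0.3),
                      cutoff - 0.05)
      exc <- post[stats::runif(length(post)) < excursionProb]
      exc <- setdiff(exc, post[1])  # never at the first-passage sample
      v[exc] <- nonnativeLevel + stats::rnorm(length(exc), 0, 0.5)
      savedTimes[i] <- times[post[1]]; event[i] <- TRUE
    } else {
      savedTimes[i] <- times[n]; event[i] <- FALSE
    }
    series[[i]] <- data.frame(time = times, rmsd = v)
  }
  list(series = series,
       manifest = list(generator = "two_state_rmsd", seed = seed, rate = rate,
                       nSims = nSims, simLength = simLength,
                       saveInterval = saveInterval, cutoff = cutoff,
                       trueTimes = draw, savedTimes = savedTimes,
                       event = event))
}

#' Helix-coil torsion table with matching coordinate trajectory
#'
#' Frames are helical with probability `pHelix` (all scored residues at
#' the canonical helix torsions plus small wrapped noise) and extended
#' otherwise.  With `frayEnds`, the two terminal residues at each end are
#' always placed outside the torsion window and their scaffold atoms are
#' displaced, so helical frames still fail a global RMSD test against the
#' intact full-helix reference while interior residues remain torsion-
#' helical - the construction behind the expected ordering of the torsion
#' route above the RMSD route.
#'
#' @param nRes residues (scored set is `1:nRes`).
#' @param pHelix per-frame helix probability.
#' @param frayEnds logical.
#' @param nFrames number of frames.
#' @param noiseSd torsion noise SD, degrees.
#' @param seed integer seed.
#' @return list with `torsions` (frame/residue/phi/psi), `traj`
#'   (CA+CB [Trajectory-class]), `reference` (full-helix frame) and
#'   `manifest` (including `helixFrames` and the expected helicity).
#' @export
synthHelixCoil <- function(nRes = 15, pHelix = 0.5, frayEnds = FALSE,
                           nFrames = 200, noiseSd = 5, seed = 1) {
  set.seed(seed)
  scaf <- helixScaffold(nRes)
  frayed <- if (frayEnds) c(1, 2, nRes - 1, nRes) else integer()
  interior <- setdiff(seq_len(nRes), frayed)
  helixFrame <- stats::runif(nFrames) < pHelix
  tor <- expand.grid(residue = seq_len(nRes), frame = seq_len(nFrames))
  tor <- tor[c("frame", "residue")]
  tor$phi <- NA_real_; tor$psi <- NA_real_
  coords <- array(NA_real_, c(nrow(scaf$coords), 3, nFrames))
  frayIdx <- which(scaf$atoms$resno %in% frayed)
  for (f in seq_len(nFrames)) {
    rows <- which(tor$frame == f)
    if (helixFrame[f]) {
      tor$phi[rows] <- -57 + stats::rnorm(nRes, 0, noiseSd)
      tor$psi[rows] <- -47 + stats::rnorm(nRes, 0, noiseSd)
      if (length(frayed)) {
        fr <- rows[tor$residue[rows] %in% frayed]
        tor$phi[fr] <- -139 + stats::rnorm(length(fr), 0, noiseSd)
        tor$psi[fr] <- 135 + stats::rnorm(length(fr), 0, noiseSd)
      }
      xyz <- scaf$coords + matrix(stats::rnorm(length(scaf$coords), 0, 0.1), ncol = 3)
      if (length(frayIdx))
        xyz[frayIdx, ] <- xyz[frayIdx, ] +
          matrix(stats::rnorm(3 * length(frayIdx), 0, 3), ncol = 3)
    } else {
      tor$phi[rows] <- -139 + stats::rnorm(nRes, 0, noiseSd)
      tor$psi[rows] <- 135 + stats::rnorm(nRes, 0, noiseSd)
      xyz <- scaf$coords +
        matrix(stats::rnorm(length(scaf$coords), 0, 4), ncol = 3)
    }
    coords[, , f] <- xyz
  }
  expected <- if (frayEnds) mean(helixFrame) * length(interior) / nRes
              else mean(helixFrame)
  list(torsions = tor,
       traj = Trajectory(coords, scaf$atoms, saveInterval = 1),
       reference = Trajectory(scaf$coords, scaf$atoms, saveInterval = 1),
       manifest = list(generator = "helix_coil", seed = seed, nRes = nRes,
                       pHelix = pHelix, frayEnds = frayEnds,
                       nFrames = nFrames, helixFrames = which(helixFrame),
                       expectedHelicity = expected))
}

#' Cone-wobble bond-vector trajectories with closed-form order parameters
#'
#' Unit vectors uniformly distributed inside a cone about a fixed
#' per-residue axis: the polar cosine is drawn uniformly on
#' `[cos(theta0), 1]` (inverse-CDF sampling, so the diffusion-in-a-cone
#' closed form applies) and the azimuth uniformly on `[0, 2 pi)`.  The
#' manifest carries the analytic order parameter
#' `S2 = ((cos(theta0) (1 + cos(theta0))) / 2)^2` per residue.
#'
#' @param M number of bond vectors.
#' @param coneSemiangle semiangle(s) in degrees, recycled to length `M`.
#' @param nFrames frames.
#' @param seed integer seed.
#' @return list with `vectors` (array `M x 3 x nFrames`) and `manifest`
#'   (including `s2`).
#' @export
synthConeWobble <- function(M = 50, coneSemiangle = 20, nFrames = 1e4,
                            seed = 1) {
  set.seed(seed)
  theta0 <- rep(coneSemiangle, length.out = M) * pi / 180
  axes <- matrix(stats::rnorm(3 * M), M)
  axes <- axes / sqrt(rowSums(axes^2))
  vec <- array(NA_real_, c(M, 3, nFrames))
  for (i in seq_len(M)) {
    ct <- stats::runif(nFrames, cos(theta0[i]), 1)
    st <- sqrt(pmax(0, 1 - ct^2))
    az <- stats::runif(nFrames, 0, 2 * pi)
    local <- rbind(st * cos(az), st * sin(az), ct)
    # orthonormal frame with the axis as z
    z <- axes[i, ]
    ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    x <- ref - sum(ref * z) * z; x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    vec[i, , ] <- cbind(x, y, z) %*% local
  }
  ct0 <- cos(theta0)
  list(vectors = vec,
       manifest = list(generator = "cone_wobble", seed = seed,
                       coneSemiangle = theta0 * 180 / pi, nFrames = nFrames,
                       s2 = ((ct0 * (1 + ct0)) / 2)^2))
}

#' Gaussian coordinate-jitter trajectory
#'
#' Independent isotropic Gaussian displacement of every atom of a rigid
#' scaffold in every frame, optionally wrapped in a random global rigid
#' motion per frame.  The analytic expectation for the two-step B-factor
#' procedure is `B = 8 pi^2 sigma^2`; the rigid-body fit absorbs about
#' `6/(3N)` of the jitter variance, so the default scaffold is large
#' enough (N = 100 atoms) to keep that bias near 2 percent.
#'
#' @param scaffold list with `coords`/`atoms` (default: 100-residue helix
#'   CA trace).
#' @param sigma per-axis jitter SD, A.
#' @param nFrames frames.
#' @param globalRigidMotion apply a random rotation + translation per
#'   frame.
#' @param seed integer seed.
#' @return list with `traj` ([Trajectory-class]) and `manifest`
#'   (including `expectedB`).
#' @export
synthJitterTrajectory <- function(scaffold = helixScaffold(100, withCB = FALSE),
                                  sigma = 0.1, nFrames = 200,
                                  globalRigidMotion = FALSE, seed = 1) {
  set.seed(seed)
  n <- nrow(scaffold$coords)
  coords <- array(NA_real_, c(n, 3, nFrames))
  for (f in seq_len(nFrames)) {
    xyz <- scaffold$coords + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
    if (globalRigidMotion)
      xyz <- sweep(xyz %*% randomRotation(), 2, stats::rnorm(3, 0, 5), "+")
    coords[, , f] <- xyz
  }
  list(traj = Trajectory(coords, scaffold$atoms, saveInterval = 1),
       manifest = list(generator = "jitter", seed = seed, sigma = sigma,
                       nFrames = nFrames, globalRigidMotion = globalRigidMotion,
                       expectedB = 8 * pi^2 * sigma^2))
}

#' Multi-well trajectory for clustering validation
#'
#' Well centres are the scaffold plus a well-specific random displacement
#' field scaled so that post-fit inter-well RMSDs are close to
#' `separation`; frames scatter about their well centre with isotropic SD
#' `intraSigma`.  Frames are emitted in shuffled order.  The manifest
#' records the true well of every frame and the realised inter-well
#' RMSDs.
#'
#' @param nWells number of wells.
#' @param separation target inter-well RMSD, A.
#' @param intraSigma per-axis within-well SD, A.
#' @param counts frames per well (recycled to `nWells`).
#' @param scaffold base geometry (default 15-residue CA+CB helix).
#' @param seed integer seed.
#' @return list with `traj` and `manifest` (including `wells`, the true
#'   assignment, and `interWellRmsd`).
#' @export
synthMultiwellTrajectory <- function(nWells = 3, separation = 4,
                                     intraSigma = 0.3, counts = 20,
                                     scaffold = helixScaffold(15), seed = 1) {
  set.seed(seed)
  counts <- rep(counts, length.out = nWells)
  n <- nrow(scaffold$coords)
  centers <- vector("list", nWells)
  for (w in seq_len(nWells)) {
    disp <- matrix(stats::rnorm(3 * n), ncol = 3)
    disp <- sweep(disp, 2, colMeans(disp))             # no net translation
    disp <- disp * separation / sqrt(mean(rowSums(disp^2)))
    centers[[w]] <- scaffold$coords + if (w == 1) 0 else disp
  }
  wells <- rep(seq_len(nWells), counts)
  ord <- sample(length(wells))
  wells <- wells[ord]
  coords <- array(NA_real_, c(n, 3, length(wells)))
  for (f in seq_along(wells))
    coords[, , f] <- centers[[wells[f]]] +
      matrix(stats::rnorm(3 * n, 0, intraSigma), ncol = 3)
  inter <- matrix(0, nWells, nWells)
  for (a in seq_len(nWells - 1)) for (b in seq.int(a + 1, nWells))
    inter[a, b] <- inter[b, a] <-
      kabschSuperpose(centers[[a]], centers[[b]])$rmsd
  list(traj = Trajectory(coords, scaffold$atoms, saveInterval = 1),
       manifest = list(generator = "multiwell", seed = seed, nWells = nWells,
                       separation = separation, intraSigma = intraSigma,
                       counts = counts, wells = wells, interWellRmsd = inter))
}

#' Miniature FF99-like frcmod fixture
#'
#' A self-contained parameter file exercising every transformation rule:
#' an aliphatic C-H bond (CT-HC, 1.090 A), an aromatic C-H bond (CA-HA,
#' 1.080 A), untouched C-O and C-N bonds, sp3-central torsions
#' (X-CT-CT-X and the disulfide CT-S-S-CT), an sp2-central amide torsion
#' (X-C-N-X), phi (C-N-CT-C, two Fourier terms) and psi (N-CT-C-N)
#' quartets at FF99 scaling, and a chi1-like torsion left unscaled.  The
#' manifest records the record counts and the values the transformation
#' must produce.
#'
#' @return list with `text` (frcmod lines) and `manifest`.
#' @export
synthFrcmod <- function() {
  text <- c(
    "synthetic FF99-style fragment for transformation tests",
    "MASS",
    "H       1.0080",
    "HC      1.0080",
    "HA      1.0080",
    "CT     12.0100",
    "CA     12.0100",
    "C      12.0100",
    "N      14.0100",
    "O      16.0000",
    "S      32.0600",
    "",
    "BOND",
    "CT-HC    340.00    1.0900",
    "CA-HA    367.00    1.0800",
    "C -O     570.00    1.2290",
    "C -N     490.00    1.3350",
    "CT-CT    310.00    1.5260",
    "CT-S     227.00    1.8100",
    "S -S     166.00    2.0380",
    "",
    "ANGLE",
    "CT-CT-HC    50.00     109.50",
    "CA-CA-HA    50.00     120.00",
    "N -CT-C     63.00     110.10",
    "",
    "DIHE",
    "X -CT-CT-X    9     1.40000       0.0   3.0    SCEE=1.20 SCNB=2.00",
    "X -C -N -X    4    10.00000     180.0   2.0    SCEE=1.20 SCNB=2.00",
    "C -N -CT-C    1     0.85000       0.0  -2.0    SCEE=1.20 SCNB=2.00",
    "C -N -CT-C    1     0.80000       0.0   1.0    SCEE=1.20 SCNB=2.00",
    "N -CT-C -N    1     1.45000     180.0  -1.0    SCEE=1.20 SCNB=2.00",
    "N -CT-C -N    1     1.58000     180.0   2.0    SCEE=1.20 SCNB=2.00",
    "CT-S -S -CT   1     3.50000       0.0  -2.0    SCEE=1.20 SCNB=2.00",
    "CT-S -S -CT   1     0.60000       0.0   3.0    SCEE=1.20 SCNB=2.00",
    "N -CT-CT-CT   1     1.40000       0.0   3.0    SCEE=1.20 SCNB=2.00",
    "",
    "IMPROPER",
    "X -X -C -O      10.50000     180.0   2.0",
    "",
    "NONBON",
    "  H       0.6000     0.0157",
    "  HC      1.4870     0.0157",
    "  HA      1.4590     0.0150",
    "  CT      1.9080     0.1094",
    "  CA      1.9080     0.0860",
    "  C       1.9080     0.0860",
    "  N       1.8240     0.1700",
    "  O       1.6612     0.2100",
    "  S       2.0000     0.2500",
    "")
  manifest <- list(
    generator = "fixture_frcmod",
    counts = list(atomTypes = 9L, bonds = 7L, angles = 3L, torsions = 9L,
                  impropers = 1L, lj = 9L),
    aliphaticBond = c("CT", "HC"), aromaticBond = c("CA", "HA"),
    expected = list(aliphaticB0 = 0.98, aromaticB0 = 0.93,
                    phiPsiScnb = 1.00, phiPsiScee = 1.18,
                    hydrogenLowMass = 0.1008),
    sp3CentralQuartets = c("X-CT-CT-X", "C-N-CT-C", "N-CT-C-N",
                           "CT-S-S-CT", "N-CT-CT-CT"))
  list(text = text, manifest = manifest)
}

#' Quality-score table of the three-model refinement study
#'
#' The printed model x method x score grid used by the Z-score worked
#' example: three comparative models (TMR01, TMR04, TMR07), the unrefined
#' reference row, two literature refinement protocols reporting only a
#' subset of scores, and three forcefield refinements with all nine
#' scores.  RMSD-type scores are lower-better; all others higher-better.
#'
#' @return a [QualityScoreTable-class].
#' @export
synthQualityScores <- function() {
  scores <- c("sseRMSD", "CaRMSD", "GDT-TS", "GDT-HA", "GDC-all",
              "RPF9", "LDDT15", "SG2n6", "CAD")
  rows <- list(
    list("TMR01", "None",      c(1.3, 6.1, 0.772, 0.593, 0.491, 0.690, 0.631, 0.495, 0.609)),
    list("TMR01", "RAPDF/HB_EM", c(0.9, NA, NA, NA, NA, NA, NA, NA, NA)),
    list("TMR01", "GBSW",      c(NA, 3.9, 0.835, NA, NA, NA, NA, NA, NA)),
    list("TMR01", "FF12MC",    c(0.7, 1.4, 0.920, 0.797, 0.820, 0.851, 0.791, 0.766, 0.693)),
    list("TMR01", "FF14SBlm",  c(1.1, 3.0, 0.849, 0.717, 0.689, 0.805, 0.750, 0.663, 0.656)),
    list("TMR01", "FF96lm",    c(1.4, 3.9, 0.854, 0.712, 0.653, 0.776, 0.723, 0.629, 0.642)),
    list("TMR04", "None",      c(1.8, 2.2, 0.743, 0.543, 0.637, 0.667, 0.603, 0.300, 0.626)),
    list("TMR04", "RAPDF/HB_EM", c(0.8, NA, NA, NA, NA, NA, NA, NA, NA)),
    list("TMR04", "GBSW",      c(NA, 1.6, 0.900, NA, NA, NA, NA, NA, NA)),
    list("TMR04", "FF12MC",    c(0.6, 1.5, 0.932, 0.811, 0.793, 0.800, 0.762, 0.831, 0.687)),
    list("TMR04", "FF14SBlm",  c(0.8, 1.1, 0.939, 0.818, 0.838, 0.805, 0.776, 0.802, 0.683)),
    list("TMR04", "FF96lm",    c(0.7, 1.6, 0.921, 0.771, 0.776, 0.777, 0.744, 0.790, 0.664)),
    list("TMR07", "None",      c(1.9, 2.2, 0.766, 0.556, 0.668, 0.686, 0.618, 0.383, 0.590)),
    list("TMR07", "RAPDF/HB_EM", c(2.1, NA, NA, NA, NA, NA, NA, NA, NA)),
    list("TMR07", "GBSW",      c(NA, 2.7, 0.810, NA, NA, NA, NA, NA, NA)),
    list("TMR07", "FF12MC",    c(1.5, 2.4, 0.846, 0.680, 0.732, 0.815, 0.762, 0.777, 0.694)),
    list("TMR07", "FF14SBlm",  c(1.2, 1.8, 0.832, 0.654, 0.753, 0.762, 0.713, 0.620, 0.689)),
    list("TMR07", "FF96lm",    c(1.6, 2.7, 0.872, 0.710, 0.719, 0.793, 0.765, 0.724, 0.711)))
  long <- do.call(rbind, lapply(rows, function(r)
    data.frame(model = r[[1]], method = r[[2]], score = scores,
               value = r[[3]], stringsAsFactors = FALSE)))
  orient <- stats::setNames(
    ifelse(scores %in% c("sseRMSD", "CaRMSD"), "lower_better", "higher_better"),
    scores)
  qualityScoreTable(long, orientation = orient, referenceMethod = "None")
}

#' Gaussian energy series with a known fluctuation ratio
#'
#' @param sigmaE,sigmaKE SDs of the total and kinetic energy series.
#' @param n samples.
#' @param seed integer seed.
#' @return list with `E`, `KE` and `manifest` (expected ratio
#'   `sigmaE/sigmaKE`).
#' @export
synthEnergySeries <- function(sigmaE = 1, sigmaKE = 2, n = 1e4, seed = 1) {
  set.seed(seed)
  list(E = stats::rnorm(n, -1e4, sigmaE), KE = stats::rnorm(n, 5e3, sigmaKE),
       manifest = list(generator = "energy_series", seed = seed,
                       expectedRatio = sigmaE / sigmaKE, n = n))
}
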