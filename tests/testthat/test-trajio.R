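# Trajectory I/O and geometric primitives.

test_that("multi-model PDB round-trips and rejects inconsistent models", {
  jt <- synthJitterTrajectory(helixScaffold(8), sigma = 0.2, nFrames = 5, seed = 7)
  txt <- writeMultiModelPDB(jt$traj)
  back <- readMultiModelPDB(txt)
  expect_equal(nFrames(back), 5)
  expect_equal(nAtoms(back), nAtoms(jt$traj))
  expect_equal(back@coords, round(jt$traj@coords, 3), tolerance = 1e-9)
  expect_equal(atomData(back)$name, atomData(jt$traj)$name)
  expect_equal(atomData(back)$resno, atomData(jt$traj)$resno)
  # single model -> one frame
  one <- readMultiModelPDB(writeMultiModelPDB(
    Trajectory(helixScaffold(4)$coords, helixScaffold(4)$atoms)))
  expect_equal(nFrames(one), 1)
  # drop an atom from the second model
  broken <- txt[-(grep("^MODEL", txt)[2] + 3)]
  expect_error(readMultiModelPDB(broken), "atom counts")
})

test_that("kabsch superposition finds the global minimum", {
  set.seed(11)
  ref <- matrix(rnorm(30), ncol = 3)
  # identical -> 0; arbitrary rigid motion -> 0 within 1e-8
  expect_equal(kabschSuperpose(ref, ref)$rmsd, 0, tolerance = 1e-10)
  moved <- applyRigidMotion(ref, seed = 12)
  fit <- kabschSuperpose(moved, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # single displaced atom: rmsd <= d and equals the quaternion oracle
  for (d in c(0.5, 2, 5)) {
    pert <- ref; pert[3, 1] <- pert[3, 1] + d
    r1 <- kabschSuperpose(pert, ref)$rmsd
    expect_lte(r1, d)
    expect_equal(r1, quaternionRmsd(pert, ref), tolerance = 1e-6)
  }
  # random deformations against the oracle
  for (k in 1:5) {
    pert <- applyRigidMotion(ref + matrix(rnorm(30, 0, 0.7), ncol = 3))
    expect_equal(kabschSuperpose(pert, ref)$rmsd, quaternionRmsd(pert, ref),
                 tolerance = 1e-6)
  }
  expect_error(kabschSuperpose(ref[1:2, ], ref[1:2, ]), "3 atoms")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabschSuperpose(line, line), "degenerate|collinear")
})

test_that("rmsd series is a rigid-motion-invariant pseudometric", {
  scaf <- helixScaffold(10)
  n <- nrow(scaf$coords)
  coords <- array(NA_real_, c(n, 3, 4))
  set.seed(3)
  for (f in 1:4) coords[, , f] <- applyRigidMotion(scaf$coords)
  traj <- Trajectory(coords, scaf$atoms)
  ref <- Trajectory(scaf$coords, scaf$atoms)
  rs <- rmsdSeries(traj, ref, "CA+CB")
  expect_true(all(rs$rmsd < 1e-8))      # rigid motion only
  # jitter trajectory against per-frame direct oracle
  jt <- synthJitterTrajectory(scaf, sigma = 0.3, nFrames = 10, seed = 4)
  rs2 <- rmsdSeries(jt$traj, ref, "CA+CB")
  direct <- vapply(1:10, function(f)
    quaternionRmsd(jt$traj@coords[, , f], scaf$coords), numeric(1))
  expect_equal(rs2$rmsd, direct, tolerance = 1e-6)
  # symmetry of the underlying fit
  a <- jt$traj@coords[, , 1]; b <- jt$traj@coords[, , 2]
  expect_equal(kabschSuperpose(a, b)$rmsd, kabschSuperpose(b, a)$rmsd,
               tolerance = 1e-9)
})

test_that("dihedral angle follows the IUPAC convention and its symmetries", {
  # planar trans and cis butane-like points
  trans <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
  expect_equal(dihedralAngle(trans[1, ], trans[2, ], trans[3, ], trans[5, ]), 180)
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedralAngle(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  set.seed(5)
  for (k in 1:10) {
    p <- matrix(rnorm(12, sd = 2), ncol = 3)
    a <- tryCatch(dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ]),
                  error = function(e) NA)
    if (is.na(a)) next
    expect_gt(a, -180); expect_lte(a, 180)
    # reversing atom order preserves the angle
    expect_equal(dihedralAngle(p[4, ], p[3, ], p[2, ], p[1, ]), a,
                 tolerance = 1e-9)
    # mirror image negates it
    m <- p; m[, 1] <- -m[, 1]
    expect_equal(dihedralAngle(m[1, ], m[2, ], m[3, ], m[4, ]),
                 ifelse(abs(a) == 180, a, -a), tolerance = 1e-9)
  }
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("torsion series agrees with manual dihedral evaluation", {
  # four-atom chain per residue: N, CA, C backbone over 3 residues
  atoms <- data.frame(
    name = rep(c("N", "CA", "C"), 3),
    resno = rep(1:3, each = 3), resname = "ALA", stringsAsFactors = FALSE)
  set.seed(6)
  coords <- array(rnorm(27 * 2, sd = 3), c(9, 3, 2))
  traj <- Trajectory(coords, atoms)
  ts <- torsionSeries(traj)
  # psi of residue 1 in frame 2, by hand
  xyz <- coords[, , 2]
  hand <- dihedralAngle(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  expect_equal(ts$angle[ts$torsion == "psi" & ts$residue == 1 & ts$frame == 2],
               hand, tolerance = 1e-9)
  # terminal residues lack phi (res 1) and psi (res 3)
  expect_false(any(ts$torsion == "phi" & ts$residue == 1))
  expect_false(any(ts$torsion == "psi" & ts$residue == 3))
  pp <- phiPsiTable(traj)
  expect_true(all(is.na(pp$phi[pp$residue == 1])))
  expect_equal(pp$psi[pp$residue == 1 & pp$frame == 2], hand, tolerance = 1e-9)
})

test_that("radius of gyration matches the direct formula and is invariant", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radiusOfGyration(two, massWeighted = FALSE), 1.0)
  expect_equal(radiusOfGyration(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  set.seed(8)
  cloud <- matrix(rnorm(60, sd = 4), ncol = 3)
  direct <- sqrt(mean(rowSums(sweep(cloud, 2, colMeans(cloud))^2)))
  expect_equal(radiusOfGyration(cloud, massWeighted = FALSE), direct,
               tolerance = 1e-12)
  expect_equal(radiusOfGyration(applyRigidMotion(cloud), massWeighted = FALSE),
               direct, tolerance = 1e-9)
  # mass weighting shifts the centroid toward heavy atoms
  el <- rep(c("C", "H"), 10)
  rgw <- radiusOfGyration(cloud, massWeighted = TRUE, elements = el)
  expect_false(isTRUE(all.equal(rgw, direct)))
})

test_that("energy fluctuation ratio handles the defined and degenerate cases", {
  ke <- c(1, 2, 3, 4)
  expect_equal(energyFluctuationRatio(rep(5, 4), ke)$ratio, 0)
  expect_equal(energyFluctuationRatio(ke, ke)$ratio, 1.0)
  es <- synthEnergySeries(sigmaE = 1, sigmaKE = 2, n = 2e4, seed = 9)
  expect_equal(energyFluctuationRatio(es$E, es$KE)$ratio,
               es$manifest$expectedRatio, tolerance = 0.05)
  expect_error(energyFluctuationRatio(c(1, 2), rep(3, 2)), "constant")
  expect_error(energyFluctuationRatio(1:3, 1:4), "equal length")
})
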