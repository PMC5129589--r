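# Karplus couplings, chi-square comparison, iRED order parameters and
# two-step B-factors.

test_that("karplus evaluation and the uniform-angle average", {
  ks <- karplusSet("test", c2 = 1)
  expect_equal(karplusJ(0, ks), 1)
  expect_equal(karplusJ(90, ks), 0, tolerance = 1e-12)
  # uniform theta average of A cos^2 + C is A/2 + C
  ks2 <- karplusSet("test", c0 = 2, c2 = 6)
  th <- seq(0, 360, length.out = 100001)[-1]
  expect_equal(mean(karplusJ(th, ks2)), 6 / 2 + 2, tolerance = 1e-3)
  # phase offset shifts the argument
  ks3 <- karplusSet("test", c1 = 1, delta = -60)
  expect_equal(karplusJ(60, ks3), 1)
  expect_error(karplusSet("empty"), "nonzero")
})

test_that("mean coupling averages J, not the angle, and is linear", {
  ks <- karplusSet("test", c2 = 4)   # A-only
  expect_equal(meanCoupling(rep(33, 5), ks), karplusJ(33, ks))
  # frames at 0 and 180: cos^2 is 1 at both, so mean J is A, while the
  # circular-mean angle (90) would give 0
  expect_equal(meanCoupling(c(0, 180), ks), 4)
  expect_false(isTRUE(all.equal(meanCoupling(c(0, 180), ks),
                                karplusJ(90, ks))))
  # linearity: concatenation equals the weighted mean of parts
  set.seed(41)
  a <- runif(30, -180, 180); b <- runif(70, -180, 180)
  expect_equal(meanCoupling(c(a, b), ks),
               0.3 * meanCoupling(a, ks) + 0.7 * meanCoupling(b, ks),
               tolerance = 1e-12)
})

test_that("configured Karplus sets load and unsourced couplings fail loudly", {
  sets <- loadKarplusSets()
  s <- getKarplusSet(sets, "3JHNHA", "Original")
  expect_equal(s$delta, -60)
  expect_gt(s$c2, 0)
  expect_error(getKarplusSet(sets, "3JC'C'"), "refused|no Karplus")
})

test_that("chi-square and RMSD against hand-computed tables", {
  calc <- data.frame(residue = 1:3, couplingId = "J", J = c(5, 6, 7))
  obsEq <- data.frame(residue = 1:3, couplingId = "J", J = c(5, 6, 7),
                      sigma = 0.5)
  r0 <- chiSquareCouplings(calc, obsEq)
  expect_equal(r0$chi2, 0); expect_equal(r0$rmsd, 0)
  # one pair with deviation exactly sigma
  one <- chiSquareCouplings(
    data.frame(residue = 1, couplingId = "J", J = 5.5),
    data.frame(residue = 1, couplingId = "J", J = 5, sigma = 0.5))
  expect_equal(one$chi2, 1)
  # three pairs by hand
  obs <- data.frame(residue = 1:3, couplingId = "J", J = c(5.5, 5.5, 8),
                    sigma = c(0.5, 1, 2))
  r <- chiSquareCouplings(calc, obs)
  expect_equal(r$chi2, mean(c((-.5 / .5)^2, (.5 / 1)^2, (-1 / 2)^2)))
  expect_equal(r$rmsd, sqrt(mean(c(.25, .25, 1))))
  # chi2 ordering invariance and 1/sigma^2 scaling
  perm <- sample(3)
  expect_equal(chiSquareCouplings(calc[perm, ], obs)$chi2, r$chi2)
  obs2 <- obs; obs2$sigma <- obs2$sigma * 2
  expect_equal(chiSquareCouplings(calc, obs2)$chi2, r$chi2 / 4)
  # unmatched pairs warn; no match errors
  expect_warning(chiSquareCouplings(
    rbind(calc, data.frame(residue = 9, couplingId = "J", J = 1)), obs),
    "skipped")
  expect_error(suppressWarnings(chiSquareCouplings(
    data.frame(residue = 9, couplingId = "J", J = 1), obs)), "match")
  # equal-weight combination with propagated SE
  comb <- combineChiSquare(c(1, 3), c(0.1, 0.2))
  expect_equal(comb$mean, 2)
  expect_equal(comb$se, sqrt(0.01 + 0.04) / 2)
})

test_that("two-step alignment removes rigid motion", {
  scaf <- helixScaffold(8)
  atoms <- scaf$atoms
  atoms$name[atoms$name == "CB"] <- "C"   # give the fit a backbone-ish set
  n <- nrow(scaf$coords)
  coords <- array(NA_real_, c(n, 3, 5))
  set.seed(42)
  for (f in 1:5) coords[, , f] <- applyRigidMotion(scaf$coords)
  traj <- Trajectory(coords, atoms)
  al <- twoStepAlignment(traj, "backbone")
  for (f in 2:5)
    expect_lt(max(abs(al@coords[, , f] - al@coords[, , 1])), 1e-8)
  # an already-aligned trajectory is unchanged
  again <- twoStepAlignment(al, "backbone")
  expect_equal(again@coords, al@coords, tolerance = 1e-8)
})

test_that("iRED order parameters: static, isotropic and cone limits", {
  # static vectors -> S2 = 1 everywhere
  cw0 <- synthConeWobble(M = 20, coneSemiangle = 0, nFrames = 4, seed = 43)
  expect_equal(iredS2(cw0$vectors)$s2, rep(1, 20), tolerance = 1e-9)
  # independent isotropic vectors, M = 50 -> S2 about excluded/M = 0.1
  set.seed(44)
  M <- 50; Tn <- 20000
  v <- array(rnorm(M * 3 * Tn), c(M, 3, Tn))
  nr <- sqrt(v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
  for (k in 1:3) v[, k, ] <- v[, k, ] / nr
  s2 <- iredS2(v)$s2
  expect_lt(abs(mean(s2) - 5 / 50), 0.01)
  # cone wobble recovers the closed form
  cw <- synthConeWobble(M = 72, coneSemiangle = 18.73, nFrames = 20000,
                        seed = 45)
  r <- iredS2(cw$vectors)
  expect_lt(max(abs(r$s2 - cw$manifest$s2)), 0.02)
  # global rotation invariance
  R <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  vr <- cw$vectors
  for (f in seq_len(dim(vr)[3])) vr[, , f] <- vr[, , f] %*% R
  expect_equal(iredS2(vr)$s2, r$s2, tolerance = 1e-6)
  expect_error(iredS2(cw$vectors[1:4, , , drop = FALSE]), "excluded modes")
})

test_that("iRED mode completeness makes the excluded-mode identity exact", {
  cw <- synthConeWobble(M = 12, coneSemiangle = 25, nFrames = 500, seed = 46)
  v <- cw$vectors
  M <- dim(v)[1]; Tn <- dim(v)[3]
  C <- matrix(0, M, M)
  for (f in seq_len(Tn)) {
    dot <- tcrossprod(v[, , f])
    C <- C + (3 * dot^2 - 1) / 2
  }
  C <- C / Tn
  expect_equal(diag(C), rep(1, M), tolerance = 1e-9)
  expect_equal(sum(diag(C)), M, tolerance = 1e-9)
  eig <- eigen(C, symmetric = TRUE)
  # completeness: sum over all modes of lambda * e^2 = 1 per residue
  expect_equal(colSums(eig$values * t(eig$vectors^2)), rep(1, M),
               tolerance = 1e-9)
  # S2 via excluded-large-modes equals 1 - internal sum
  r <- iredS2(v)
  internal <- colSums(eig$values[6:M] * t(eig$vectors[, 6:M]^2))
  expect_equal(r$s2, pmin(pmax(1 - internal, 0), 1), tolerance = 1e-9)
})

test_that("B-factors recover the jitter variance and ignore rigid motion", {
  jt <- synthJitterTrajectory(sigma = 0.1, nFrames = 300, seed = 47)
  bf <- bFactors(jt$traj, "CA")
  expect_equal(mean(bf$B), jt$manifest$expectedB, tolerance = 0.05)
  # static trajectory -> all zero
  scaf <- helixScaffold(10, withCB = FALSE)
  still <- Trajectory(array(rep(scaf$coords, 3), c(nrow(scaf$coords), 3, 3)),
                      scaf$atoms)
  expect_equal(bFactors(still, "CA")$B, rep(0, 10), tolerance = 1e-12)
  # global rigid motion adds nothing
  jr <- synthJitterTrajectory(sigma = 0.1, nFrames = 300,
                              globalRigidMotion = TRUE, seed = 47)
  bfr <- bFactors(jr$traj, "CA")
  expect_equal(mean(bfr$B), jt$manifest$expectedB, tolerance = 0.05)
})

test_that("observable RMSD is the plain root-mean-square difference", {
  expect_equal(observableRmsd(1:5, 1:5), 0)
  expect_equal(observableRmsd(1:5 + 0.3, 1:5), 0.3)
  set.seed(48)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(observableRmsd(a, b), sqrt(mean((a - b)^2)))
  expect_error(observableRmsd(1:3, 1:4), "length")
})
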