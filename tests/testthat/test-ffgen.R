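# Parameter-file parsing, the four forcefield modifications, and the
# mass/timestep bookkeeping.

fixtureFF <- function() parseParameterFile(synthFrcmod()$text, "frcmod")

test_that("frcmod parsing matches the generator manifest and round-trips", {
  fx <- synthFrcmod()
  ff <- fixtureFF()
  counts <- fx$manifest$counts
  expect_equal(nrow(atomTypes(ff)), counts$atomTypes)
  expect_equal(nrow(bondTypes(ff)), counts$bonds)
  expect_equal(nrow(angleTypes(ff)), counts$angles)
  expect_equal(nrow(torsionTypes(ff)), counts$torsions)
  expect_equal(nrow(ljTypes(ff)), counts$lj)

  # single MASS record read directly
  one <- parseParameterFile(c("t", "MASS", "CT 12.01", ""), "frcmod")
  expect_equal(atomTypes(one)$mass, 12.01)

  # write(parse(f)) re-parses to an equal object, and is idempotent text
  txt1 <- writeParameterFile(ff)
  ff2 <- parseParameterFile(txt1, "frcmod")
  for (acc in list(atomTypes, bondTypes, angleTypes, torsionTypes, ljTypes))
    expect_equal(acc(ff2), acc(ff))
  expect_identical(writeParameterFile(ff2), txt1)
})

test_that("parm_dat dialect round-trips including pass-through sections", {
  frc <- fixtureFF()
  dat <- frc
  dat@dialect <- "parm_dat"
  dat@extras <- list(hydrophilic = "N   O   S ", hbond = "  HW  OW  0000.     0000.",
                     equivalences = "N   NA  N2", nonbonLabel = "MOD4      RE")
  txt <- writeParameterFile(dat)
  back <- parseParameterFile(txt, "parm_dat")
  for (acc in list(atomTypes, bondTypes, angleTypes, torsionTypes, ljTypes))
    expect_equal(acc(back), acc(dat))
  expect_identical(back@extras$hydrophilic, dat@extras$hydrophilic)
  expect_identical(back@extras$equivalences, dat@extras$equivalences)
})

test_that("parse errors name the offending line; unknown dialect refused", {
  bad <- c("title", "junk before any section header")
  expect_error(parseParameterFile(bad, "frcmod"), "line 2")
  expect_error(parseParameterFile("x", "nonsense"), "dialect")
})

test_that("C-H bonds shorten to 0.98/0.93 A and other bonds are untouched", {
  res <- shortenCHBonds(fixtureFF(), defaultTransformRules())
  b <- bondTypes(res$ff)
  expect_equal(b$b0[b$ai == "CT" & b$aj == "HC"], 0.98)
  expect_equal(b$b0[b$ai == "CA" & b$aj == "HA"], 0.93)
  expect_equal(b$b0[b$ai == "C" & b$aj == "O"], 1.229)
  expect_equal(b$kb, bondTypes(fixtureFF())$kb)  # force constants unchanged
  # a pair in both classes is a configuration error
  expect_error(defaultTransformRules(
    aliphaticPairs = rbind(c("CT", "HC")),
    aromaticPairs = rbind(c("CT", "HC"))) |> validObject(),
    "both")
})

test_that("torsions with an sp3 central atom are zeroed, sp2 kept, count preserved", {
  ff <- fixtureFF()
  res <- zeroSp3Torsions(ff, defaultTransformRules())
  tr <- torsionTypes(res$ff)
  expect_equal(nrow(tr), nrow(torsionTypes(ff)))
  quartet <- paste(tr$ai, tr$aj, tr$ak, tr$al, sep = "-")
  expect_true(all(tr$kphi[quartet == "X-CT-CT-X"] == 0))
  expect_true(all(tr$kphi[quartet == "CT-S-S-CT"] == 0))   # disulfide
  expect_equal(tr$kphi[quartet == "X-C-N-X"], 10)          # amide untouched
  expect_true(all(res$report$field == "kphi" & res$report$new == 0))
  # no sp3 match is valid and reports zero changes
  none <- zeroSp3Torsions(ff, defaultTransformRules(sp3Types = "ZZ"))
  expect_equal(nrow(none$report), 0)
})

test_that("phi/psi terms get SCNB 1.00 / SCEE 1.18, others keep file values", {
  res <- setPhiPsiScaling(fixtureFF(), defaultTransformRules())
  tr <- torsionTypes(res$ff)
  quartet <- paste(tr$ai, tr$aj, tr$ak, tr$al, sep = "-")
  phi <- quartet == "C-N-CT-C"; psi <- quartet == "N-CT-C-N"
  expect_true(all(tr$scnb[phi | psi] == 1.00))
  expect_true(all(tr$scee[phi | psi] == 1.18))
  chi <- quartet == "N-CT-CT-CT"
  expect_equal(tr$scnb[chi], 2.00)
  expect_equal(tr$scee[chi], 1.20)
  # absent quartet group warns, does not error
  noPhi <- parseParameterFile(c("t", "DIHE",
    "N -CT-C -N    1     1.45000     180.0   1.0", ""), "frcmod")
  expect_warning(setPhiPsiScaling(noPhi, defaultTransformRules()), "phi")
})

test_that("mass scaling is uniform, errors on nonpositive scale", {
  ff <- fixtureFF()
  res <- scaleMasses(ff, 0.1)
  at <- atomTypes(res$ff)
  expect_equal(at$mass[at$type == "H"], 0.1008)
  expect_equal(at$mass[at$type == "O"], 1.600)
  expect_equal(atomTypes(scaleMasses(ff, 1)$ff), atomTypes(ff))
  expect_error(scaleMasses(ff, 0), "positive")
})

test_that("prmtop MASS block rescales in place, other bytes identical", {
  prm <- c("%VERSION x", "%FLAG TITLE", "%FORMAT(20a4)", "test",
           "%FLAG MASS", "%FORMAT(5E16.8)",
           paste0(sprintf("%16.8E", c(1.008, 12.01, 14.01, 16.00, 32.06)),
                  collapse = ""),
           paste0(sprintf("%16.8E", c(1.008, 12.01)), collapse = ""),
           "%FLAG CHARGE", "%FORMAT(5E16.8)",
           paste0(sprintf("%16.8E", c(0.5, -0.5)), collapse = ""))
  out <- scalePrmtopMasses(prm, 0.1)
  diffs <- which(out != prm)
  expect_equal(diffs, c(7L, 8L))                       # only MASS data lines
  expect_identical(scalePrmtopMasses(prm, 1.0), prm)   # identity at scale 1
  v <- as.numeric(substring(out[7], seq(1, 65, 16), seq(16, 80, 16)))
  expect_equal(v, c(0.1008, 1.201, 1.401, 1.600, 3.206))
  expect_error(scalePrmtopMasses(prm[1:4], 0.1), "MASS")
})

test_that("equivalent timestep follows the sqrt mass-scale law", {
  expect_equal(equivalentTimestep(1.00, 0.1), sqrt(10), tolerance = 1e-12)
  expect_equal(round(equivalentTimestep(1.00, 0.1), 2), 3.16)
  expect_equal(equivalentTimestep(1.7, 1.0), 1.7)
  expect_equal(equivalentTimestep(2.00, 0.25), 4.00)
  # inversion to machine precision
  for (s in c(0.1, 0.25, 0.77))
    expect_equal(equivalentTimestep(1.3, s) * sqrt(s), 1.3, tolerance = 1e-14)
  expect_error(equivalentTimestep(-1, 0.1), "positive")
})

test_that("full transform composes correctly and is idempotent at scale 1", {
  ff <- fixtureFF()
  sm <- applyFF12MC(ff, defaultTransformRules(massScale = 1.0))
  expect_equal(atomTypes(sm$ff), atomTypes(ff))        # standard-mass variant
  lm <- applyFF12MC(ff, defaultTransformRules(massScale = 0.1))
  expect_equal(atomTypes(lm$ff)$mass, atomTypes(ff)$mass * 0.1)
  # run twice: second pass reports no changes
  again <- applyFF12MC(sm$ff, defaultTransformRules(massScale = 1.0))
  expect_equal(nrow(again$report), 0)
  expect_equal(torsionTypes(again$ff), torsionTypes(sm$ff))
})

test_that("mass scaling commutes with the other three transforms", {
  ff <- fixtureFF()
  rules <- defaultTransformRules(massScale = 0.1)
  massFirst <- applyFF12MC(scaleMasses(ff, 0.1)$ff,
                           defaultTransformRules(massScale = 1.0))$ff
  massLast <- applyFF12MC(ff, rules)$ff
  for (acc in list(atomTypes, bondTypes, angleTypes, torsionTypes, ljTypes))
    expect_equal(acc(massFirst), acc(massLast))
})
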