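# The four forcefield modifications and the mass/timestep bookkeeping.
#
# The transformation pipeline rewrites an FF99-style parameter set into its
# fast-sampling variant: (1) C-H equilibrium bond lengths set to the values
# observed in sub-angstrom cryogenic protein structures (0.98 A aliphatic,
# 0.93 A aromatic), (2) torsion potentials whose central atoms are sp3
# zeroed, (3) phi/psi 1-4 scaling divisors reduced to SCNB 1.00 / SCEE 1.18,
# and (4) optionally all atomic masses multiplied by 0.1 for low-mass
# sampling enhancement.

#' Default transformation rules
#'
#' The hybridisation and C-H classification tables follow FF99 atom-type
#' conventions: `CT`-family carbons (and sp3 N/O/S types) count as sp3 when
#' central in a torsion; hydrogens `HC`/`H1`/`H2`/`H3`/`HP` bonded to
#' sp3 carbons form the aliphatic C-H class and `HA`/`H4`/`H5` bonded to
#' aromatic carbons form the aromatic class.  The source publications name
#' no explicit type lists, so these tables are an editable inference; pass
#' modified matrices to override any of them.
#'
#' @param massScale uniform mass multiplier; `0.1` produces the low-mass
#'   variant, `1` the standard-mass variant.
#' @param aliphaticCHb0,aromaticCHb0 target equilibrium lengths, A.
#' @param phiPsiScnb,phiPsiScee 1-4 scaling divisors written onto phi/psi.
#' @param sp3Types character vector of sp3-classified atom types.
#' @param aliphaticPairs,aromaticPairs 2-column character matrices of
#'   (C type, H type) bonds to shorten.
#' @param phiQuartets,psiQuartets 4-column character matrices of backbone
#'   torsion quartets.
#' @return a [TransformRules-class].
#' @export
defaultTransformRules <- function(massScale = 0.1,
                                  aliphaticCHb0 = 0.98,
                                  aromaticCHb0 = 0.93,
                                  phiPsiScnb = 1.00,
                                  phiPsiScee = 1.18,
                                  sp3Types = c("CT", "3C", "2C", "C8", "N3",
                                               "S", "SH", "OH", "OS", "CX"),
                                  aliphaticPairs = NULL,
                                  aromaticPairs = NULL,
                                  phiQuartets = NULL,
                                  psiQuartets = NULL) {
  sp3C <- c("CT", "3C", "2C", "C8", "CX")
  aroC <- c("CA", "CB", "CC", "CN", "CR", "CV", "CW", "C*")
  if (is.null(aliphaticPairs))
    aliphaticPairs <- as.matrix(expand.grid(
      sp3C, c("HC", "H1", "H2", "H3", "HP"), stringsAsFactors = FALSE))
  if (is.null(aromaticPairs))
    aromaticPairs <- as.matrix(expand.grid(
      aroC, c("HA", "H4", "H5"), stringsAsFactors = FALSE))
  if (is.null(phiQuartets))
    phiQuartets <- rbind(c("C", "N", "CT", "C"), c("C", "N", "CX", "C"))
  if (is.null(psiQuartets))
    psiQuartets <- rbind(c("N", "CT", "C", "N"), c("N", "CX", "C", "N"))
  dimnames(aliphaticPairs) <- dimnames(aromaticPairs) <- NULL
  new("TransformRules",
      aliphaticCHb0 = aliphaticCHb0, aromaticCHb0 = aromaticCHb0,
      sp3Types = sp3Types,
      aliphaticPairs = aliphaticPairs, aromaticPairs = aromaticPairs,
      phiQuartets = phiQuartets, psiQuartets = psiQuartets,
      phiPsiScnb = phiPsiScnb, phiPsiScee = phiPsiScee,
      massScale = massScale)
}

pairKey <- function(a, b) {
  # order-insensitive bond key
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

matchPairs <- function(bonds, pairs) {
  if (!nrow(bonds) || !nrow(pairs)) return(logical(nrow(bonds)))
  pairKey(bonds$ai, bonds$aj) %in% pairKey(pairs[, 1], pairs[, 2])
}

emptyReport <- function() {
  data.frame(step = character(), record = character(), field = character(),
             old = numeric(), new = numeric(), stringsAsFactors = FALSE)
}

reportRows <- function(step, record, field, old, new) {
  old <- rep_len(old, length(record))
  new <- rep_len(new, length(record))
  keep <- which(old != new)
  data.frame(step = rep_len(step, length(keep)), record = record[keep],
             field = rep_len(field, length(keep)),
             old = old[keep], new = new[keep], stringsAsFactors = FALSE)
}

#' Shorten C-H equilibrium bond lengths
#'
#' Sets `b0` of every bond whose type pair is classified aliphatic C-H to
#' `rules@aliphaticCHb0` (0.98 A by default) and of every aromatic C-H pair
#' to `rules@aromaticCHb0` (0.93 A).  Force constants and all other bonds
#' are untouched.  Pair matching is order-insensitive.
#'
#' @param ff an [FFParamSet-class].
#' @param rules a [TransformRules-class].
#' @return list with elements `ff` (transformed set) and `report`
#'   (data.frame of changed records).
#' @export
shortenCHBonds <- function(ff, rules) {
  validObject(rules)
  b <- ff@bonds
  ali <- matchPairs(b, rules@aliphaticPairs)
  aro <- matchPairs(b, rules@aromaticPairs)
  rep1 <- reportRows("shorten_ch", pairKey(b$ai, b$aj)[ali], "b0",
                     b$b0[ali], rules@aliphaticCHb0)
  rep2 <- reportRows("shorten_ch", pairKey(b$ai, b$aj)[aro], "b0",
                     b$b0[aro], rules@aromaticCHb0)
  b$b0[ali] <- rules@aliphaticCHb0
  b$b0[aro] <- rules@aromaticCHb0
  ff@bonds <- b
  list(ff = ff, report = rbind(rep1, rep2))
}

#' Zero torsion potentials with a nonperipheral sp3 atom
#'
#' A torsion i-j-k-l is affected when either central atom (j or k) has a
#' type in `rules@sp3Types`.  Affected terms get `kphi = 0`; no record is
#' added or deleted, so a Fourier series keeps all of its (zeroed) terms
#' and downstream topology builders still find every parameter.  Impropers
#' are never touched.
#'
#' @inheritParams shortenCHBonds
#' @return list with `ff` and `report`; the report lists every zeroed
#'   quartet (possibly zero rows).
#' @export
zeroSp3Torsions <- function(ff, rules) {
  tr <- ff@torsions
  hit <- tr$aj %in% rules@sp3Types | tr$ak %in% rules@sp3Types
  rec <- apply(tr[c("ai", "aj", "ak", "al")], 1, paste, collapse = "-")
  rep <- reportRows("zero_sp3", rec[hit], "kphi", tr$kphi[hit], 0)
  tr$kphi[hit] <- 0
  ff@torsions <- tr
  list(ff = ff, report = rep)
}

quartetKey <- function(ai, aj, ak, al) {
  # direction-insensitive torsion key
  fwd <- paste(ai, aj, ak, al, sep = "|")
  rev <- paste(al, ak, aj, ai, sep = "|")
  ifelse(fwd <= rev, fwd, rev)
}

#' Reduce the phi/psi 1-4 interaction scaling factors
#'
#' Torsion terms matching a configured phi or psi quartet get
#' `scnb = rules@phiPsiScnb` (1.00) and `scee = rules@phiPsiScee` (1.18).
#' All other terms keep the divisors stored in the file (2.00 / 1.20 for
#' standard files).  Configured quartets with no matching term produce a
#' warning, not an error.
#'
#' @inheritParams shortenCHBonds
#' @return list with `ff` and `report`.
#' @export
setPhiPsiScaling <- function(ff, rules) {
  tr <- ff@torsions
  key <- quartetKey(tr$ai, tr$aj, tr$ak, tr$al)
  keyOf <- function(q) quartetKey(q[, 1], q[, 2], q[, 3], q[, 4])
  phiKey <- keyOf(rules@phiQuartets); psiKey <- keyOf(rules@psiQuartets)
  for (grp in list(c("phi", phiKey), c("psi", psiKey)))
    if (!any(key %in% grp[-1]))
      warning("no ", grp[1], " torsion quartet present in the parameter set",
              call. = FALSE)
  wantKey <- c(phiKey, psiKey)
  hit <- key %in% wantKey
  rec <- apply(tr[c("ai", "aj", "ak", "al")], 1, paste, collapse = "-")
  rep <- rbind(
    reportRows("phi_psi_scaling", rec[hit], "scnb", tr$scnb[hit], rules@phiPsiScnb),
    reportRows("phi_psi_scaling", rec[hit], "scee", tr$scee[hit], rules@phiPsiScee))
  tr$scnb[hit] <- rules@phiPsiScnb
  tr$scee[hit] <- rules@phiPsiScee
  ff@torsions <- tr
  list(ff = ff, report = rep)
}

#' Uniformly scale atomic masses
#'
#' Multiplies every atom-type mass by `massScale`; nothing else changes.
#' The scaling applies to every type present, solvent included, matching
#' the low-mass protocol of scaling the entire simulation system.
#'
#' @param ff an [FFParamSet-class].
#' @param massScale multiplier in (0, 1].
#' @return list with `ff` and `report`.
#' @export
scaleMasses <- function(ff, massScale) {
  if (!is.numeric(massScale) || massScale <= 0)
    stopUsage("massScale must be positive")
  at <- ff@atomTypes
  rep <- reportRows("scale_masses", at$type, "mass", at$mass, at$mass * massScale)
  at$mass <- at$mass * massScale
  ff@atomTypes <- at
  list(ff = ff, report = rep)
}

#' Standard-mass-equivalent timestep of a mass-scaled simulation
#'
#' With all masses multiplied by `massScale`, a simulation integrated at
#' `dt` of standard-mass time is theoretically equivalent to a
#' standard-mass simulation at `dt / sqrt(massScale)`: a tenfold mass
#' reduction stretches the effective timestep by sqrt(10), so 1.00 fs
#' becomes 3.16 fs.
#'
#' @param dt timestep in fs (standard-mass time).
#' @param massScale mass multiplier, > 0.
#' @return equivalent timestep in fs.
#' @export
equivalentTimestep <- function(dt, massScale) {
  if (any(dt <= 0) || any(massScale <= 0))
    stopUsage("dt and massScale must be positive")
  dt / sqrt(massScale)
}

#' Apply the full forcefield transformation
#'
#' Runs [shortenCHBonds()], [zeroSp3Torsions()] and [setPhiPsiScaling()] in
#' order, then [scaleMasses()] when `rules@massScale < 1`.  With
#' `massScale = 1` the output is the standard-mass variant of the
#' forcefield; with `massScale = 0.1` the low-mass variant additionally has
#' every atomic mass reduced tenfold.
#'
#' @inheritParams shortenCHBonds
#' @return list with `ff` (the transformed [FFParamSet-class]) and
#'   `report` (data.frame enumerating every changed record, with columns
#'   `step`, `record`, `field`, `old`, `new`).
#' @export
applyFF12MC <- function(ff, rules = defaultTransformRules()) {
  validObject(rules)
  s1 <- shortenCHBonds(ff, rules)
  s2 <- zeroSp3Torsions(s1$ff, rules)
  s3 <- setPhiPsiScaling(s2$ff, rules)
  out <- s3
  report <- rbind(s1$report, s2$report, s3$report)
  if (rules@massScale < 1) {
    s4 <- scaleMasses(s3$ff, rules@massScale)
    out <- s4
    report <- rbind(report, s4$report)
  }
  list(ff = out$ff, report = report)
}
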