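# Torsion-based fractional helicity and RMSD-based alpha-helix population.

#' Alpha-helix window criterion
#'
#' A residue is helical in a frame when it belongs to a run of at least
#' `runLength` consecutive residues whose phi and psi both lie within
#' `tolerance` degrees (wrapped difference) of the canonical alpha-helix
#' values.
#'
#' @param phiCenter,psiCenter canonical helix torsions, degrees.
#' @param tolerance half-width of the acceptance window, degrees.
#' @param runLength minimum number of consecutive eligible residues.
#' @param scoredResidues residue numbers entering the helicity average
#'   (terminal capping groups are never scored).
#' @return list of criterion fields.
#' @export
helixCriterion <- function(phiCenter = -57, psiCenter = -47, tolerance = 20,
                           runLength = 4, scoredResidues = 1:15) {
  if (tolerance <= 0 || runLength < 1)
    stopUsage("tolerance must be positive and runLength >= 1")
  list(phiCenter = phiCenter, psiCenter = psiCenter, tolerance = tolerance,
       runLength = runLength, scoredResidues = scoredResidues)
}

#' Per-frame, per-residue helix flags
#'
#' Windows may extend through eligible residues outside the scored set;
#' only the scored residues are averaged later.  Residues with a missing
#' phi or psi are ineligible.
#'
#' @param torsionTable data.frame with columns `frame`, `residue`, `phi`,
#'   `psi` (degrees; `NA` allowed), as from [phiPsiTable()].
#' @param criterion see [helixCriterion()].
#' @return data.frame with columns `frame`, `residue`, `helical`.
#' @export
residueHelixFlags <- function(torsionTable, criterion = helixCriterion()) {
  tt <- torsionTable[order(torsionTable$frame, torsionTable$residue), ]
  eligible <- !is.na(tt$phi) & !is.na(tt$psi) &
    angleDiff(tt$phi, criterion$phiCenter) <= criterion$tolerance &
    angleDiff(tt$psi, criterion$psiCenter) <= criterion$tolerance
  helical <- logical(nrow(tt))
  for (f in unique(tt$frame)) {
    sel <- which(tt$frame == f)
    r <- stats::setNames(rle(eligible[sel]), c("lengths", "values"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= criterion$runLength
    for (k in which(ok)) helical[sel[starts[k]:ends[k]]] <- TRUE
  }
  data.frame(frame = tt$frame, residue = tt$residue, helical = helical)
}

#' Fractional helicity over one or more simulations
#'
#' The component fractional helicity of a residue is the fraction of all
#' frames (pooled over simulations) in which the residue is helical; the
#' fractional helicity is the equal-weight mean of the component values
#' over the scored residues.  The SD across simulations uses each
#' simulation's own fractional helicity, as for aggregated populations.
#'
#' @param flagTables list of flag tables from [residueHelixFlags()] (or a
#'   single table).
#' @param criterion see [helixCriterion()].
#' @return list with `perResidue` (named vector over scored residues),
#'   `mean`, `sd` (NA for a single simulation) and `nSims`.
#' @export
fractionalHelicity <- function(flagTables, criterion = helixCriterion()) {
  if (is.data.frame(flagTables)) flagTables <- list(flagTables)
  if (!length(flagTables)) stopUsage("no flag tables supplied")
  scored <- criterion$scoredResidues
  pooled <- do.call(rbind, flagTables)
  pooled <- pooled[pooled$residue %in% scored, ]
  perRes <- tapply(pooled$helical, factor(pooled$residue, levels = scored), mean)
  perRes[is.na(perRes)] <- 0
  perSim <- vapply(flagTables, function(ft) {
    ft <- ft[ft$residue %in% scored, ]
    pr <- tapply(ft$helical, factor(ft$residue, levels = scored), mean)
    pr[is.na(pr)] <- 0
    mean(pr)
  }, numeric(1))
  list(perResidue = perRes, mean = mean(perSim),
       sd = if (length(perSim) >= 2) stats::sd(perSim) else NA_real_,
       nSims = length(flagTables))
}

#' Alpha-helix population from a global RMSD series
#'
#' Fraction of conformations within the native cutoff of the full-helix
#' reference conformation; a thin wrapper over [nativePopulation()] with
#' the helix reference.
#'
#' @param series RMSD series of the trajectory against the full-helix
#'   reference (see [rmsdSeries()]).
#' @param criterion see [nativeStateCriterion()].
#' @return fraction in \[0, 1\].
#' @export
alphaHelixPopulation <- function(series, criterion = nativeStateCriterion()) {
  nativePopulation(series, criterion)
}
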