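#' @import methods
NULL

# ---- FFParamSet -------------------------------------------------------------

#' Container for AMBER-style forcefield constants
#'
#' An `FFParamSet` holds the parameter records of one parameter file: atom
#' types with masses, bond, angle and proper/improper torsion terms, and
#' Lennard-Jones radii/well depths.  Torsion rows carry the AMBER `PK`
#' convention (barrier height divided by `divider`) together with their
#' per-term 1-4 scaling divisors `scee` and `scnb`.
#'
#' @slot title character title line of the source file.
#' @slot atomTypes data.frame with columns `type`, `mass` (Da) and
#'   `polarizability` (may be `NA`).
#' @slot bonds data.frame with columns `ai`, `aj`, `kb`
#'   (kcal/mol/A^2) and `b0` (A).
#' @slot angles data.frame with columns `ai`, `aj`, `ak`, `ktheta`
#'   (kcal/mol/rad^2) and `theta0` (degrees).
#' @slot torsions data.frame with columns `ai`..`al`, `divider`, `kphi`
#'   (kcal/mol), `phase` (degrees), `periodicity`, `scee`, `scnb`.  Multiple
#'   rows per atom-type quartet form a Fourier series.
#' @slot impropers data.frame with columns `ai`..`al`, `kphi`, `phase`,
#'   `periodicity`.
#' @slot lj data.frame with columns `type`, `radius` (A), `epsilon`
#'   (kcal/mol).
#' @slot extras list of pass-through sections retained verbatim for the
#'   `parm_dat` dialect (hydrophilic card, H-bond 10-12 terms, nonbonded
#'   equivalence card, nonbonded label line).
#' @slot dialect `"frcmod"` or `"parm_dat"`.
#' @export
setClass("FFParamSet", representation(
  title = "character",
  atomTypes = "data.frame",
  bonds = "data.frame",
  angles = "data.frame",
  torsions = "data.frame",
  impropers = "data.frame",
  lj = "data.frame",
  extras = "list",
  dialect = "character"
))

setValidity("FFParamSet", function(object) {
  msgs <- character()
  at <- object@atomTypes
  if (nrow(at)) {
    if (anyDuplicated(at$type))
      msgs <- c(msgs, "atom type names must be unique")
    if (any(!nzchar(at$type)))
      msgs <- c(msgs, "atom type names must be non-empty")
    if (any(!is.finite(at$mass)) || any(at$mass <= 0))
      msgs <- c(msgs, "atom masses must be positive")
    known <- c(at$type, "X")
    refs <- c(
      unlist(object@bonds[c("ai", "aj")], use.names = FALSE),
      unlist(object@angles[c("ai", "aj", "ak")], use.names = FALSE),
      unlist(object@torsions[c("ai", "aj", "ak", "al")], use.names = FALSE)
    )
    bad <- setdiff(refs, known)
    if (length(bad))
      msgs <- c(msgs, paste0("types referenced but not declared: ",
                             paste(sort(bad), collapse = ", ")))
  }
  if (nrow(object@bonds) && any(object@bonds$b0 <= 0))
    msgs <- c(msgs, "bond b0 must be positive")
  if (nrow(object@torsions)) {
    tr <- object@torsions
    if (any(tr$divider < 1) || any(tr$periodicity < 1))
      msgs <- c(msgs, "torsion divider and periodicity must be positive")
    if (any(tr$scee <= 0) || any(tr$scnb <= 0))
      msgs <- c(msgs, "scee and scnb must be positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FFParamSet compact record counts.
#' @param object an `FFParamSet`.
#' @export
setMethod("show", "FFParamSet", function(object) {
  cat("FFParamSet (", object@dialect, "): ", object@title, "\n", sep = "")
  cat(sprintf("  %d atom types, %d bonds, %d angles, %d torsions, %d impropers, %d LJ entries\n",
              nrow(object@atomTypes), nrow(object@bonds), nrow(object@angles),
              nrow(object@torsions), nrow(object@impropers), nrow(object@lj)))
})

#' @rdname ffAccessors
#' @export
setGeneric("atomTypes", function(x) standardGeneric("atomTypes"))
#' @rdname ffAccessors
#' @export
setGeneric("bondTypes", function(x) standardGeneric("bondTypes"))
#' @rdname ffAccessors
#' @export
setGeneric("angleTypes", function(x) standardGeneric("angleTypes"))
#' @rdname ffAccessors
#' @export
setGeneric("torsionTypes", function(x) standardGeneric("torsionTypes"))
#' @rdname ffAccessors
#' @export
setGeneric("ljTypes", function(x) standardGeneric("ljTypes"))

#' Accessors for FFParamSet record tables
#'
#' Return the record tables of an [FFParamSet-class] as data.frames.
#'
#' @param x an `FFParamSet`.
#' @return a data.frame of the requested record type.
#' @name ffAccessors
NULL

#' @rdname ffAccessors
#' @export
setMethod("atomTypes", "FFParamSet", function(x) x@atomTypes)
#' @rdname ffAccessors
#' @export
setMethod("bondTypes", "FFParamSet", function(x) x@bonds)
#' @rdname ffAccessors
#' @export
setMethod("angleTypes", "FFParamSet", function(x) x@angles)
#' @rdname ffAccessors
#' @export
setMethod("torsionTypes", "FFParamSet", function(x) x@torsions)
#' @rdname ffAccessors
#' @export
setMethod("ljTypes", "FFParamSet", function(x) x@lj)

# ---- TransformRules ---------------------------------------------------------

#' Rules driving the forcefield transformation
#'
#' Holds the classification tables and target values for the four
#' modifications: C-H bond shortening, zeroing of torsions with a
#' nonperipheral sp3 central atom, reduced phi/psi 1-4 scaling, and uniform
#' mass scaling.  The hybridisation and C-H pair tables are configuration
#' data, not read from parameter files; see [defaultTransformRules()].
#'
#' @slot aliphaticCHb0 target equilibrium length (A) for aliphatic C-H bonds.
#' @slot aromaticCHb0 target equilibrium length (A) for aromatic C-H bonds.
#' @slot sp3Types atom types treated as sp3 when central in a torsion.
#' @slot aliphaticPairs 2-column character matrix of (C type, H type) pairs.
#' @slot aromaticPairs 2-column character matrix of (C type, H type) pairs.
#' @slot phiQuartets 4-column character matrix of phi torsion quartets.
#' @slot psiQuartets 4-column character matrix of psi torsion quartets.
#' @slot phiPsiScnb SCNB divisor written onto phi/psi terms.
#' @slot phiPsiScee SCEE divisor written onto phi/psi terms.
#' @slot massScale uniform mass multiplier in (0, 1]; 0.1 for the low-mass
#'   variant, 1 for the standard-mass variant.
#' @export
setClass("TransformRules", representation(
  aliphaticCHb0 = "numeric",
  aromaticCHb0 = "numeric",
  sp3Types = "character",
  aliphaticPairs = "matrix",
  aromaticPairs = "matrix",
  phiQuartets = "matrix",
  psiQuartets = "matrix",
  phiPsiScnb = "numeric",
  phiPsiScee = "numeric",
  massScale = "numeric"
))

setValidity("TransformRules", function(object) {
  msgs <- character()
  if (object@aliphaticCHb0 <= 0 || object@aromaticCHb0 <= 0)
    msgs <- c(msgs, "target bond lengths must be positive")
  if (object@massScale <= 0 || object@massScale > 1)
    msgs <- c(msgs, "massScale must be in (0, 1]")
  if (ncol(object@aliphaticPairs) != 2 || ncol(object@aromaticPairs) != 2)
    msgs <- c(msgs, "pair tables must have two columns")
  if (ncol(object@phiQuartets) != 4 || ncol(object@psiQuartets) != 4)
    msgs <- c(msgs, "quartet tables must have four columns")
  ali <- apply(object@aliphaticPairs, 1, paste, collapse = "-")
  aro <- apply(object@aromaticPairs, 1, paste, collapse = "-")
  both <- intersect(ali, aro)
  if (length(both))
    msgs <- c(msgs, paste0("pairs classified both aliphatic and aromatic: ",
                           paste(both, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TransformRules summary of the rule tables.
#' @param object a `TransformRules`.
#' @export
setMethod("show", "TransformRules", function(object) {
  cat("TransformRules\n")
  cat(sprintf("  aliphatic C-H b0 %.2f A (%d pairs); aromatic C-H b0 %.2f A (%d pairs)\n",
              object@aliphaticCHb0, nrow(object@aliphaticPairs),
              object@aromaticCHb0, nrow(object@aromaticPairs)))
  cat("  sp3 central types:", paste(object@sp3Types, collapse = " "), "\n")
  cat(sprintf("  phi/psi SCNB %.2f, SCEE %.2f; mass scale %.2f\n",
              object@phiPsiScnb, object@phiPsiScee, object@massScale))
})

# ---- Trajectory -------------------------------------------------------------

#' Multi-frame coordinate trajectory
#'
#' Ordered coordinate frames with constant atom composition, plus the
#' standard-mass time between saved frames.
#'
#' @slot coords numeric array of dimension `c(nAtoms, 3, nFrames)` in A.
#' @slot atoms data.frame with columns `name`, `resno` (1-based), `resname`,
#'   `chain`, `element`; one row per atom, constant across frames.
#' @slot saveInterval standard-mass time per saved frame, ns.
#' @slot originTime time of the first frame, ns.
#' @export
setClass("Trajectory", representation(
  coords = "array",
  atoms = "data.frame",
  saveInterval = "numeric",
  originTime = "numeric"
))

setValidity("Trajectory", function(object) {
  msgs <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msgs <- c(msgs, "coords must be an nAtoms x 3 x nFrames array")
  else if (d[1] != nrow(object@atoms))
    msgs <- c(msgs, "atom table and coordinate array disagree on atom count")
  if (any(!is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (object@saveInterval <= 0)
    msgs <- c(msgs, "saveInterval must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Trajectory
#'
#' @param coords numeric array `c(nAtoms, 3, nFrames)`, or an `nAtoms x 3`
#'   matrix for a single frame.
#' @param atoms data.frame with columns `name`, `resno`, `resname` and
#'   optionally `chain`, `element`.  Missing optional columns are filled.
#' @param saveInterval ns of standard-mass time between frames.
#' @param originTime ns, time of the first frame.
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(coords, atoms, saveInterval = 1, originTime = saveInterval) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element)) atoms$element <- guessElement(atoms$name)
  new("Trajectory", coords = coords, atoms = atoms,
      saveInterval = saveInterval, originTime = originTime)
}

#' @rdname trajAccessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname trajAccessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname trajAccessors
#' @export
setGeneric("frameCoords", function(x, frame) standardGeneric("frameCoords"))
#' @rdname trajAccessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname trajAccessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Accessors for Trajectory objects
#'
#' @param x a [Trajectory-class].
#' @param frame 1-based frame index.
#' @return `nFrames`/`nAtoms` return integers; `frameCoords` an
#'   `nAtoms x 3` matrix; `frameTimes` a numeric vector in ns; `atomData`
#'   the per-atom data.frame.
#' @name trajAccessors
NULL

#' @rdname trajAccessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname trajAccessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname trajAccessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame) x@coords[, , frame, drop = TRUE])
#' @rdname trajAccessors
#' @export
setMethod("frameTimes", "Trajectory", function(x)
  x@originTime + (seq_len(nFrames(x)) - 1L) * x@saveInterval)
#' @rdname trajAccessors
#' @export
setMethod("atomData", "Trajectory", function(x) x@atoms)

#' @describeIn Trajectory frame/atom counts and time base.
#' @param object a `Trajectory`.
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms x %d frames, save interval %g ns\n",
              nAtoms(object), nFrames(object), object@saveInterval))
})

# ---- QualityScoreTable ------------------------------------------------------

#' Model x method x score grid of refinement quality scores
#'
#' Long-format quality scores for ranking refinement methods, together with
#' the orientation of every score (whether higher or lower values are
#' better) and the name of the unrefined reference row, which by the frozen
#' package convention does not enter the per-score statistics.
#'
#' @slot scores data.frame with columns `model`, `method`, `score`, `value`
#'   (`NA` allowed for missing entries).
#' @slot orientation named character vector mapping every score name to
#'   `"higher_better"` or `"lower_better"`.
#' @slot referenceMethod method label of the unrefined starting model
#'   (`NA_character_` if none).
#' @export
setClass("QualityScoreTable", representation(
  scores = "data.frame",
  orientation = "character",
  referenceMethod = "character"
))

setValidity("QualityScoreTable", function(object) {
  msgs <- character()
  need <- c("model", "method", "score", "value")
  if (!all(need %in% names(object@scores)))
    msgs <- c(msgs, "scores must have columns model, method, score, value")
  else {
    sc <- unique(object@scores$score)
    miss <- setdiff(sc, names(object@orientation))
    if (length(miss))
      msgs <- c(msgs, paste0("orientation undeclared for: ",
                             paste(miss, collapse = ", ")))
    if (!all(object@orientation %in% c("higher_better", "lower_better")))
      msgs <- c(msgs, "orientation values must be higher_better or lower_better")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a QualityScoreTable
#'
#' @param scores long-format data.frame (`model`, `method`, `score`,
#'   `value`).
#' @param orientation named character vector, one entry per score name,
#'   `"higher_better"` or `"lower_better"`.
#' @param referenceMethod label of the unrefined row, excluded from the
#'   per-score statistics; `NA` if the table has none.
#' @return a [QualityScoreTable-class].
#' @export
qualityScoreTable <- function(scores, orientation, referenceMethod = NA_character_) {
  new("QualityScoreTable",
      scores = as.data.frame(scores, stringsAsFactors = FALSE),
      orientation = orientation, referenceMethod = referenceMethod)
}

#' @describeIn QualityScoreTable grid dimensions.
#' @param object a `QualityScoreTable`.
#' @export
setMethod("show", "QualityScoreTable", function(object) {
  s <- object@scores
  cat(sprintf("QualityScoreTable: %d models x %d methods x %d scores (%d values, %d missing)\n",
              length(unique(s$model)), length(unique(s$method)),
              length(unique(s$score)), sum(!is.na(s$value)), sum(is.na(s$value))))
})

# ---- ZScoreReport -----------------------------------------------------------

#' Z-score aggregation of a quality-score table
#'
#' Standardised scores at the three levels of aggregation: per (model,
#' score) cell over methods, per model (equal-weight mean over scores, with
#' missing scores contributing zero), and per method over models.
#'
#' @slot variant `"classical"` (mean/SD) or `"robust"` (median/MAD).
#' @slot qsZ data.frame `model`, `method`, `score`, `z`.
#' @slot modelZ data.frame `model`, `method`, `z`.
#' @slot methodZ named numeric vector of method-level Z, sorted decreasing.
#' @slot convention list recording the statistics conventions used.
#' @export
setClass("ZScoreReport", representation(
  variant = "character",
  qsZ = "data.frame",
  modelZ = "data.frame",
  methodZ = "numeric",
  convention = "list"
))

#' @describeIn ZScoreReport ranked method-level scores.
#' @param object a `ZScoreReport`.
#' @export
setMethod("show", "ZScoreReport", function(object) {
  cat("ZScoreReport (", object@variant, " variant)\n", sep = "")
  z <- object@methodZ
  for (i in seq_along(z))
    cat(sprintf("  %2d. %-12s %+.2f\n", i, names(z)[i], z[i]))
})

#' @rdname methodZ
#' @export
setGeneric("methodZ", function(x) standardGeneric("methodZ"))

#' Method-level Z scores of a report
#'
#' @param x a [ZScoreReport-class].
#' @return named numeric vector, best method first.
#' @name methodZ
#' @export
setMethod("methodZ", "ZScoreReport", function(x) x@methodZ)

# ---- FoldingTimeEstimate ----------------------------------------------------

#' Survival-analysis estimate of the mean folding time
#'
#' @slot mean mean time-to-folding, ns.
#' @slot lcl,ucl 95\% confidence limits, ns.
#' @slot nEvents number of simulations that captured a folding event.
#' @slot nTotal number of simulations.
#' @slot method `"km"` or `"parametric"`.
#' @slot distribution `"none"`, `"exponential"` or `"weibull"`.
#' @export
setClass("FoldingTimeEstimate", representation(
  mean = "numeric", lcl = "numeric", ucl = "numeric",
  nEvents = "integer", nTotal = "integer",
  method = "character", distribution = "character"
))

setValidity("FoldingTimeEstimate", function(object) {
  msgs <- character()
  if (object@nEvents > object@nTotal)
    msgs <- c(msgs, "nEvents cannot exceed nTotal")
  if (is.finite(object@lcl) && is.finite(object@ucl) &&
      !(object@lcl <= object@mean + 1e-9 && object@mean <= object@ucl + 1e-9))
    msgs <- c(msgs, "confidence limits must bracket the mean")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FoldingTimeEstimate estimate with its confidence interval.
#' @param object a `FoldingTimeEstimate`.
#' @export
setMethod("show", "FoldingTimeEstimate", function(object) {
  cat(sprintf("Mean time-to-folding: %.4g ns (95%% CI %.4g-%.4g), %d events of %d [%s%s]\n",
              object@mean, object@lcl, object@ucl, object@nEvents, object@nTotal,
              object@method,
              if (object@distribution == "none") "" else paste0(", ", object@distribution)))
})
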