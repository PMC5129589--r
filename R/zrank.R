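# Refinement-quality scoring and classical/robust Z-score aggregation.
#
# Standardisation is per (model, score) cell over the refinement methods.
# Two conventions the printed tables leave open are frozen package
# defaults, derived once by disambiguateZConventions(): the unrefined
# reference row is excluded from the per-score statistics, and
# lower-is-better scores are sign-flipped before standardisation (the
# classical variant uses the sample, n-1, standard deviation).

zCell <- function(values, variant, sdType) {
  # values: oriented scores of the participating methods (NA = missing)
  v <- values[!is.na(values)]
  z <- rep(0, length(values))
  if (length(v) < 2) {
    if (length(v) == 1)
      warning("single available value in a score cell; Z set to 0",
              call. = FALSE)
    return(z)
  }
  if (variant == "classical") {
    mu <- mean(v)
    s <- if (sdType == "population") sqrt(mean((v - mu)^2)) else stats::sd(v)
    if (s > 0) z[!is.na(values)] <- (v - mu) / s
  } else {
    md <- stats::median(v)
    madv <- stats::median(abs(v - md))
    if (madv > 0) z[!is.na(values)] <- (v - md) / (1.4826 * madv)
  }
  z
}

#' Z-score aggregation of a quality-score table
#'
#' For every (model, score) cell the available method scores are
#' standardised (classical mean/SD or robust median/MAD with consistency
#' constant 1.4826); lower-is-better scores are negated first so that a
#' larger Z always means better.  Missing scores get Z = 0.  Model-level Z
#' is the equal-weight mean over score names, method-level Z the
#' equal-weight mean over models.
#'
#' @param table a [QualityScoreTable-class].
#' @param variant `"robust"` or `"classical"`.
#' @param sdType `"sample"` (n-1) or `"population"` SD for the classical
#'   variant.
#' @param includeReference include the unrefined reference row in the
#'   per-cell statistics (it never receives aggregated scores itself).
#' @return a [ZScoreReport-class].
#' @export
zScores <- function(table, variant = c("robust", "classical"),
                    sdType = c("sample", "population"),
                    includeReference = FALSE) {
  variant <- match.arg(variant)
  sdType <- match.arg(sdType)
  validObject(table)
  s <- table@scores
  refM <- table@referenceMethod
  methods <- setdiff(unique(s$method), if (is.na(refM)) character() else refM)
  models <- unique(s$model)
  scoreNames <- unique(s$score)
  qs <- expand.grid(model = models, method = methods, score = scoreNames,
                    stringsAsFactors = FALSE)
  qs$z <- 0
  for (m in models) for (sc in scoreNames) {
    pool <- if (includeReference || is.na(refM)) unique(s$method) else methods
    vals <- s$value[match(paste(m, pool, sc), paste(s$model, s$method, s$score))]
    if (table@orientation[sc] == "lower_better") vals <- -vals
    zAll <- zCell(vals, variant, sdType)
    sel <- qs$model == m & qs$score == sc
    qs$z[sel] <- zAll[match(qs$method[sel], pool)]
  }
  modelZ <- stats::aggregate(z ~ model + method, qs, mean)
  mz <- tapply(modelZ$z, modelZ$method, mean)
  mz <- sort(stats::setNames(as.numeric(mz), names(mz)), decreasing = TRUE)
  new("ZScoreReport", variant = variant, qsZ = qs, modelZ = modelZ,
      methodZ = mz,
      convention = list(sdType = sdType, includeReference = includeReference,
                        orientationFlip = TRUE))
}

#' @rdname zScores
#' @param ... passed to [zScores()].
#' @export
classicalZ <- function(table, ...) zScores(table, variant = "classical", ...)

#' @rdname zScores
#' @export
robustZ <- function(table, ...) zScores(table, variant = "robust", ...)

#' Derive the frozen standardisation conventions
#'
#' Enumerates the open convention choices (include the unrefined reference
#' row in per-cell statistics or not; sample vs population SD for the
#' classical variant) and keeps the combination whose robust and classical
#' method rankings both reproduce `expectedOrder`.  Orientation flipping of
#' lower-is-better scores is always applied; without it no combination can
#' rank refinement methods sensibly.
#'
#' @param table a [QualityScoreTable-class].
#' @param expectedOrder character vector of method labels from best to
#'   worst.
#' @return list with the selected `includeReference` and `sdType`, plus
#'   `candidates`, a data.frame of every combination and whether it
#'   matched.
#' @export
disambiguateZConventions <- function(table, expectedOrder) {
  grid <- expand.grid(includeReference = c(FALSE, TRUE),
                      sdType = c("sample", "population"),
                      stringsAsFactors = FALSE)
  grid$matches <- vapply(seq_len(nrow(grid)), function(k) {
    ok <- vapply(c("robust", "classical"), function(v) {
      z <- zScores(table, variant = v, sdType = grid$sdType[k],
                   includeReference = grid$includeReference[k])
      identical(names(methodZ(z)), expectedOrder)
    }, logical(1))
    all(ok)
  }, logical(1))
  hit <- which(grid$matches)
  if (!length(hit))
    stopUsage("no convention combination reproduces the expected ranking")
  list(includeReference = grid$includeReference[hit[1]],
       sdType = grid$sdType[hit[1]], candidates = grid)
}

#' Alpha-carbon RMSD refinement score
#'
#' Best-fit (unweighted) RMSD over alpha carbons between a model and the
#' reference crystal structure, matched by residue number.
#'
#' @param model,reference single-frame [Trajectory-class] objects (or
#'   lists with `coords` and `atoms`).
#' @return RMSD in A.
#' @export
caRmsdScore <- function(model, reference) {
  model <- asReferenceFrame(model); reference <- asReferenceFrame(reference)
  m <- matchSelection(model$atoms, reference$atoms, "CA")
  kabschSuperpose(model$coords[m$traj, , drop = FALSE],
                  reference$coords[m$ref, , drop = FALSE])$rmsd
}

#' Secondary-structure-element RMSD refinement score
#'
#' Best-fit RMSD over the backbone CA, C, N, O atoms of the residues
#' assigned to secondary-structure elements in the reference structure.
#'
#' @inheritParams caRmsdScore
#' @param sseResidues residue numbers of the secondary-structure elements.
#' @return RMSD in A.
#' @export
sseRmsdScore <- function(model, reference, sseResidues) {
  model <- asReferenceFrame(model); reference <- asReferenceFrame(reference)
  m <- matchSelection(model$atoms, reference$atoms, "backbone",
                      residues = sseResidues)
  kabschSuperpose(model$coords[m$traj, , drop = FALSE],
                  reference$coords[m$ref, , drop = FALSE])$rmsd
}

#' Read a long-format quality-score CSV
#'
#' Expected columns: `model`, `method`, `score`, `value`, `orientation`
#' (constant per score).  Lines starting with `#` are comments.  Empty
#' `value` fields become missing entries.
#'
#' @param file CSV path.
#' @param referenceMethod label of the unrefined row, if present.
#' @return a [QualityScoreTable-class].
#' @export
readQualityScores <- function(file, referenceMethod = "None") {
  d <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  orient <- tapply(d$orientation, d$score, function(x) x[1])
  if (!referenceMethod %in% d$method) referenceMethod <- NA_character_
  qualityScoreTable(d[c("model", "method", "score", "value")],
                    orientation = stats::setNames(as.character(orient),
                                                  names(orient)),
                    referenceMethod = referenceMethod)
}
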