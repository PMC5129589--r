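# Parameter-file I/O: AMBER frcmod and parm .dat dialects.
#
# Both dialects store the same record types; frcmod announces each section
# with a keyword header (MASS, BOND, ANGLE, DIHE, IMPROPER, NONBON) while
# parm .dat relies on a fixed block order separated by blank lines.  Atom
# type fields are fixed-width (2 characters, dash-separated), so parsing
# slices columns rather than splitting on whitespace.

.FRCMOD_SECTIONS <- c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER", "NONBON")

splitTypeField <- function(field, n) {
  # "C -N -CT-C " -> c("C","N","CT","C"); fields are 2 chars + dash
  out <- character(n)
  for (i in seq_len(n)) out[i] <- trimws(substr(field, 3 * i - 2, 3 * i - 1))
  out
}

joinTypeField <- function(types) {
  paste(sprintf("%-2s", types), collapse = "-")
}

numTokens <- function(rest) {
  toks <- strsplit(trimws(rest), "\\s+")[[1]]
  suppressWarnings(as.numeric(toks))
}

parseScaleTokens <- function(line) {
  scee <- regmatches(line, regexpr("SCEE\\s*=\\s*[0-9.]+", line))
  scnb <- regmatches(line, regexpr("SCNB\\s*=\\s*[0-9.]+", line))
  list(
    scee = if (length(scee)) as.numeric(sub(".*=\\s*", "", scee)) else NA_real_,
    scnb = if (length(scnb)) as.numeric(sub(".*=\\s*", "", scnb)) else NA_real_
  )
}

emptyFF <- function(title = "", dialect = "frcmod") {
  new("FFParamSet",
      title = title,
      atomTypes = data.frame(type = character(), mass = numeric(),
                             polarizability = numeric(), stringsAsFactors = FALSE),
      bonds = data.frame(ai = character(), aj = character(),
                         kb = numeric(), b0 = numeric(), stringsAsFactors = FALSE),
      angles = data.frame(ai = character(), aj = character(), ak = character(),
                          ktheta = numeric(), theta0 = numeric(), stringsAsFactors = FALSE),
      torsions = data.frame(ai = character(), aj = character(), ak = character(),
                            al = character(), divider = integer(), kphi = numeric(),
                            phase = numeric(), periodicity = integer(),
                            scee = numeric(), scnb = numeric(), stringsAsFactors = FALSE),
      impropers = data.frame(ai = character(), aj = character(), ak = character(),
                             al = character(), kphi = numeric(), phase = numeric(),
                             periodicity = integer(), stringsAsFactors = FALSE),
      lj = data.frame(type = character(), radius = numeric(), epsilon = numeric(),
                      stringsAsFactors = FALSE),
      extras = list(), dialect = dialect)
}

parseMassLine <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  data.frame(type = toks[1], mass = as.numeric(toks[2]),
             polarizability = if (length(toks) >= 3)
               suppressWarnings(as.numeric(toks[3])) else NA_real_,
             stringsAsFactors = FALSE)
}

parseBondLine <- function(line) {
  tp <- splitTypeField(substr(line, 1, 5), 2)
  v <- numTokens(substr(line, 6, nchar(line)))
  data.frame(ai = tp[1], aj = tp[2], kb = v[1], b0 = v[2], stringsAsFactors = FALSE)
}

parseAngleLine <- function(line) {
  tp <- splitTypeField(substr(line, 1, 8), 3)
  v <- numTokens(substr(line, 9, nchar(line)))
  data.frame(ai = tp[1], aj = tp[2], ak = tp[3],
             ktheta = v[1], theta0 = v[2], stringsAsFactors = FALSE)
}

parseDiheLine <- function(line) {
  tp <- splitTypeField(substr(line, 1, 11), 4)
  sc <- parseScaleTokens(line)
  body <- sub("SCEE\\s*=\\s*[0-9.]+", "", line)
  body <- sub("SCNB\\s*=\\s*[0-9.]+", "", body)
  body <- gsub(",", " ", substr(body, 12, nchar(body)))
  v <- numTokens(body)
  data.frame(ai = tp[1], aj = tp[2], ak = tp[3], al = tp[4],
             divider = as.integer(v[1]), kphi = v[2], phase = v[3],
             periodicity = as.integer(abs(v[4])),
             scee = if (is.na(sc$scee)) 1.20 else sc$scee,
             scnb = if (is.na(sc$scnb)) 2.00 else sc$scnb,
             stringsAsFactors = FALSE)
}

parseImproperLine <- function(line) {
  tp <- splitTypeField(substr(line, 1, 11), 4)
  v <- numTokens(substr(line, 12, nchar(line)))
  data.frame(ai = tp[1], aj = tp[2], ak = tp[3], al = tp[4],
             kphi = v[1], phase = v[2], periodicity = as.integer(abs(v[3])),
             stringsAsFactors = FALSE)
}

parseNonbonLine <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  data.frame(type = toks[1], radius = as.numeric(toks[2]),
             epsilon = as.numeric(toks[3]), stringsAsFactors = FALSE)
}

#' Parse an AMBER-style parameter file
#'
#' Reads forcefield constants from text in either the `frcmod` dialect
#' (keyword section headers) or the `parm_dat` dialect (fixed block order).
#' Pass-through sections of `parm_dat` files (hydrophilic card, H-bond
#' 10-12 terms, nonbonded equivalences) are retained verbatim so that
#' writing is lossless.
#'
#' @param text character vector of file lines, a single string with
#'   embedded newlines, or a path to an existing file.
#' @param dialect `"frcmod"` or `"parm_dat"`.
#' @return an [FFParamSet-class].
#' @seealso [writeParameterFile()], [applyFF12MC()]
#' @export
parseParameterFile <- function(text, dialect = c("frcmod", "parm_dat")) {
  if (length(dialect) == 1 && !dialect %in% c("frcmod", "parm_dat"))
    stopUsage("unknown parameter-file dialect: ", dialect)
  dialect <- match.arg(dialect)
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (dialect == "frcmod") parseFrcmod(text) else parseParmDat(text)
}

parseFrcmod <- function(lines) {
  ff <- emptyFF(title = if (length(lines)) trimws(lines[1]) else "",
                dialect = "frcmod")
  section <- NA_character_
  for (i in seq_along(lines)[-1]) {
    line <- lines[i]
    if (!nzchar(trimws(line))) { section <- NA_character_; next }
    key <- toupper(trimws(line))
    if (key %in% c(.FRCMOD_SECTIONS, "DIHEDRAL", "NONB")) {
      section <- key
      if (section == "DIHEDRAL") section <- "DIHE"
      if (section == "NONB") section <- "NONBON"
      next
    }
    if (is.na(section))
      stopUsage("malformed section header at line ", i, ": '", trimws(line), "'")
    rec <- switch(section,
      MASS = parseMassLine(line),
      BOND = parseBondLine(line),
      ANGLE = parseAngleLine(line),
      DIHE = parseDiheLine(line),
      IMPROPER = parseImproperLine(line),
      NONBON = parseNonbonLine(line))
    if (anyNA(rec[vapply(rec, is.numeric, TRUE)][
      setdiff(names(rec)[vapply(rec, is.numeric, TRUE)], "polarizability")]))
      stopUsage("unparseable ", section, " record at line ", i, ": '", line, "'")
    slotName <- switch(section, MASS = "atomTypes", BOND = "bonds",
                       ANGLE = "angles", DIHE = "torsions",
                       IMPROPER = "impropers", NONBON = "lj")
    slot(ff, slotName) <- rbind(slot(ff, slotName), rec)
  }
  validObject(ff)
  ff
}

parseParmDat <- function(lines) {
  ff <- emptyFF(title = if (length(lines)) trimws(lines[1]) else "",
                dialect = "parm_dat")
  i <- 2L
  n <- length(lines)
  takeBlock <- function() {
    block <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      block <- c(block, lines[i]); i <<- i + 1L
    }
    i <<- i + 1L  # skip the blank terminator
    block
  }
  parseBlock <- function(block, fn, what) {
    if (!length(block)) return(NULL)
    do.call(rbind, lapply(seq_along(block), function(k) {
      rec <- tryCatch(fn(block[k]), error = function(e) NULL)
      if (is.null(rec)) stopUsage("unparseable ", what, " record: '", block[k], "'")
      rec
    }))
  }
  ff@atomTypes <- parseBlock(takeBlock(), parseMassLine, "MASS") %||%
    ff@atomTypes
  ff@extras$hydrophilic <- takeBlock()
  ff@bonds <- parseBlock(takeBlock(), parseBondLine, "BOND") %||% ff@bonds
  ff@angles <- parseBlock(takeBlock(), parseAngleLine, "ANGLE") %||% ff@angles
  ff@torsions <- parseBlock(takeBlock(), parseDiheLine, "DIHE") %||% ff@torsions
  ff@impropers <- parseBlock(takeBlock(), parseImproperLine, "IMPROPER") %||%
    ff@impropers
  ff@extras$hbond <- takeBlock()
  ff@extras$equivalences <- takeBlock()
  # the nonbonded kind label (e.g. "MOD4      RE") is a single line followed
  # directly by the LJ records
  ff@extras$nonbonLabel <- if (i <= n && nzchar(trimws(lines[i]))) {
    lbl <- lines[i]; i <- i + 1L; lbl
  } else "MOD4      RE"
  ff@lj <- parseBlock(takeBlock(), parseNonbonLine, "NONBON") %||% ff@lj
  validObject(ff)
  ff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmtMassLine <- function(rec) {
  base <- sprintf("%-2s %10.4f", rec$type, rec$mass)
  if (is.finite(rec$polarizability))
    base <- sprintf("%s %12.3f", base, rec$polarizability)
  base
}

fmtBondLine <- function(rec)
  sprintf("%s %9.2f %9.4f", joinTypeField(c(rec$ai, rec$aj)), rec$kb, rec$b0)

fmtAngleLine <- function(rec)
  sprintf("%s %9.2f %10.2f", joinTypeField(c(rec$ai, rec$aj, rec$ak)),
          rec$ktheta, rec$theta0)

fmtDiheLine <- function(rec, continued) {
  sprintf("%s %3d %11.5f %9.1f %5.1f    SCEE=%.2f SCNB=%.2f",
          joinTypeField(c(rec$ai, rec$aj, rec$ak, rec$al)),
          rec$divider, rec$kphi, rec$phase,
          if (continued) -rec$periodicity else rec$periodicity,
          rec$scee, rec$scnb)
}

fmtImproperLine <- function(rec)
  sprintf("%s     %11.5f %9.1f %5.1f",
          joinTypeField(c(rec$ai, rec$aj, rec$ak, rec$al)),
          rec$kphi, rec$phase, as.numeric(rec$periodicity))

fmtNonbonLine <- function(rec)
  sprintf("  %-2s %15.4f %10.4f", rec$type, rec$radius, rec$epsilon)

fmtTorsionBlock <- function(torsions) {
  if (!nrow(torsions)) return(character())
  quartet <- apply(torsions[c("ai", "aj", "ak", "al")], 1, paste, collapse = "-")
  continued <- c(quartet[-1] == quartet[-length(quartet)], FALSE)
  vapply(seq_len(nrow(torsions)), function(k)
    fmtDiheLine(torsions[k, ], continued[k]), character(1))
}

#' Write an FFParamSet back to parameter-file text
#'
#' Emits the canonical fixed-width form of the stored records in the
#' object's own dialect.  Consecutive torsion rows sharing one atom-type
#' quartet are written as a Fourier series with negative periodicities on
#' all but the last term; per-term `SCEE=`/`SCNB=` divisors are always
#' written (the legacy global-scaling syntax is not supported).
#'
#' @param ff an [FFParamSet-class].
#' @param file optional path; when given, the text is also written there.
#' @return character vector of file lines, invisibly when `file` is set.
#' @export
writeParameterFile <- function(ff, file = NULL) {
  rows <- function(df, fn) if (nrow(df))
    vapply(seq_len(nrow(df)), function(k) fn(df[k, ]), character(1)) else character()
  if (ff@dialect == "frcmod") {
    out <- c(ff@title,
             "MASS", rows(ff@atomTypes, fmtMassLine), "",
             "BOND", rows(ff@bonds, fmtBondLine), "",
             "ANGLE", rows(ff@angles, fmtAngleLine), "",
             "DIHE", fmtTorsionBlock(ff@torsions), "",
             "IMPROPER", rows(ff@impropers, fmtImproperLine), "",
             "NONBON", rows(ff@lj, fmtNonbonLine), "")
  } else {
    out <- c(ff@title,
             rows(ff@atomTypes, fmtMassLine), "",
             ff@extras$hydrophilic, "",
             rows(ff@bonds, fmtBondLine), "",
             rows(ff@angles, fmtAngleLine), "",
             fmtTorsionBlock(ff@torsions), "",
             rows(ff@impropers, fmtImproperLine), "",
             ff@extras$hbond, "",
             ff@extras$equivalences, "",
             ff@extras$nonbonLabel %||% "MOD4      RE",
             rows(ff@lj, fmtNonbonLine), "",
             "END")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Rescale the MASS block of an AMBER topology file
#'
#' Multiplies every value in the `%FLAG MASS` block of prmtop text by
#' `massScale`, re-emitting the block in its `5E16.8` layout.  Every other
#' byte of the file is left untouched.
#'
#' @param text prmtop content as a character vector of lines, a single
#'   string, or a path to an existing file.
#' @param massScale multiplier in (0, 1].
#' @return character vector of the modified lines.
#' @export
scalePrmtopMasses <- function(text, massScale) {
  if (massScale <= 0) stopUsage("massScale must be positive")
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  flag <- which(trimws(text) == "%FLAG MASS")
  if (!length(flag)) stopUsage("no %FLAG MASS block in prmtop text")
  start <- flag[1] + 1L
  if (grepl("^%FORMAT", text[start])) start <- start + 1L
  end <- start
  while (end <= length(text) && !startsWith(text[end], "%")) end <- end + 1L
  for (i in seq(start, end - 1L)) {
    line <- text[i]
    nf <- nchar(line) %/% 16L
    vals <- vapply(seq_len(nf), function(k)
      as.numeric(substr(line, 16 * k - 15, 16 * k)), numeric(1))
    text[i] <- paste(sprintf("%16.8E", vals * massScale), collapse = "")
  }
  text
}
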