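# small shared helpers

# element inferred from a PDB atom name: leading digits stripped, then the
# first character (two-character elements are not expected in protein-only
# fixtures apart from explicit overrides)
guessElement <- function(name) {
  nm <- toupper(sub("^[0-9']+", "", trimws(name)))
  substr(nm, 1L, 1L)
}

# wrapped angular difference in degrees, result in [0, 180]
angleDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# map any angle to (-180, 180]
wrapAngle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# standard atomic masses (Da) for mass-weighted geometry
elementMass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
           S = 32.06, P = 30.974)
  m <- tab[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

stopUsage <- function(...) stop(..., call. = FALSE)
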