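# Monoisotopic mass constants (Da). Sources: CODATA atomic masses; residue
# masses are the dehydrated (in-chain) monosaccharide residues.
MASS_CH2    <- 14.01565
MASS_H2O    <- 18.01056
MASS_NA     <- 22.98977
MASS_PROTON <- 1.00728
MASS_C13C12 <- 1.00336   # 13C - 12C spacing used for isotopologue m/z
MASS_OAC    <- 42.01057  # O-acetyl (+C2H2O)
END_PERME   <- 46.04186  # permethylated free-reducing end group (+C2H6O)

# exact atomic masses for formula arithmetic
ATOM_MASS <- c(C = 12.0, H = 1.00782503, N = 14.00307401, O = 15.99491462,
               Na = 22.98976928)

#' Monosaccharide residue table
#'
#' The residue-mass and elemental-composition table that all mass arithmetic
#' in the package is built on. Each row is a dehydrated (in-chain)
#' monosaccharide residue class distinguishable by MS1: hexose (Hex),
#' N-acetylhexosamine (HexNAc), deoxyhexose (dHex), and the sialic acids
#' NeuAc, NeuGc and KDN. `sites` is the number of permethylation sites per
#' residue; the permethylated residue mass is
#' `mass + sites * 14.01565`.
#'
#' @return A data.frame with columns `residue`, `mass` (underivatized
#'   monoisotopic, Da), `C`, `H`, `N`, `O` (elemental formula) and `sites`.
#' @examples
#' residue_table()
#' @export
residue_table <- function() {
  tab <- data.frame(
    residue = c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc", "KDN"),
    mass    = c(162.05282, 203.07937, 146.05791, 291.09542, 307.09033,
                250.06887),
    C = c(6, 8, 6, 11, 11, 9),
    H = c(10, 13, 10, 17, 17, 14),
    N = c(0, 1, 0, 1, 1, 0),
    O = c(5, 5, 4, 8, 9, 8),
    sites = c(3, 3, 2, 5, 6, 6),
    stringsAsFactors = FALSE
  )
  tab$perme_mass <- tab$mass + tab$sites * MASS_CH2
  tab
}

# fast lookup vectors (computed once at load)
.res_env <- new.env(parent = emptyenv())

.residues <- function() {
  if (is.null(.res_env$tab)) {
    tab <- residue_table()
    .res_env$tab <- tab
    .res_env$mass <- stats::setNames(tab$mass, tab$residue)
    .res_env$perme <- stats::setNames(tab$perme_mass, tab$residue)
    .res_env$sites <- stats::setNames(tab$sites, tab$residue)
  }
  .res_env$tab
}

residue_mass <- function(residue, derivatization = "permethylated") {
  .residues()
  m <- switch(match.arg(derivatization, c("permethylated", "native")),
              permethylated = .res_env$perme, native = .res_env$mass)
  if (!all(residue %in% names(m)))
    stop("unknown residue kind: ",
         paste(setdiff(residue, names(m)), collapse = ", "))
  unname(m[residue])
}

#' Export the constants table
#'
#' Writes the residue table plus the scalar mass constants to CSV so that
#' downstream audits of reported m/z values are bit-exact against a fixed,
#' versioned table.
#'
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_constants_csv <- function(path) {
  tab <- residue_table()
  consts <- data.frame(
    residue = c("(CH2)", "(H2O)", "(Na)", "(proton)", "(13C-12C)",
                "(O-acetyl)", "(perMe end group)"),
    mass = c(MASS_CH2, MASS_H2O, MASS_NA, MASS_PROTON, MASS_C13C12,
             MASS_OAC, END_PERME),
    C = NA, H = NA, N = NA, O = NA, sites = NA, perme_mass = NA)
  utils::write.csv(rbind(tab, consts), path, row.names = FALSE)
  invisible(path)
}

# round-half-up to 2 decimals; matches how instrument software displays m/z
round2 <- function(x) floor(x * 100 + 0.5) / 100
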