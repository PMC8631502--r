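COMP_KINDS <- c("neuac", "neugc", "kdn", "hex", "hexnac", "dhex", "oacetyl")
# residue-table row used for each composition slot (oacetyl handled apart)
COMP_RESIDUE <- c(neuac = "NeuAc", neugc = "NeuGc", kdn = "KDN",
                  hex = "Hex", hexnac = "HexNAc", dhex = "dHex")

#' Monosaccharide composition
#'
#' A composition is the unit of MS1 assignment: counts of the residue
#' classes distinguishable by mass alone, plus the number of O-acetyl
#' groups carried on sialic acids (native glycans only; permethylation
#' strips O-acetylation).
#'
#' @param neuac,neugc,kdn,hex,hexnac,dhex,oacetyl non-negative residue /
#'   modification counts.
#' @param oacetyl_cap maximum O-acetyl groups allowed per sialic acid
#'   (default 3, the biological cap used throughout the package).
#' @return an object of class `glycan_composition` (named integer vector).
#' @examples
#' glycan_composition(neuac = 2, hex = 5, hexnac = 4)
#' parse_composition("NeuAc2Hex5HexNAc4")
#' @export
glycan_composition <- function(neuac = 0, neugc = 0, kdn = 0, hex = 0,
                               hexnac = 0, dhex = 0, oacetyl = 0,
                               oacetyl_cap = 3) {
  x <- c(neuac = neuac, neugc = neugc, kdn = kdn, hex = hex,
         hexnac = hexnac, dhex = dhex, oacetyl = oacetyl)
  if (any(x < 0)) stop("composition counts must be non-negative")
  if (any(x != round(x))) stop("composition counts must be integers")
  x <- as.integer(round(x))
  names(x) <- COMP_KINDS
  n_sa <- x[["neuac"]] + x[["neugc"]] + x[["kdn"]]
  cap <- if (is.finite(oacetyl_cap)) oacetyl_cap * n_sa else
    if (n_sa == 0) 0 else Inf
  if (x[["oacetyl"]] > cap)
    stop("oacetyl count ", x[["oacetyl"]], " exceeds cap of ",
         if (is.finite(oacetyl_cap)) oacetyl_cap else "any number",
         " per sialic acid (", n_sa, " sialic acids)")
  structure(x, class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) {
  lab <- c(neuac = "NeuAc", neugc = "NeuGc", kdn = "KDN", hex = "Hex",
           hexnac = "HexNAc", dhex = "dHex", oacetyl = "OAc")
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste0(lab[names(nz)], unclass(nz), collapse = "")
}

#' Parse a composition string
#'
#' Accepts strings such as `"NeuAc2Hex5HexNAc4"` or
#' `"NeuAc1deoxyHex1Hex10HexNAc6"`; token order is free, absent residues
#' default to zero. `deoxyHex`, `dHex` and `Fuc` are synonyms, as are
#' `OAc`/`Ac` for O-acetyl counts.
#'
#' @param s composition string.
#' @param oacetyl_cap passed to [glycan_composition()].
#' @return a `glycan_composition`.
#' @export
parse_composition <- function(s, oacetyl_cap = 3) {
  stopifnot(is.character(s), length(s) == 1)
  syn <- c(NeuAc = "neuac", NeuGc = "neugc", KDN = "kdn", Hex = "hex",
           HexNAc = "hexnac", HexNAx = "hexnac", dHex = "dhex",
           deoxyHex = "dhex", Fuc = "dhex", OAc = "oacetyl", Ac = "oacetyl")
  pat <- "(NeuAc|NeuGc|KDN|HexNAc|HexNAx|deoxyHex|dHex|Hex|Fuc|OAc|Ac)([0-9]+)"
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1 && nzchar(gsub("\\s", "", s)))
    stop("cannot parse composition string: ", s)
  toks <- regmatches(s, gregexpr(pat, s, perl = TRUE))[[1]]
  if (nchar(paste(toks, collapse = "")) != nchar(gsub("\\s", "", s)))
    stop("unrecognized tokens in composition string: ", s)
  counts <- stats::setNames(rep(0L, length(COMP_KINDS)), COMP_KINDS)
  for (t in toks) {
    kind <- syn[[sub("[0-9]+$", "", t)]]
    counts[kind] <- counts[kind] + as.integer(sub("^[A-Za-z]+", "", t))
  }
  do.call(glycan_composition, c(as.list(counts), list(oacetyl_cap = oacetyl_cap)))
}

#' Test whether a composition can be an N-glycan
#'
#' All N-glycans share the chitobiose-trimannosyl core Hex3HexNAc2, so a
#' plausible N-glycan composition needs `hexnac >= 2` and `hex >= 3`.
#'
#' @param comp a `glycan_composition`.
#' @return logical.
#' @export
is_n_glycan <- function(comp) {
  comp[["hexnac"]] >= 2 && comp[["hex"]] >= 3
}

# componentwise sum of two compositions
comp_add <- function(a, b) {
  do.call(glycan_composition,
          c(as.list(unclass(a) + unclass(b)), list(oacetyl_cap = Inf)))
}

total_residues <- function(comp) {
  sum(unclass(comp)[setdiff(COMP_KINDS, "oacetyl")])
}
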