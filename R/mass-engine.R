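#' Neutral monoisotopic mass of a glycan composition
#'
#' Sums derivatization-specific residue masses and adds the free-reducing
#' end-group constant (+46.04186 Da permethylated, +18.01056 Da native).
#' O-acetyl groups (+42.01057 Da each) are supported for native glycans
#' only: permethylation removes base-labile O-acetylation, so a
#' permethylated composition with `oacetyl > 0` is an error.
#'
#' @param comp a [glycan_composition()] (or composition string).
#' @param derivatization `"permethylated"` or `"native"`.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass(parse_composition("NeuAc2Hex5HexNAc4"), "permethylated")
#' @export
neutral_mass <- function(comp, derivatization = c("permethylated", "native")) {
  derivatization <- match.arg(derivatization)
  comp <- as_composition(comp)
  if (derivatization == "permethylated" && comp[["oacetyl"]] > 0)
    stop("O-acetyl groups are incompatible with permethylation ",
         "(permethylation removes base-labile O-acetylation); ",
         "use derivatization = \"native\"")
  counts <- unclass(comp)[names(COMP_RESIDUE)]
  m <- sum(counts * residue_mass(COMP_RESIDUE, derivatization))
  end <- if (derivatization == "permethylated") END_PERME else MASS_H2O
  m + end + comp[["oacetyl"]] * MASS_OAC
}

as_composition <- function(comp) {
  if (is.character(comp)) comp <- parse_composition(comp, oacetyl_cap = Inf)
  stopifnot(inherits(comp, "glycan_composition"))
  comp
}

#' Elemental formula of a glycan composition
#'
#' @inheritParams neutral_mass
#' @return named integer vector with elements C, H, N, O, Na.
#' @export
elemental_formula <- function(comp,
                              derivatization = c("permethylated", "native")) {
  derivatization <- match.arg(derivatization)
  comp <- as_composition(comp)
  if (derivatization == "permethylated" && comp[["oacetyl"]] > 0)
    stop("O-acetyl groups are incompatible with permethylation")
  tab <- residue_table()
  rownames(tab) <- tab$residue
  counts <- unclass(comp)[names(COMP_RESIDUE)]
  f <- c(C = 0, H = 0, N = 0, O = 0, Na = 0)
  for (kind in names(COMP_RESIDUE)) {
    n <- counts[[kind]]
    if (n == 0) next
    r <- tab[COMP_RESIDUE[[kind]], ]
    add <- c(C = r$C, H = r$H, N = r$N, O = r$O, Na = 0)
    if (derivatization == "permethylated")
      add <- add + c(C = r$sites, H = 2 * r$sites, N = 0, O = 0, Na = 0)
    f <- f + n * add
  }
  end <- if (derivatization == "permethylated")
    c(C = 2, H = 6, N = 0, O = 1, Na = 0) else c(C = 0, H = 2, N = 0, O = 1, Na = 0)
  f <- f + end + comp[["oacetyl"]] * c(C = 2, H = 2, N = 0, O = 1, Na = 0)
  storage.mode(f) <- "integer"
  f
}

formula_mass <- function(formula) {
  stopifnot(all(names(formula) %in% names(ATOM_MASS)))
  sum(formula * ATOM_MASS[names(formula)])
}

# isotope abundance vectors per element, index = extra neutrons + 1
.ISOTOPES <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Na = 1.0
)

# truncated polynomial product
.poly_mul <- function(a, b, depth) {
  out <- numeric(depth + 1)
  for (i in seq_along(a)) {
    jmax <- min(length(b), depth + 2 - i)
    if (jmax >= 1)
      out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + a[i] * b[1:jmax]
  }
  out
}

.poly_pow <- function(p, n, depth) {
  out <- c(1, numeric(depth))
  base <- c(p, numeric(max(0, depth + 1 - length(p))))[1:(depth + 1)]
  while (n > 0) {
    if (n %% 2 == 1) out <- .poly_mul(out, base, depth)
    base <- .poly_mul(base, base, depth)
    n <- n %/% 2
  }
  out
}

#' Isotopologue distribution of an elemental formula
#'
#' Computes relative abundances of the A+k isotopologues (k extra neutrons
#' over monoisotopic) by per-element convolution of the natural isotope
#' abundances, normalized so that the monoisotopic peak has abundance 1.
#' 17O and 18O contribute at k = 1 and k = 2 respectively; fine isotope
#' structure within a nominal k is not resolved, matching ion-trap
#' resolution.
#'
#' @param formula named vector (C, H, N, O, Na) as from
#'   [elemental_formula()].
#' @param depth largest k to report (max 6).
#' @return numeric vector of length `depth + 1`, names `"0"..depth`.
#' @export
isotope_distribution <- function(formula, depth = 6) {
  stopifnot(depth >= 0, depth <= 6)
  p <- c(1, numeric(depth))
  for (el in names(.ISOTOPES)) {
    n <- if (el %in% names(formula)) formula[[el]] else 0
    if (n > 0) p <- .poly_mul(p, .poly_pow(.ISOTOPES[[el]], n, depth), depth)
  }
  if (p[1] <= 0) stop("monoisotopic abundance underflow")
  stats::setNames(p / p[1], 0:depth)
}

#' Ion m/z for a glycan composition
#'
#' Permethylated glycans are observed in positive mode as sodiated species
#' carrying one Na+ per charge; native glycans in negative mode as
#' deprotonated species `[M - zH]z-`. `k` selects the isotopologue
#' (k extra neutrons, spaced 1.00336/z).
#'
#' @inheritParams neutral_mass
#' @param z charge state, 1..4.
#' @param k isotopologue index, 0..6.
#' @param polarity `"+"` or `"-"`; defaults to the mode matching the
#'   derivatization, any other combination is an error.
#' @return m/z (full precision; use [round2()]-style display for the 2
#'   decimals customarily reported).
#' @examples
#' ion_mz("NeuAc2Hex5HexNAc4", z = 2, k = 1)  # 1408.19
#' @export
ion_mz <- function(comp, z, k = 0,
                   derivatization = c("permethylated", "native"),
                   polarity = NULL) {
  derivatization <- match.arg(derivatization)
  stopifnot(z >= 1, z <= 4, k >= 0, k <= 6)
  default_pol <- if (derivatization == "permethylated") "+" else "-"
  if (is.null(polarity)) polarity <- default_pol
  if (polarity != default_pol)
    stop("unsupported polarity/derivatization combination: ", derivatization,
         " glycans are analyzed in ", default_pol, " mode ",
         "(sodiated positive for permethylated, deprotonated negative for native)")
  M <- neutral_mass(comp, derivatization)
  if (polarity == "+") (M + k * MASS_C13C12 + z * MASS_NA) / z
  else                 (M + k * MASS_C13C12 - z * MASS_PROTON) / z
}

#' m/z of the most abundant isotopologue
#'
#' Total-ion-mapping quantification sums the isotope cluster, and peaks are
#' conventionally reported at the cluster's most intense member. This
#' resolves k from the full isotopic distribution (ties toward smaller k)
#' and returns the corresponding m/z.
#'
#' @inheritParams ion_mz
#' @return m/z, with the resolved `k` attached as attribute `"k"`.
#' @examples
#' most_abundant_ion_mz("NeuAc3Hex10HexNAc6", z = 4)  # 1183.82, k = 2
#' @export
most_abundant_ion_mz <- function(comp, z,
                                 derivatization = c("permethylated", "native")) {
  derivatization <- match.arg(derivatization)
  dist <- isotope_distribution(elemental_formula(comp, derivatization))
  k <- unname(which.max(dist)) - 1L
  structure(ion_mz(comp, z = z, k = k, derivatization = derivatization), k = k)
}

#' Sodiated B-type fragment m/z
#'
#' B-ions of permethylated glycans retain the non-reducing side of a
#' glycosidic cleavage. A fragment released by a single B-cleavage is fully
#' methylated; every further cleavage that removed a substituent from this
#' fragment leaves an unmethylated hydroxyl scar (-14.01565 Da each).
#'
#' @param comp composition of the fragment (terminal subtree).
#' @param n_scars number of scars on the fragment (0 for a plain B-ion).
#' @return singly charged sodiated fragment m/z.
#' @examples
#' b_fragment_mz("Hex3HexNAc1")           # 894.43
#' b_fragment_mz("Hex2HexNAc1", n_scars = 1)  # 676.32
#' @export
b_fragment_mz <- function(comp, n_scars = 0) {
  comp <- as_composition(comp)
  if (comp[["oacetyl"]] > 0)
    stop("B-fragment arithmetic is defined for permethylated glycans only")
  counts <- unclass(comp)[names(COMP_RESIDUE)]
  if (sum(counts) == 0) stop("empty fragment composition")
  m <- sum(counts * residue_mass(COMP_RESIDUE, "permethylated")) +
    MASS_CH2 + MASS_NA - n_scars * MASS_CH2
  if (m <= 0) stop("negative fragment mass: too many scars")
  m
}

#' Neutral loss of a terminal residue in MSn
#'
#' When a permethylated glycan ion loses a terminal residue in MSn, the
#' leaving group departs with the glycosidic oxygen's methyl, so the loss
#' equals the permethylated residue mass + 14.01565 Da (and the remaining
#' ion gains one scar).
#'
#' @param residue residue kind (e.g. `"NeuAc"`, `"Hex"`).
#' @param derivatization only `"permethylated"` is modeled.
#' @return neutral-loss mass in Da.
#' @examples
#' neutral_loss("NeuAc")  # 375.19
#' @export
neutral_loss <- function(residue, derivatization = "permethylated") {
  if (!identical(derivatization, "permethylated"))
    stop("sequential neutral losses are modeled for permethylated glycans only")
  residue_mass(residue, "permethylated") + MASS_CH2
}
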