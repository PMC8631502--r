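#' Default composition search bounds
#'
#' Per-residue count ranges searched during assignment. NeuGc and KDN are
#' searched (0-2) even though they are not expected in these sera, so
#' their absence is a result rather than an assumption. O-acetyl variants
#' are searched only in native mode; permethylation erases them.
#'
#' @param mode `"permethylated"` or `"native"`.
#' @return named list of `c(min, max)` integer ranges.
#' @export
default_bounds <- function(mode = c("permethylated", "native")) {
  mode <- match.arg(mode)
  b <- list(neuac = c(0, 6), neugc = c(0, 2), kdn = c(0, 2),
            hex = c(3, 14), hexnac = c(2, 8), dhex = c(0, 3),
            oacetyl = c(0, 0))
  if (mode == "native") b$oacetyl <- c(0, 6)
  b
}

#' Enumerate candidate compositions within bounds
#'
#' @param bounds named list of `c(min, max)` ranges as from
#'   [default_bounds()]; missing kinds default to `c(0, 0)`.
#' @return data.frame with one column per residue kind, exhaustive within
#'   bounds. Errors if the bounds span more than 10^7 candidates.
#' @export
enumerate_compositions <- function(bounds = default_bounds()) {
  full <- stats::setNames(rep(list(c(0, 0)), length(COMP_KINDS)), COMP_KINDS)
  full[names(bounds)] <- bounds
  sizes <- vapply(full, function(r) r[2] - r[1] + 1, numeric(1))
  if (prod(sizes) > 1e7)
    stop("bounds span ", format(prod(sizes), big.mark = ","),
         " candidates (> 1e7); tighten the search ranges")
  grid <- do.call(expand.grid, lapply(full, function(r) seq(r[1], r[2])))
  names(grid) <- COMP_KINDS
  # O-acetyl only on sialic acids, at most 3 per sialic acid
  n_sa <- grid$neuac + grid$neugc + grid$kdn
  grid[grid$oacetyl <= 3 * n_sa, , drop = FALSE]
}

# annotation ranking policy: biosynthetically plausible sialylation first
# (at most a di-SA pair per antenna, antennae = hexnac - 2), then fewest
# rare sialic acids (NeuGc/KDN are searched so their absence is a result,
# but a canonical NeuAc-family explanation is preferred whenever one fits
# the tolerance: ion-trap direct infusion cannot resolve ppm-level margins,
# and NeuAc+Hex <-> NeuGc+dHex is an exact-mass degeneracy), then smallest
# |ppm| error, then parsimony (fewest residues), then smallest isotopologue
# index.
# |error| is compared at the instrument's 0.01 m/z display precision;
# within a bin the margin is not meaningful and parsimony decides.
# k_offset: cluster peaks are reported at the most abundant isotopologue,
# so a candidate matched away from its own distribution maximum is
# demoted -- this breaks near-1 Da count-swap aliases (e.g. 3 NeuAc + 2
# HexNAc vs 6 Hex + 2 dHex + 1.00 Da) that the k-search would otherwise
# admit at a shifted isotopologue.
.rank_candidates <- function(res) {
  order(!res$canonical, !res$plausible, res$rare, res$k_offset,
        round2(abs(res$error_mz)), res$n_residues, res$k,
        abs(res$error_ppm))
}

# canonical serum-N-glycan template check: chitobiose-trimannosyl core, up
# to tetra-antennary (hexnac <= 6), core fucose only (dhex <= 1), at most a
# di-SA pair per antenna, and hexose counts bounded by the antenna
# extensions seen in these sera (up to three Gal per antenna, e.g. the
# sturgeon Gala(Galb)Galb cap) or by Man9 for high-mannose structures.
.canonical_n_glycan <- function(neuac, neugc, kdn, hex, hexnac, dhex) {
  ant <- pmax(0L, hexnac - 2L)
  sia <- neuac + neugc + kdn
  hexnac >= 2 & hex >= 3 & hexnac <= 6 & dhex <= 1 &
    sia <= 2L * ant & hex <= ifelse(ant == 0L, 9L, 3L + 3L * ant)
}

# vectorized most-abundant isotopologue index from element counts:
# coefficient-of-x^k of prod_e (per-atom isotope polynomial)^n_e,
# truncated at k = 4 (relative abundances; normalization irrelevant for
# the argmax)
.argmax_k_vec <- function(nC, nH, nN, nO) {
  r <- function(p) p[-1] / p[1]
  rC <- r(.ISOTOPES$C); rH <- r(.ISOTOPES$H); rN <- r(.ISOTOPES$N)
  rO <- r(.ISOTOPES$O)  # rO[1] = 17O, rO[2] = 18O
  binom_poly <- function(n, rr)
    cbind(1, choose(n, 1) * rr, choose(n, 2) * rr^2,
          choose(n, 3) * rr^3, choose(n, 4) * rr^4)
  # (1 + r17 x + r18 x^2)^n truncated at x^4
  o_poly <- function(n) {
    c0 <- rep(1, length(n))
    c1 <- choose(n, 1) * rO[1]
    c2 <- choose(n, 1) * rO[2] + choose(n, 2) * rO[1]^2
    c3 <- choose(n, 1) * choose(n - 1, 1) * rO[1] * rO[2] +
      choose(n, 3) * rO[1]^3
    c4 <- choose(n, 2) * rO[2]^2 +
      choose(n, 2) * choose(n - 2, 1) * rO[1]^2 * rO[2] +
      choose(n, 4) * rO[1]^4
    cbind(c0, c1, c2, c3, c4)
  }
  conv <- function(a, b) {
    out <- matrix(0, nrow(a), 5)
    for (i in 1:5) for (j in 1:(5 - i + 1))
      out[, i + j - 1] <- out[, i + j - 1] + a[, i] * b[, j]
    out
  }
  p <- conv(conv(binom_poly(nC, rC), binom_poly(nH, rH)),
            conv(binom_poly(nN, rN), o_poly(nO)))
  max.col(p, ties.method = "first") - 1L
}

# composition table with precomputed neutral masses, cached per
# (bounds, derivatization) so repeated spectrum assignment is fast
.mass_cache <- new.env(parent = emptyenv())

composition_mass_table <- function(bounds = default_bounds(),
                                   derivatization = "permethylated") {
  key <- paste(derivatization,
               paste(names(bounds), vapply(bounds, paste, "", collapse = ":"),
                     collapse = ";"))
  hit <- .mass_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- enumerate_compositions(bounds)
  res_mass <- residue_mass(COMP_RESIDUE, derivatization)
  end <- if (derivatization == "permethylated") END_PERME else MASS_H2O
  tab$neutral_mass <- as.matrix(tab[names(COMP_RESIDUE)]) %*% res_mass + end +
    tab$oacetyl * MASS_OAC
  tab$neutral_mass <- as.numeric(tab$neutral_mass)
  tab$n_residues <- rowSums(tab[names(COMP_RESIDUE)])
  rt <- residue_table(); rownames(rt) <- rt$residue
  rt <- rt[COMP_RESIDUE, ]
  perme <- derivatization == "permethylated"
  cnt <- as.matrix(tab[names(COMP_RESIDUE)])
  nC <- cnt %*% (rt$C + if (perme) rt$sites else 0) + 2 * tab$oacetyl +
    if (perme) 2 else 0
  nH <- cnt %*% (rt$H + if (perme) 2 * rt$sites else 0) + 2 * tab$oacetyl +
    if (perme) 6 else 2
  nN <- cnt %*% rt$N
  nO <- cnt %*% rt$O + tab$oacetyl + 1
  tab$argmax_k <- .argmax_k_vec(as.numeric(nC), as.numeric(nH),
                                as.numeric(nN), as.numeric(nO))
  lab <- c(neuac = "NeuAc", neugc = "NeuGc", kdn = "KDN", hex = "Hex",
           hexnac = "HexNAc", dhex = "dHex", oacetyl = "OAc")
  parts <- lapply(COMP_KINDS, function(kind)
    ifelse(tab[[kind]] > 0, paste0(lab[[kind]], tab[[kind]]), ""))
  tab$label <- do.call(paste0, parts)
  tab$label[tab$label == ""] <- "(empty)"
  .mass_cache[[key]] <- tab
  tab
}

#' Assign compositions to an observed peak
#'
#' Searches all compositions within `bounds` and all isotopologue indices
#' `k <= k_max` for matches with `|observed - ion_mz(comp, z, k)| <=
#' tolerance`. Matching is isotopologue-aware because direct-infusion
#' peaks of large glycans are reported at the most abundant (A+1 or A+2)
#' isotope, not the monoisotopic one. Candidates are ranked the way a
#' practised annotator resolves collisions: consistency with the
#' canonical serum N-glycan templates first (up to tetra-antennary, core
#' fucose only, bounded antenna extension), then plausible sialylation
#' (at most a di-SA pair per antenna), then fewest rare sialic acids
#' (NeuGc/KDN are searched, so their absence is a result, but a
#' NeuAc-family explanation within tolerance is preferred), then
#' agreement of the matched isotopologue with the candidate's own most
#' abundant one, then mass error at the instrument's 0.01 m/z display
#' precision, then parsimony (fewest residues), then smaller k. All
#' collisions within tolerance are reported rather than silently
#' dropped; exact-mass degeneracies (NeuAc+Hex = NeuGc+dHex) and
#' near-1 Da count swaps make ties beyond ppm error unavoidable.
#'
#' @param mz observed m/z.
#' @param z charge state.
#' @param tolerance m/z tolerance (default 0.05).
#' @param bounds search bounds, see [default_bounds()].
#' @param k_max largest isotopologue index searched (default 3).
#' @param derivatization `"permethylated"` (sodiated, positive) or
#'   `"native"` (deprotonated, negative).
#' @return data.frame of candidates: `composition`, `k`, `theoretical_mz`,
#'   `error_mz`, `error_ppm`, `n_residues`, `n_glycan` (core-plausibility
#'   flag), best first; zero rows when nothing matches.
#' @examples
#' assign_peak(1408.19, z = 2)[1, "composition"]  # "NeuAc2Hex5HexNAc4"
#' @export
assign_peak <- function(mz, z, tolerance = 0.05, bounds = default_bounds(),
                        k_max = 3, derivatization = "permethylated") {
  tab <- composition_mass_table(bounds, derivatization)
  adduct <- if (derivatization == "permethylated") z * MASS_NA else -z * MASS_PROTON
  hits <- list()
  for (k in 0:k_max) {
    theo <- (tab$neutral_mass + k * MASS_C13C12 + adduct) / z
    err <- mz - theo
    sel <- which(abs(err) <= tolerance)
    if (length(sel)) {
      sia <- tab$neuac[sel] + tab$neugc[sel] + tab$kdn[sel]
      hits[[length(hits) + 1]] <- data.frame(
        composition = tab$label[sel], k = k, theoretical_mz = theo[sel],
        error_mz = err[sel], error_ppm = err[sel] / theo[sel] * 1e6,
        n_residues = tab$n_residues[sel],
        n_glycan = tab$hexnac[sel] >= 2 & tab$hex[sel] >= 3,
        canonical = .canonical_n_glycan(tab$neuac[sel], tab$neugc[sel],
                                        tab$kdn[sel], tab$hex[sel],
                                        tab$hexnac[sel], tab$dhex[sel]),
        plausible = sia <= pmax(0, 2 * (tab$hexnac[sel] - 2)),
        rare = tab$neugc[sel] + tab$kdn[sel],
        k_offset = abs(k - tab$argmax_k[sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(composition = character(), k = integer(),
                      theoretical_mz = numeric(), error_mz = numeric(),
                      error_ppm = numeric(), n_residues = numeric(),
                      n_glycan = logical(), canonical = logical(),
                      plausible = logical(), rare = integer(),
                      k_offset = integer()))
  res <- do.call(rbind, hits)
  res <- res[.rank_candidates(res), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign a whole spectrum to a glycan profile
#'
#' Pipeline: collapse isotope clusters, assign each cluster's most intense
#' peak (using the inferred charge, or trying 1..4 when unknown), sum
#' charge states per composition, apply the 3%-of-base-peak threshold,
#' and normalize retained abundances to 100%.
#'
#' @param peaks peak data.frame (`mz`, `intensity`, optional `charge`).
#' @param tolerance assignment tolerance in m/z (default 0.05).
#' @param bounds composition search bounds.
#' @param k_max isotopologue search depth.
#' @param derivatization analysis mode.
#' @param threshold_fraction intensity threshold as a fraction of the most
#'   intense assigned composition (default 0.03).
#' @param cluster_tolerance tolerance for isotope-cluster collapse.
#' @param standard_mz expected m/z of the co-injected internal standard
#'   (singly charged); the matching cluster is excluded from the profile
#'   and its intensity reported separately. `NULL` to disable.
#' @param require_n_glycan keep only compositions satisfying the
#'   N-glycan core constraint (default TRUE).
#' @return a `glycan_profile`: list with `table` (data.frame
#'   `composition`, `intensity`, `rel_abundance`), `mode`,
#'   `unassigned_fraction`, `standard_intensity`, `audit` (per-cluster
#'   assignment log including collisions).
#' @export
assign_spectrum <- function(peaks, tolerance = 0.05,
                            bounds = default_bounds("permethylated"),
                            k_max = 3, derivatization = "permethylated",
                            threshold_fraction = 0.03,
                            cluster_tolerance = 0.05,
                            standard_mz = NULL,
                            require_n_glycan = TRUE) {
  clusters <- collapse_isotope_clusters(peaks, tolerance = cluster_tolerance)
  standard_intensity <- NA_real_
  if (!is.null(standard_mz) && nrow(clusters)) {
    d <- abs(clusters$mz - standard_mz)
    hit <- which(d <= max(tolerance, 0.1) &
                   (is.na(clusters$charge) | clusters$charge == 1))
    if (length(hit)) {
      hit <- hit[which.min(d[hit])]
      standard_intensity <- clusters$intensity[hit]
      clusters <- clusters[-hit, , drop = FALSE]
    }
  }
  assigned <- list(); audit <- list()
  total_int <- sum(clusters$intensity)
  for (i in seq_len(nrow(clusters))) {
    zs <- if (is.na(clusters$charge[i])) 1:4 else clusters$charge[i]
    cand <- do.call(rbind, lapply(zs, function(z) {
      res <- assign_peak(clusters$mz[i], z, tolerance, bounds, k_max,
                         derivatization)
      if (nrow(res)) cbind(res, z = z) else NULL
    }))
    if (is.null(cand) || !nrow(cand)) next
    if (require_n_glycan) cand <- cand[cand$n_glycan, , drop = FALSE]
    if (!nrow(cand)) next
    cand <- cand[.rank_candidates(cand), , drop = FALSE]
    top <- cand[1, ]
    assigned[[length(assigned) + 1]] <- data.frame(
      composition = top$composition, intensity = clusters$intensity[i],
      mz = clusters$mz[i], z = top$z, k = top$k,
      error_ppm = top$error_ppm, stringsAsFactors = FALSE)
    if (nrow(cand) > 1)
      audit[[length(audit) + 1]] <- data.frame(
        mz = clusters$mz[i], n_candidates = nrow(cand),
        top = top$composition, runner_up = cand$composition[2],
        stringsAsFactors = FALSE)
  }
  assigned <- if (length(assigned)) do.call(rbind, assigned) else
    data.frame(composition = character(), intensity = numeric())
  summed <- sum_charge_states(assigned)
  # threshold against the MS1 base peak (most intense single peak), the
  # per-sample reference the acquisition protocol prescribes
  base_peak <- if (nrow(peaks)) max(peaks$intensity) else 0
  retained <- threshold_filter(summed, threshold_fraction,
                               reference = base_peak)
  if (nrow(retained))
    retained$rel_abundance <- retained$intensity / sum(retained$intensity) * 100
  else retained$rel_abundance <- numeric()
  unassigned <- if (total_int > 0)
    1 - sum(assigned$intensity) / total_int else 0
  glycan_profile(retained, mode = derivatization,
                 unassigned_fraction = unassigned,
                 standard_intensity = standard_intensity,
                 audit = if (length(audit)) do.call(rbind, audit) else NULL)
}

#' Glycan profile container
#'
#' @param table data.frame with `composition`, `intensity`,
#'   `rel_abundance` (and optionally `topology`).
#' @param mode `"permethylated"` or `"native"`.
#' @param species optional species label.
#' @param unassigned_fraction fraction of clustered intensity left
#'   unassigned.
#' @param standard_intensity internal-standard cluster intensity (NA when
#'   not located).
#' @param audit assignment-collision log.
#' @return object of class `glycan_profile`.
#' @export
glycan_profile <- function(table, mode = "permethylated", species = NA_character_,
                           unassigned_fraction = NA_real_,
                           standard_intensity = NA_real_, audit = NULL) {
  rownames(table) <- NULL
  if (nrow(table) && abs(sum(table$rel_abundance) - 100) > 0.01)
    stop("relative abundances must sum to 100")
  structure(list(table = table, mode = mode, species = species,
                 unassigned_fraction = unassigned_fraction,
                 standard_intensity = standard_intensity, audit = audit),
            class = "glycan_profile")
}

#' @export
print.glycan_profile <- function(x, ...) {
  cat("<glycan_profile>", if (!is.na(x$species)) x$species else "",
      sprintf("(%s mode, %d glycans)\n", x$mode, nrow(x$table)))
  if (nrow(x$table))
    print(utils::head(x$table[order(-x$table$rel_abundance), ], 10),
          row.names = FALSE)
  invisible(x)
}
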