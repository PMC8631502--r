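# Independent closed-form isotopologue oracle: sums binomial/multinomial
# probabilities over explicit heavy-isotope counts (i 13C, j 2H, l 15N,
# m 17O, n 18O with i+j+l+m+2n = k), normalized to the monoisotopic term.
# Deliberately shares no code with the package's convolution engine.
iso_oracle <- function(formula, depth = 6) {
  ab <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
             N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205))
  n <- function(el) if (el %in% names(formula)) formula[[el]] else 0
  dbin <- function(x, size, p) {
    if (x > size) return(0)
    choose(size, x) * p^x * (1 - p)^(size - x)
  }
  dtri <- function(m17, n18, size, p) {
    if (m17 + n18 > size) return(0)
    factorial(size) / (factorial(m17) * factorial(n18) *
                         factorial(size - m17 - n18)) *
      p[2]^m17 * p[3]^n18 * p[1]^(size - m17 - n18)
  }
  pk <- numeric(depth + 1)
  for (k in 0:depth) {
    tot <- 0
    for (i in 0:k) for (j in 0:(k - i)) for (l in 0:(k - i - j))
      for (n18 in 0:((k - i - j - l) %/% 2)) {
        m17 <- k - i - j - l - 2 * n18
        tot <- tot + dbin(i, n("C"), ab$C[2]) * dbin(j, n("H"), ab$H[2]) *
          dbin(l, n("N"), ab$N[2]) * dtri(m17, n18, n("O"), ab$O)
      }
    pk[k + 1] <- tot
  }
  pk / pk[1]
}

# round-half-up to 2 decimals, as instrument software displays m/z
r2 <- function(x) floor(x * 100 + 0.5) / 100

# random glycan topology for fuzz tests: a rooted tree of random residues,
# depth-limited; returns a topology string
random_topology_string <- function(max_depth = 6) {
  residues <- c("Gal", "Man", "Glc", "GlcNAc", "GalNAc", "Fuc",
                "NeuAc", "NeuGc", "KDN", "Hex", "HexNAc")
  anomers <- c("a", "b", "?")
  build <- function(depth) {
    res <- sample(residues, 1)
    link <- paste0("(", sample(anomers, 1), "-)")
    n_kids <- if (depth >= max_depth) 0 else sample(0:2, 1,
                                                    prob = c(0.5, 0.35, 0.15))
    if (n_kids == 0) return(list(str = res, link = link))
    kids <- lapply(seq_len(n_kids), function(i) build(depth + 1))
    inline <- paste0(kids[[1]]$str, kids[[1]]$link)
    branches <- if (n_kids > 1)
      paste0("[", kids[[2]]$str, kids[[2]]$link, "]") else ""
    list(str = paste0(inline, branches, res), link = link)
  }
  build(1)$str
}

# noise-free generator settings
no_noise <- list(mz_sigma = 0, intensity_cv = 0, spurious_rate = 0)

dp4_mz <- function() ion_mz(glycan_composition(hex = 4), z = 1, k = 0)

# canonical NeuAc-family serum N-glycan sample space used by recovery
# fuzz tests (see the methods vignette for why unrestricted composition
# space is ill-posed: exact mass degeneracies)
canonical_space <- function(derivatization = "permethylated") {
  tab <- glycoMS:::composition_mass_table(default_bounds(), derivatization)
  ant <- pmax(0, tab$hexnac - 2)
  ok <- tab$neugc == 0 & tab$kdn == 0 & tab$hexnac >= 2 & tab$hexnac <= 6 &
    tab$hex >= 3 & tab$dhex <= 1 & tab$neuac <= 2 * ant &
    tab$hex <= ifelse(ant == 0, 9, 3 + 3 * ant)
  tab[ok, , drop = FALSE]
}
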