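test_that("neutral mass reproduces derivatization arithmetic", {
  expect_equal(neutral_mass("NeuAc2Hex5HexNAc4", "permethylated"),
               2769.3934, tolerance = 1e-3)
  expect_equal(neutral_mass(glycan_composition(), "permethylated"),
               46.04186, tolerance = 1e-4)
  # native with one O-acetyl: residue sums + H2O + 42.01057
  expect_equal(neutral_mass(parse_composition("NeuAc2Hex5HexNAc4Ac1"),
                            "native"),
               2264.7936, tolerance = 1e-3)
  expect_error(neutral_mass(parse_composition("NeuAc2Hex5HexNAc4Ac1"),
                            "permethylated"), "permethylat")
})

test_that("elemental formulas agree with masses and worked examples", {
  f <- elemental_formula(glycan_composition(hex = 1), "permethylated")
  expect_equal(unname(f[c("C", "H", "O")]), c(11L, 22L, 6L))
  expect_equal(unname(elemental_formula(glycan_composition(), "native")),
               c(0L, 2L, 0L, 1L, 0L))
  f2 <- elemental_formula("NeuAc1dHex1Hex10HexNAc6", "permethylated")
  expect_equal(f2[["C"]], 182L)
  set.seed(31)
  for (i in 1:20) {
    comp <- glycan_composition(neuac = sample(0:3, 1), hex = sample(0:9, 1),
                               hexnac = sample(0:6, 1), dhex = sample(0:2, 1))
    for (d in c("permethylated", "native"))
      expect_lt(abs(glycoMS:::formula_mass(elemental_formula(comp, d)) -
                      neutral_mass(comp, d)), 1e-3)
  }
})

test_that("isotope distributions match the closed-form oracle", {
  expect_equal(isotope_distribution(c(C = 0, H = 0, N = 0, O = 0), 0),
               c("0" = 1))
  d <- isotope_distribution(c(C = 2, H = 6, N = 0, O = 1), 2)
  expect_lt(abs(unname(d[2]) - 0.0226), 5e-4)
  # oracle equivalence on fuzzed small formulas (<= 30 atoms)
  set.seed(41)
  for (i in 1:150) {
    repeat {
      f <- c(C = sample(0:15, 1), H = sample(0:15, 1),
             N = sample(0:5, 1), O = sample(0:8, 1))
      if (sum(f) <= 30 && sum(f) > 0) break
    }
    expect_equal(unname(isotope_distribution(f, 5)),
                 unname(iso_oracle(f, 5)), tolerance = 1e-10,
                 label = paste(names(f), f, collapse = " "))
  }
})

test_that("isotope argmax matches observed reporting conventions", {
  d <- isotope_distribution(
    elemental_formula("NeuAc2Hex5HexNAc4", "permethylated"))
  expect_equal(unname(which.max(d)) - 1L, 1L)
  expect_equal(attr(most_abundant_ion_mz(glycan_composition(hex = 1), 1), "k"),
               0L)
})

test_that("sodiated/deprotonated ion m/z reproduces printed peaks", {
  expect_equal(r2(ion_mz("NeuAc2Hex5HexNAc4", z = 2, k = 1)), 1408.19)
  expect_equal(r2(ion_mz("NeuAc2Hex7HexNAc4", z = 3, k = 1)), 1082.52)
  expect_equal(r2(ion_mz(glycan_composition(), z = 1, k = 0)), 69.03)
  expect_error(ion_mz("Hex5HexNAc2", z = 1, polarity = "-"), "polarity")
  expect_error(ion_mz("Hex5HexNAc2", z = 1, derivatization = "native",
                      polarity = "+"), "polarity")
})

test_that("most-abundant-isotopologue m/z resolves k from the distribution", {
  m <- most_abundant_ion_mz("NeuAc3Hex10HexNAc6", z = 4)
  expect_equal(as.numeric(r2(m)), 1183.82)
  expect_equal(attr(m, "k"), 2L)
  m2 <- most_abundant_ion_mz("NeuAc1Hex7HexNAc4", z = 3)
  expect_equal(as.numeric(r2(m2)), 962.13)
  expect_equal(attr(m2, "k"), 1L)
})

test_that("charge states are consistent for fixed composition and k", {
  for (comp in c("NeuAc2Hex5HexNAc4", "Hex5HexNAc2")) {
    neutral <- vapply(1:4, function(z)
      ion_mz(comp, z = z, k = 2) * z - z * 22.98977 - 2 * 1.00336, numeric(1))
    expect_lt(max(neutral) - min(neutral), 1e-6)
  }
})

test_that("B-fragment and neutral-loss arithmetic match MSn observations", {
  expect_equal(r2(b_fragment_mz("Hex3HexNAc1")), 894.43)
  expect_equal(r2(b_fragment_mz("Hex2HexNAc1")), 690.33)
  expect_equal(r2(b_fragment_mz("Hex2HexNAc1", n_scars = 1)), 676.32)
  expect_equal(r2(neutral_loss("NeuAc")), 375.19)
  expect_equal(r2(neutral_loss("Hex")), 218.12)
  # per-charge shift at 3+ for a NeuAc loss explains 1388.02 -> ~1263
  expect_equal(r2(neutral_loss("NeuAc") / 3), 125.06)
  expect_error(b_fragment_mz(glycan_composition()), "empty")
  expect_error(neutral_loss("Xyl"), "unknown residue")
})

test_that("neutral mass is strictly monotone in every residue count", {
  base <- glycan_composition(neuac = 1, hex = 4, hexnac = 3, dhex = 1)
  for (kind in c("neuac", "neugc", "kdn", "hex", "hexnac", "dhex")) {
    v <- unclass(base)
    v[[kind]] <- v[[kind]] + 1L
    bumped <- do.call(glycan_composition, as.list(v))
    for (d in c("permethylated", "native"))
      expect_gt(neutral_mass(bumped, d), neutral_mass(base, d))
  }
  # removing one Hex lowers permethylated mass by exactly one residue unit
  minus <- glycan_composition(neuac = 1, hex = 3, hexnac = 3, dhex = 1)
  expect_equal(neutral_mass(base, "permethylated") -
                 neutral_mass(minus, "permethylated"), 204.09977,
               tolerance = 1e-9)
})

test_that("constants table exports losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_constants_csv(path)
  tab <- read.csv(path)
  expect_equal(tab$mass[tab$residue == "NeuAc"], 291.09542)
  expect_equal(tab$mass[tab$residue == "(13C-12C)"], 1.00336)
})
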