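test_that("the five presets encode the reported prevalences", {
  pr <- species_presets()
  expect_named(pr, c("atlantic_salmon", "arctic_char", "shortnose_sturgeon",
                     "atlantic_sturgeon", "channel_catfish"))
  for (p in pr) {
    expect_equal(sum(p$glycans$abundance), 100, tolerance = 1e-9)
    for (s in p$glycans$topology)
      expect_true(is_n_glycan(composition_of(parse_glycan(s))))
  }
  disa_pct <- function(p) {
    prof <- preset_profile(p)
    f <- feature_prevalence(prof)
    f$value[f$feature == "disa_pct"]
  }
  expect_equal(disa_pct(pr$arctic_char), 5)
  expect_equal(disa_pct(pr$atlantic_salmon), 2)
  tetra <- pr$atlantic_salmon$glycans
  expect_equal(tetra$abundance[grepl("tetrasialylated", tetra$name)], 0.38)
  expect_equal(pr$arctic_char$glycans$abundance[
    grepl("tetrasialylated", pr$arctic_char$glycans$name)], 0.12)
  # catfish: top glycan NeuAc2Hex7HexNAc4, and no NeuAc3Hex5HexNAc4
  cf <- pr$channel_catfish$glycans
  top <- cf$topology[which.max(cf$abundance)]
  expect_equal(format(composition_of(parse_glycan(top))), "NeuAc2Hex7HexNAc4")
  comps <- vapply(cf$topology, function(s)
    format(composition_of(parse_glycan(s))), "")
  expect_false("NeuAc3Hex5HexNAc4" %in% comps)
  # triantennary trisialylated: present in salmon, absent from char
  salmon_comps <- vapply(pr$atlantic_salmon$glycans$topology, function(s)
    format(composition_of(parse_glycan(s))), "")
  char_comps <- vapply(pr$arctic_char$glycans$topology, function(s)
    format(composition_of(parse_glycan(s))), "")
  expect_true("NeuAc3Hex6HexNAc5" %in% salmon_comps)
  expect_false("NeuAc3Hex6HexNAc5" %in% char_comps)
  # core fucose prevalence: shortnose >40%, Atlantic sturgeon 2%
  fuc_pct <- function(p) {
    f <- feature_prevalence(preset_profile(p))
    f$value[f$feature == "core_fucose_pct"]
  }
  expect_gt(fuc_pct(pr$shortnose_sturgeon), 40)
  expect_equal(fuc_pct(pr$atlantic_sturgeon), 2)
})

test_that("the shipped preset JSON matches the built-in library", {
  path <- system.file("extdata", "species_presets.json", package = "glycoMS")
  expect_true(nzchar(path))
  back <- read_presets_json(path)
  built <- species_presets()
  expect_identical(names(back), names(built))
  for (nm in names(built)) {
    expect_identical(back[[nm]]$glycans, built[[nm]]$glycans)
    expect_equal(back[[nm]]$oacetyl_dist, built[[nm]]$oacetyl_dist)
    expect_equal(back[[nm]]$charge_weights, built[[nm]]$charge_weights)
  }
})

test_that("simulation is deterministic and seed-sensitive", {
  pr <- species_presets()$atlantic_salmon
  a <- generate_ms1(pr, "permethylated", seed = 5)
  b <- generate_ms1(pr, "permethylated", seed = 5)
  expect_identical(a, b)
  c <- generate_ms1(pr, "permethylated", seed = 6)
  expect_false(identical(a$peaks, c$peaks))
  expect_error(generate_ms1(pr, "permethylated"), "seed")
})

test_that("noise-free peaks sit exactly on theoretical m/z", {
  pr <- species_presets()$atlantic_salmon
  sim <- generate_ms1(pr, "permethylated", seed = 1, noise = no_noise)
  comp <- parse_composition("NeuAc2Hex5HexNAc4")
  theo <- vapply(0:4, function(k) ion_mz(comp, z = 2, k = k), numeric(1))
  for (m in theo)
    expect_lt(min(abs(sim$peaks$mz - m)), 1e-6)
})

test_that("salmon simulation shows the 1408.19 (2+) cluster apex", {
  pr <- species_presets()$atlantic_salmon
  sim <- generate_ms1(pr, "permethylated", seed = 1)
  cl <- collapse_isotope_clusters(sim$peaks)
  near <- cl[abs(cl$mz - 1408.19) < 0.05, ]
  expect_gte(nrow(near), 1)
  expect_equal(near$charge[1], 2L)
})

test_that("native simulation spaces O-acetyl ladders by 42.01057/z", {
  pr <- species_presets()$atlantic_salmon
  sim <- generate_ms1(pr, "native", seed = 4, noise = no_noise)
  base <- parse_composition("NeuAc2Hex5HexNAc4")
  for (z in 2:3) {
    mz0 <- ion_mz(base, z = z, derivatization = "native")
    have <- vapply(0:3, function(n)
      min(abs(sim$peaks$mz - (mz0 + n * 42.01057 / z))), numeric(1))
    expect_true(all(have < 1e-6))
  }
})

test_that("MSn simulation honours dropout and determinism", {
  epi <- "NeuAc(a-)[Gal(b-)]Gal(b-)GlcNAc"
  full <- generate_msn(epi, stage = 3, seed = 1)
  expect_gt(nrow(full$fragments), 0)
  none <- generate_msn(epi, stage = 3, seed = 1, dropout = 1)
  expect_equal(nrow(none$fragments), 0)
  expect_identical(generate_msn(epi, stage = 4, seed = 9),
                   generate_msn(epi, stage = 4, seed = 9))
})

test_that("digest series shift compositions exactly as the enzymes allow", {
  pr <- species_presets()
  states <- generate_digest_series(
    pr$shortnose_sturgeon, list(alpha_galactosidase(), beta_galactosidase()),
    seed = 5, noise = no_noise)
  expect_length(states, 3)
  comp_of <- function(state, pattern) {
    g <- state$truth$glycans
    g$composition[grepl(pattern, g$glycan)][1]
  }
  # the tetraantennary sturgeon glycan: -2 Hex after alpha (the 1388.02
  # (3+) -> 1251.61 (3+) shift), then -4 more after beta
  expect_equal(parse_composition(comp_of(states[[1]], "tetraantennary")),
               parse_composition("NeuAc1deoxyHex1Hex10HexNAc6"))
  expect_equal(parse_composition(comp_of(states[[2]], "tetraantennary")),
               parse_composition("NeuAc1deoxyHex1Hex8HexNAc6"))
  expect_equal(parse_composition(comp_of(states[[3]], "tetraantennary")),
               parse_composition("NeuAc1deoxyHex1Hex4HexNAc6"))
  # empty enzyme list: before equals after
  same <- generate_digest_series(pr$channel_catfish, list(), seed = 2,
                                 noise = no_noise)
  expect_length(same, 1)
  # beta alone leaves catfish sialylated epitopes unshifted
  beta <- generate_digest_series(pr$channel_catfish,
                                 list(beta_galactosidase()), seed = 2,
                                 noise = no_noise)
  g0 <- beta[[1]]$truth$glycans
  g1 <- beta[[2]]$truth$glycans
  sialylated_top <- grepl("two NeuAc-branched", g0$glycan)
  expect_equal(g1$composition[sialylated_top], g0$composition[sialylated_top])
  gg <- grepl("two GalbGalb", g0$glycan)
  expect_equal(parse_composition(g1$composition[gg])[["hex"]],
               parse_composition(g0$composition[gg])[["hex"]] - 4L)
})

test_that("ground truth labels which abundances are synthetic assumptions", {
  pr <- species_presets()$atlantic_salmon
  sim <- generate_ms1(pr, "permethylated", seed = 1)
  expect_type(sim$truth$synthetic_abundances, "logical")
  expect_true(any(sim$truth$synthetic_abundances))
  expect_false(all(sim$truth$synthetic_abundances))
  expect_equal(sim$truth$seed, 1)
  expect_equal(sim$truth$preset, "atlantic_salmon")
})
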