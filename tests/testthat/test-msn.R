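catfish_epi <- "NeuAc(a-)[Gal(b-)]Gal(b-)GlcNAc"

test_that("fragment prediction reproduces the catfish signature ions", {
  pred <- predict_fragments(parse_glycan(catfish_epi))
  mz <- round(pred$mz, 1)
  expect_true(1051.5 %in% mz)  # intact sialylated tetrasaccharide B-ion
  expect_true(676.3 %in% mz)   # NeuAc loss with one scar
  expect_equal(nrow(predict_fragments(parse_glycan("GlcNAc"))), 0)
})

test_that("branched and linear trihexosyl epitopes predict different sets", {
  br <- predict_fragments(parse_glycan("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc"))
  li <- predict_fragments(parse_glycan("Gal(a-)Gal(b-)Gal(b-)GlcNAc"))
  expect_false(setequal(round(br$mz, 2), round(li$mz, 2)))
  # the linear form has an unscarred Hex2 B-ion the branched form lacks
  expect_true(any(abs(li$mz - 445.21) < 0.05 & li$scars == 0))
  expect_false(any(abs(br$mz - 445.21) < 0.05 & br$scars == 0))
})

test_that("B-ion plus complementary residue mass reconstructs the precursor", {
  # for any unscarred B-ion of a proper subtree S of W:
  # B(W) - B(S) = sum of permethylated residue masses of W \ S
  kinds <- c(neuac = "NeuAc", neugc = "NeuGc", kdn = "KDN",
             hex = "Hex", hexnac = "HexNAc", dhex = "dHex")
  for (s in c(n_glycan_string(c("sial", "gg")),
              n_glycan_string(c("disa", "sturgeon"), core_fucose = TRUE))) {
    t <- parse_glycan(s)
    prec_b <- b_fragment_mz(composition_of(t))
    pred <- predict_fragments(t, max_losses = 0)
    pred <- pred[pred$scars == 0, ]
    expect_gt(nrow(pred), 0)
    for (i in seq_len(nrow(pred))) {
      rest <- unclass(composition_of(t)) -
        unclass(parse_composition(pred$composition[i]))
      complement <- sum(rest[names(kinds)] *
                          glycoMS:::residue_mass(kinds, "permethylated"))
      expect_equal(prec_b - pred$mz[i], complement, tolerance = 1e-6)
    }
  }
})

test_that("topology scoring ranks the generating structure first", {
  br <- "Gal(a-)[Gal(b-)]Gal(b-)GlcNAc"
  li <- "Gal(a-)Gal(b-)Gal(b-)GlcNAc"
  obs <- predict_fragments(parse_glycan(br))$mz
  sc <- score_topologies(list(branched = br, linear = li), obs)
  expect_equal(sc$candidate[1], "branched")
  expect_false(attr(sc, "all_zero"))
  disc <- attr(sc, "discriminating")
  expect_gt(length(disc$top_only) + length(disc$runner_up_only), 0)
  # a perfect observation leaves nothing unexplained for its own candidate
  sc2 <- score_topologies(list(a = br, b = li),
                          predict_fragments(parse_glycan(li))$mz)
  expect_equal(sc2$candidate[1], "b")
  expect_equal(sc2$unexplained[sc2$candidate == "b"], 0)
})

test_that("di-SA candidates win on the NeuAc2 B-ion evidence", {
  # NeuAc3Hex5HexNAc4 admits a di-SA biantennary and (hypothetically) a
  # fully sialylated triantennary reading; the NeuAc-NeuAc B-ion at 759.35
  # separates them
  disa_ant <- n_glycan_string(c("disa", "sial"))
  two_single <- n_glycan_string(c("sial", "sial", "sial"))
  expect_equal(round(b_fragment_mz("NeuAc2"), 2), 759.35)
  obs <- predict_fragments(parse_glycan(disa_ant), max_losses = 1)$mz
  expect_true(any(abs(obs - 759.35) < 0.05))
  sc <- score_topologies(list(disa = disa_ant, singly = two_single), obs,
                         max_losses = 1)
  expect_equal(sc$candidate[1], "disa")
})

test_that("scoring property: generating topology never loses on clean data", {
  set.seed(71)
  pool <- c(n_glycan_string(c("sial", "sial")),
            n_glycan_string(c("disa", "sial")),
            n_glycan_string(c("catfish", "gg")),
            n_glycan_string(c("sturgeon", "sturgeon")),
            "Gal(a-)[Gal(b-)]Gal(b-)GlcNAc",
            "NeuAc(a-)[Gal(b-)]Gal(b-)GlcNAc")
  for (g in seq_along(pool)) {
    obs <- predict_fragments(parse_glycan(pool[g]), max_losses = 2)$mz
    sc <- score_topologies(as.list(pool), obs, max_losses = 2)
    top_score <- sc$score[sc$candidate == paste0("candidate", g)]
    expect_gte(top_score, max(sc$score) - 1e-9)
  }
})

test_that("di-SA detection follows the antenna heuristic", {
  expect_equal(detect_disa("NeuAc3Hex5HexNAc4"), 1L)
  expect_equal(detect_disa("NeuAc2Hex5HexNAc4"), 0L)
  expect_equal(detect_disa("NeuAc4Hex6HexNAc5"), 1L)
  hm <- detect_disa("Hex5HexNAc2")
  expect_true(is.na(hm))
  expect_match(attr(hm, "reason"), "not applicable")
})

test_that("MGF files round-trip spectra with stage metadata", {
  sp1 <- generate_msn(catfish_epi, stage = 4, seed = 1)
  sp2 <- generate_msn("Gal(a-)[Gal(b-)]Gal(b-)GlcNAc", stage = 3, seed = 2,
                      dropout = 0.3)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(sp1, sp2), path)
  back <- read_mgf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$stage, 4L)
  expect_equal(back[[1]]$fragments$mz, sp1$fragments$mz, tolerance = 1e-5)
  expect_equal(back[[2]]$charge, 1L)
  expect_equal(nrow(back[[2]]$fragments), nrow(sp2$fragments))
  writeLines(c("BEGIN IONS", "TITLE=x", "1 2"), path)
  expect_error(read_mgf(path), "unterminated")
})
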