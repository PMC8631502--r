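test_that("TIM windows step and cover as configured", {
  w <- tim_windows(600, 2000, 2.8, 0.8)
  expect_equal(w$start[1], 600)
  expect_equal(w$end[1], 602.8)
  expect_equal(w$start[2], 602)
  expect_equal(nrow(w), 700)
  expect_gte(w$end[nrow(w)], 2000)
  expect_equal(nrow(tim_windows(600, 602.8, 2.8, 0.8)), 1)
  expect_error(tim_windows(600, 2000, 0.8, 2.8), "exceed")
  # coverage: every m/z in range lies in >= 1 window; overlaps in exactly 2
  probes <- seq(600, 2000, by = 0.37)
  hits <- vapply(probes, function(m) sum(m >= w$start & m <= w$end),
                 numeric(1))
  expect_true(all(hits >= 1))
  expect_true(all(hits <= 2))
  in_overlap <- vapply(probes, function(m)
    any(m >= w$start[-1] & m <= w$end[-nrow(w)]), logical(1))
  expect_true(all(hits[in_overlap] == 2))
})

test_that("TIM profile sums peaks per window including overlap regions", {
  peaks <- data.frame(mz = c(600.5, 602.4, 610.0), intensity = c(10, 20, 5))
  prof <- tim_profile(peaks, tim_windows(600, 612, 2.8, 0.8))
  expect_equal(prof$intensity[1], 30)   # 600.0-602.8 gets both
  expect_equal(prof$intensity[2], 20)   # 602.0-604.8 gets the overlap peak
  # the 610.0 peak sits in the overlap of two windows and counts in both
  expect_equal(sum(prof$intensity >= 5), 4)
})

test_that("isotope clusters collapse with correct charge and summed intensity", {
  comp <- parse_composition("NeuAc2Hex5HexNAc4")
  dist <- isotope_distribution(elemental_formula(comp, "permethylated"), 4)
  mk_cluster <- function(z, scale) data.frame(
    mz = vapply(0:4, function(k) ion_mz(comp, z = z, k = k), numeric(1)),
    intensity = scale * as.numeric(dist / sum(dist)))
  p2 <- mk_cluster(2, 100)
  out <- collapse_isotope_clusters(p2)
  expect_equal(nrow(out), 1)
  expect_equal(out$charge, 2L)
  expect_equal(out$intensity, 100)
  expect_equal(out$mz, p2$mz[which.max(p2$intensity)])
  # single peak passes through
  single <- collapse_isotope_clusters(data.frame(mz = 900.1, intensity = 5))
  expect_equal(nrow(single), 1)
  expect_true(is.na(single$charge))
  # interleaved 2+ and 3+ clusters of different glycans resolve separately
  comp3 <- parse_composition("NeuAc3Hex6HexNAc5")
  p3 <- data.frame(
    mz = vapply(0:4, function(k) ion_mz(comp3, z = 3, k = k), numeric(1)),
    intensity = 60 * as.numeric(dist / sum(dist)))
  both <- collapse_isotope_clusters(rbind(p2, p3))
  expect_equal(nrow(both), 2)
  expect_setequal(both$charge, c(2L, 3L))
  expect_equal(sum(both$intensity), 160)
})

test_that("charge-state summation and thresholding behave as specified", {
  assigned <- data.frame(
    composition = c("NeuAc2Hex5HexNAc4", "NeuAc2Hex5HexNAc4", "Hex5HexNAc2"),
    intensity = c(70, 30, 8))
  summed <- sum_charge_states(assigned)
  expect_equal(summed$intensity[summed$composition == "NeuAc2Hex5HexNAc4"],
               100)
  expect_equal(nrow(sum_charge_states(assigned[0, ])), 0)
  kept <- threshold_filter(c(A = 100, B = 5, C = 2))
  expect_named(kept, c("A", "B"))
  expect_length(threshold_filter(c(A = 7)), 1)
  expect_length(threshold_filter(rep(4, 5)), 5)
  expect_length(threshold_filter(numeric()), 0)
  # idempotence
  v <- c(100, 40, 3.1, 2.9, 0.5)
  expect_equal(threshold_filter(threshold_filter(v)), threshold_filter(v))
})

test_that("collapse plus charge-summing conserves grouped intensity", {
  set.seed(53)
  comp <- parse_composition("NeuAc1Hex7HexNAc4")
  dist <- isotope_distribution(elemental_formula(comp, "permethylated"), 4)
  peaks <- do.call(rbind, lapply(2:3, function(z) data.frame(
    mz = vapply(0:4, function(k) ion_mz(comp, z = z, k = k), numeric(1)),
    intensity = runif(1, 50, 150) * as.numeric(dist / sum(dist)))))
  total <- sum(peaks$intensity)
  cl <- collapse_isotope_clusters(peaks)
  expect_equal(sum(cl$intensity), total, tolerance = 1e-12)
})

test_that("internal-standard quantification follows the spike arithmetic", {
  expect_equal(quantify_vs_standard(c(a = 500), 500, 50, 0.05),
               c(a = 1000))
  expect_equal(unname(quantify_vs_standard(c(0), 500, 50, 0.05)), 0)
  expect_error(quantify_vs_standard(c(10), 0, 50, 0.05), "relative-only")
  expect_error(quantify_vs_standard(c(10), 500, 50, 1.5), "spike_fraction")
  # generator round trip: recovered amounts equal the simulated amounts
  pr <- species_presets()$channel_catfish
  sim <- generate_ms1(pr, "permethylated", seed = 3, noise = no_noise)
  prof <- assign_spectrum(sim$peaks, standard_mz = dp4_mz())
  amounts <- quantify_vs_standard(prof$table, prof$standard_intensity,
                                  pr$standard$amount, pr$standard$fraction)
  truth <- tapply(sim$truth$glycans$amount, sim$truth$glycans$composition, sum)
  expect_equal(unname(amounts[names(truth)]), unname(as.numeric(truth)),
               tolerance = 1e-6)
})

test_that("peak-list CSV i/o validates input", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaks(data.frame(mz = c(900.2, 1000.5), intensity = c(10, 3)), path)
  back <- read_peaks(path)
  expect_equal(back$mz, c(900.2, 1000.5))
  writeLines("mz,intensity\n-5,3", path)
  expect_error(read_peaks(path), "line")
  writeLines("a,b\n1,2", path)
  expect_error(read_peaks(path), "mz,intensity")
})
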