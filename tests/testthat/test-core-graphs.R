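test_that("mass scaling rounds half-up onto integer ticks", {
  expect_identical(scale_and_round(0, 1), 0L)
  expect_identical(scale_and_round(0, 1000), 0L)
  expect_identical(scale_and_round(87.03203, 1), 87L)
  expect_identical(scale_and_round(79.96633, 100), 7997L)
  expect_identical(scale_and_round(0.005, 100), 1L) # ties round up
  expect_error(scale_and_round(-1, 1), "non-negative")
  expect_error(scale_and_round(1, 0), "scale")
})

test_that("the PMG has one black edge per residue and red edges per target", {
  g <- build_pmg("SYLDR", list(mod_phospho(c("S", "Y"))), scale = 1)
  expect_equal(g$n + 1L, 6L)
  expect_length(g$black, 5L)
  expect_equal(nrow(g$red), 2L)

  g2 <- build_pmg("G", scale = 1)
  expect_equal(g2$n + 1L, 2L)
  expect_equal(nrow(g2$red), 0L)

  g3 <- build_pmg("SYSDMK", list(mod_phospho(), mod_oxidation()), scale = 1)
  expect_equal(g3$n + 1L, 7L)
  expect_length(g3$black, 6L)
  expect_equal(nrow(g3$red), 4L) # S, Y, S phospho + M oxidation

  expect_error(build_pmg("SXB"), "unknown residue")
})

test_that("the SMG carries virtual endpoints and merges duplicate masses", {
  h <- example_smg()
  expect_equal(h$m, 8L)
  expect_equal(h$peaks$mass[1], 0L)
  expect_equal(h$peaks$intensity[1], 0)
  expect_equal(h$peaks$mass[9], 791L)
  expect_identical(h$peaks$mass, sort(h$peaks$mass))
  expect_equal(h$terminal_mass, scale_and_round(example_precursor() - 18.0105646863, 1))

  # empty spectrum: origin + virtual terminal only
  h0 <- build_smg(tibble::tibble(mass = numeric(), intensity = numeric()),
                  precursor_mass = 500 + 18.010565, scale = 1)
  expect_equal(h0$m, 1L)
  expect_equal(h0$peaks$mass, c(0L, 500L))
  expect_false(h0$terminal_observed)
  expect_equal(h0$peaks$intensity[2], 0)

  # duplicate scaled masses keep the maximum intensity
  hd <- build_smg(tibble::tibble(mass = c(87.001, 87.004, 200),
                                 intensity = c(5, 9, 1)),
                  precursor_mass = 500 + 18.010565, scale = 1)
  expect_equal(hd$peaks$intensity[hd$peaks$mass == 87L], 9)
})

test_that("m/z input space maps b and y interpretations to prefix masses", {
  # b1 ion of Ser at charge 1: 87.032 + proton
  h <- build_smg(tibble::tibble(mass = 88.039, intensity = 10),
                 precursor_mass = 791 + 18.010565, scale = 1,
                 input_space = "mz")
  expect_true(87L %in% h$peaks$mass) # b interpretation
  # y interpretation: (M - H2O) - (frag - H2O) = 791 - 69.02 -> 722
  expect_true(722L %in% h$peaks$mass)
})

test_that("path mass sets match exhaustive enumeration", {
  # toy graph: two positions, each with edge masses {1, 2}
  toy <- pmg_from_edges(black = c(1L, 1L),
                        red = data.frame(pos = c(1, 2), mass = c(2, 2)))
  expect_equal(path_mass_set(toy, 0, 2), c(2L, 3L, 4L))
  expect_length(realizing_paths(toy, 0, 2, 3L), 2L) # e1e4 and e2e3
  expect_equal(path_mass_set(toy, 1, 1), 0L)

  g <- build_pmg("SYSDMK", list(mod_phospho()), scale = 1)
  expect_equal(path_mass_set(g, 0, 2), c(250L, 330L, 410L))
  expect_error(path_mass_set(g, 3, 1), "exceed")

  # property: equals brute-force enumeration on random graphs
  set.seed(11)
  for (rep in 1:10) {
    inst <- random_small_instance()
    gg <- inst$pmg
    for (s in 0:gg$n) for (i in s:gg$n) {
      brute <- sort(unique(vapply(oracle_paths(gg, s, i), sum, numeric(1))))
      expect_equal(path_mass_set(gg, s, i), as.integer(brute))
    }
  }
})

test_that("adding a red edge never removes a path mass", {
  g0 <- build_pmg("SYSDMK", scale = 1)
  g1 <- build_pmg("SYSDMK", list(mod_phospho()), scale = 1)
  for (s in 0:5) for (i in s:6) {
    expect_true(all(path_mass_set(g0, s, i) %in% path_mass_set(g1, s, i)))
  }
})

test_that("peak-support rate counts bonds backed by b or y ions", {
  pep <- "SYSDMK"
  pref <- prefix_masses(pep, 1, 21)
  total <- pref[6]
  b_mz <- pref[1:5] + 1.00727646688
  full <- tibble::tibble(mass = b_mz, intensity = 1)
  expect_equal(peak_support_rate(full, pep, 1, 21), 1.0)

  empty <- tibble::tibble(mass = numeric(), intensity = numeric())
  expect_equal(peak_support_rate(empty, pep, 1, 21), 0.0)

  # support 4 of 5 bonds of a 6-residue peptide: r = 0.8
  four <- tibble::tibble(mass = b_mz[1:4], intensity = 1)
  expect_equal(peak_support_rate(four, pep, 1, 21), 0.8)

  # a y ion supports the same bond as its complementary b ion
  y5 <- (total - pref[1]) + 18.0105646863 + 1.00727646688
  expect_equal(peak_support_rate(tibble::tibble(mass = y5, intensity = 1), pep, 1, 21),
               0.2)
  expect_error(peak_support_rate(full, "K"), "two residues")
})

test_that("peak-support rate is non-decreasing as peaks are added", {
  set.seed(3)
  pep <- "SYSDMK"
  pref <- prefix_masses(pep, 1, 21)
  mz <- pref + 1.00727646688
  r_prev <- 0
  pool <- sample(mz)
  for (t in seq_along(pool)) {
    r <- peak_support_rate(tibble::tibble(mass = pool[1:t], intensity = 1), pep, 1, 21)
    expect_gte(r, r_prev)
    r_prev <- r
  }
})
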