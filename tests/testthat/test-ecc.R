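test_that("the correction table reproduces the worked example", {
  tab <- compute_correction_sets(example_pmg(), example_smg(), delta = 0,
                                 max_missing = 2, mod_counts = c(`21` = 1L))
  e35 <- correction_set(tab, 3, 5)
  expect_equal(e35$pred_i, c(2L, 2L))
  expect_equal(e35$pred_j, c(3L, 4L))
  expect_equal(e35$pred_k, c(0L, 0L))
  expect_equal(correction_set(tab, 1, 1)[, 1:3],
               tibble::tibble(pred_i = 0L, pred_j = 0L, pred_k = 0L))
  expect_equal(correction_set(tab, 1, 2)[, 1:3],
               tibble::tibble(pred_i = 0L, pred_j = 0L, pred_k = 0L))
  expect_error(compute_correction_sets(example_pmg(), example_smg(), delta = -1),
               "non-negative")
})

test_that("a missing peak opens a skip entry in the correction table", {
  tab <- compute_correction_sets(example_pmg(), example_smg_missing(),
                                 delta = 0, max_missing = 2,
                                 mod_counts = c(`21` = 1L))
  # peak indices shift down by one once the 250 peak is gone: the 417 peak
  # is now y_4; its entry gains the skip predecessor (x_1, y_1)
  e <- correction_set(tab, 3, 4)
  expect_equal(nrow(e), 2L)
  expect_true(any(e$pred_i == 2L & e$pred_j == 3L & e$n_missing == 0L))
  expect_true(any(e$pred_i == 1L & e$pred_j == 1L & e$n_missing == 1L))
})

test_that("backtracking graphs match the worked-example counts", {
  b1 <- example_btg()
  expect_equal(nrow(b1$nodes), 9L)
  expect_equal(sum(b1$edges$color == "blue"), 9L)
  expect_equal(sum(b1$edges$color == "red"), 0L)

  b2 <- example_btg(example_smg_missing())
  expect_equal(nrow(b2$nodes), 8L)
  expect_equal(sum(b2$edges$color == "blue"), 7L)
  expect_equal(sum(b2$edges$color == "red"), 1L)
  expect_equal(b2$edges$n_missing[b2$edges$color == "red"], 1L)

  # unmodified 3-residue peptide with all prefixes observed: a 4-node chain
  g <- build_pmg("GAV", scale = 1)
  pref <- cumsum(scale_and_round(residue_mass(c("G", "A", "V")), 1))
  h <- build_smg(tibble::tibble(mass = pref, intensity = 1),
                 precursor_mass = pref[3] + 18.010565, scale = 1, delta = 0)
  b3 <- build_backtracking_graph(g, h, delta = 0)
  expect_equal(nrow(b3$nodes), 4L)
  expect_equal(nrow(b3$edges), 3L)
  expect_length(enumerate_alignments(b3), 1L)
})

test_that("an unmatchable precursor yields an empty graph", {
  g <- build_pmg("GAV", scale = 1)
  h <- build_smg(tibble::tibble(mass = 100, intensity = 1),
                 precursor_mass = 1000, scale = 1, delta = 0)
  b <- build_backtracking_graph(g, h, delta = 0)
  expect_equal(nrow(b$nodes), 0L)
  expect_match(b$message, "no isoform")
})

test_that("alignment enumeration finds each coexisting isoform", {
  als1 <- enumerate_alignments(example_btg())
  expect_length(als1, 2L)
  first_peaks <- sort(vapply(als1, function(a) a$nodes$mass[2], integer(1)))
  expect_equal(first_peaks, c(87L, 167L)) # phospho at site 3 vs site 1

  als2 <- enumerate_alignments(example_btg(example_smg_missing()))
  expect_length(als2, 2L)
  miss <- vapply(als2, function(a) a$n_missing_total, integer(1))
  expect_equal(sort(miss), c(0L, 1L))
})

test_that("the six-peak spectrum aligns with corrections (1,0,-1,0,1,0)", {
  g <- isoform_pmg("SYSDMK", pos = 1, unimod = 21, scale = 1)
  h <- build_smg(tibble::tibble(mass = c(166, 330, 418, 532, 662, 791),
                                intensity = rep(10, 6)),
                 precursor_mass = example_precursor(), scale = 1, delta = 1)
  b <- build_backtracking_graph(g, h, delta = 1)
  full <- Filter(function(a) nrow(a$nodes) == 7L, enumerate_alignments(b))
  expect_length(full, 1L)
  expect_equal(full[[1]]$nodes$k, c(0L, 1L, 0L, -1L, 0L, 1L, 0L))
  expect_true(validate_alignment(full[[1]], g, h, delta = 1))

  # perturbing one correction breaks the path-mass constraint
  bad <- tibble::tibble(i = 0:6, j = 0:6, k = c(0L, 1L, 0L, 0L, 0L, 1L, 0L))
  v <- validate_alignment(bad, g, h, delta = 1)
  expect_false(as.logical(v))
  expect_match(attr(v, "reason"), "path mass")

  empty <- tibble::tibble(i = integer(), j = integer(), k = integer())
  expect_false(as.logical(validate_alignment(empty, g, h, delta = 1)))
})

test_that("enumerated alignments equal exhaustive search on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    inst <- random_small_instance()
    b <- build_backtracking_graph(inst$pmg, inst$smg,
                                  delta = inst$delta_ticks, max_missing = 2)
    got <- sort(vapply(enumerate_alignments(b), function(a) {
      align_key(as.matrix(a$nodes[, c("i", "j", "k")]))
    }, character(1)))
    want <- oracle_alignment_set(inst$pmg, inst$smg, inst$delta_ticks, 2L)
    expect_equal(got, want)
  }
})

test_that("telescoping: step masses sum to the corrected terminal mass", {
  set.seed(5)
  for (rep in 1:10) {
    inst <- random_small_instance()
    b <- build_backtracking_graph(inst$pmg, inst$smg,
                                  delta = inst$delta_ticks, max_missing = 2)
    for (a in enumerate_alignments(b)) {
      expect_equal(sum(a$steps$m), a$nodes$corrected[nrow(a$nodes)])
      expect_equal(a$steps$n_missing, diff(a$nodes$i) - 1L)
    }
  }
})

test_that("zero tolerance forces zero corrections and max_missing=0 bans reds", {
  set.seed(6)
  for (rep in 1:10) {
    inst <- random_small_instance(delta_ticks = 0)
    b <- build_backtracking_graph(inst$pmg, inst$smg, delta = 0, max_missing = 2)
    expect_true(all(b$nodes$k == 0L))
    b0 <- build_backtracking_graph(inst$pmg, inst$smg, delta = 0, max_missing = 0)
    expect_true(all(b0$edges$color == "blue"))
  }
})
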