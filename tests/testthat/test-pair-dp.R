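test_that("node intensity errors follow the shared/unshared rules", {
  expect_equal(node_intensity_error(99, v = TRUE, q1 = 70, q2 = 30), 1)
  expect_equal(node_intensity_error(39, q1 = 70, q2 = 30, role = 2), 9)
  expect_equal(node_intensity_error(70, q1 = 70, q2 = 30, role = 1), 0)
  expect_error(node_intensity_error(10, q1 = 1, q2 = 1, role = 3), "role")
})

test_that("missing peaks cost the isoform's theoretical intensity", {
  expect_equal(missing_peak_penalty(1, 30), 30)
  expect_equal(missing_peak_penalty(0, 99), 0)
  expect_equal(missing_peak_penalty(2, 70), 140)
  expect_error(missing_peak_penalty(-1, 1), "non-negative")
})

test_that("the pair error total reproduces the printed example sums", {
  als <- enumerate_alignments(example_btg())
  iso1 <- alignment_starting_at(als, 167L) # phospho on residue 1
  iso2 <- alignment_starting_at(als, 87L)  # phospho on residue 3
  expect_equal(pair_error_total(iso1, iso2, 70, 30), 47)
  expect_equal(pair_error_total(iso2, iso1, 30, 70), 47) # swap symmetry

  alsm <- enumerate_alignments(example_btg(example_smg_missing()))
  iso1m <- alignment_starting_at(alsm, 167L)
  iso2m <- alignment_starting_at(alsm, 87L)
  expect_equal(iso2m$n_missing_total, 1L)
  expect_equal(pair_error_total(iso1m, iso2m, 70, 30), 74)
})

test_that("pair error is zero when every shared peak equals q1 + q2", {
  g <- build_pmg("GAV", scale = 1)
  pref <- cumsum(scale_and_round(residue_mass(c("G", "A", "V")), 1))
  h <- build_smg(tibble::tibble(mass = pref, intensity = 100),
                 precursor_mass = pref[3] + 18.010565, scale = 1, delta = 0)
  b <- build_backtracking_graph(g, h, delta = 0)
  a <- enumerate_alignments(b)[[1]]
  expect_equal(pair_error_total(a, a, 60, 40), 0)
})

test_that("pair scheduling expands frontiers and is closed under the recurrences", {
  # single-chain graph: schedule runs from the origin pair to the terminal pair
  g <- build_pmg("GAV", scale = 1)
  pref <- cumsum(scale_and_round(residue_mass(c("G", "A", "V")), 1))
  h <- build_smg(tibble::tibble(mass = pref, intensity = 1),
                 precursor_mass = pref[3] + 18.010565, scale = 1, delta = 0)
  b <- build_backtracking_graph(g, h, delta = 0)
  sch <- schedule_pairs(b)
  org <- b$nodes$id[b$nodes$is_origin]
  trm <- b$nodes$id[b$nodes$is_terminal]
  expect_equal(unlist(sch[1, c("u", "v")], use.names = FALSE), c(org, org))
  expect_equal(unlist(sch[nrow(sch), c("u", "v")], use.names = FALSE), c(trm, trm))

  # closure: every pair consumed by the recurrences is itself scheduled
  for (btg in list(example_btg(), example_btg(example_smg_missing()))) {
    sch <- schedule_pairs(btg)
    nd <- btg$nodes
    have <- paste(sch$u, sch$v)
    succ <- lapply(nd$id, function(v) hommtm:::btg_successors(btg, v))
    for (r in seq_len(nrow(sch))) {
      u <- sch$u[r]; v <- sch$v[r]
      if (nd$is_terminal[u] && nd$is_terminal[v]) next
      if (nd$j[u] == nd$j[v]) {
        if (nd$k[u] != nd$k[v] || nd$is_terminal[u] || nd$is_terminal[v]) next
        for (up in succ[[u]]) for (vp in succ[[v]]) {
          expect_true(paste(up, vp) %in% have)
        }
      } else if (nd$j[u] < nd$j[v]) {
        for (up in succ[[u]]) expect_true(paste(up, v) %in% have)
      } else {
        for (vp in succ[[v]]) expect_true(paste(u, vp) %in% have)
      }
    }
  }
})

test_that("the two-path DP equals the brute-force pair minimum", {
  b1 <- example_btg()
  als <- enumerate_alignments(b1)
  expect_equal(compute_pair_dp(b1, 70, 30)$total, 47)
  expect_equal(oracle_pair_min(als, 70, 30), 47)

  # with the 250 peak missing, the best pair at (70, 30) collapses onto the
  # fully-supported single isoform (total 73 < 74 of the two-isoform pair)
  b2 <- example_btg(example_smg_missing())
  als2 <- enumerate_alignments(b2)
  expect_equal(compute_pair_dp(b2, 70, 30)$total, 73)
  expect_equal(oracle_pair_min(als2, 70, 30), 73)

  # forced pair on a single-path graph
  g <- build_pmg("GAV", scale = 1)
  pref <- cumsum(scale_and_round(residue_mass(c("G", "A", "V")), 1))
  h <- build_smg(tibble::tibble(mass = pref, intensity = c(10, 20, 30)),
                 precursor_mass = pref[3] + 18.010565, scale = 1, delta = 0)
  b3 <- build_backtracking_graph(g, h, delta = 0)
  a <- enumerate_alignments(b3)[[1]]
  expect_equal(compute_pair_dp(b3, 12, 13)$total,
               pair_error_total(a, a, 12, 13))

  expect_error(compute_pair_dp(b1, 0, 10), "positive")
})

test_that("a peak shared at different PMG nodes is still charged once", {
  # both paths use the mass-5 peak: path A at x_1 (via the red 5-edge),
  # path B at x_2 (via 3+2); both reach the terminal skipping two nodes
  g <- pmg_from_edges(black = c(3L, 2L, 2L, 3L),
                      red = data.frame(pos = c(1, 3), mass = c(5, 4)))
  h <- build_smg(tibble::tibble(mass = c(5, 12), intensity = c(9, 10)),
                 precursor_mass = 12 + 18.010565, scale = 1, delta = 0)
  b <- build_backtracking_graph(g, h, delta = 0, max_missing = 2)
  als <- enumerate_alignments(b)
  expect_length(als, 2L)
  i_at <- sort(vapply(als, function(a) a$nodes$i[2], integer(1)))
  expect_equal(i_at, c(1L, 2L))
  q1 <- 7; q2 <- 4
  want <- abs(9 - q1 - q2) + abs(10 - q1 - q2) + 2 * q1 + 2 * q2
  expect_equal(oracle_pair_min(als, q1, q2), want)
  expect_equal(compute_pair_dp(b, q1, q2)$total, want)
})

test_that("DP equals brute force across random instances and intensities", {
  set.seed(202)
  done <- 0
  while (done < 12) {
    inst <- random_small_instance()
    b <- build_backtracking_graph(inst$pmg, inst$smg,
                                  delta = inst$delta_ticks, max_missing = 2)
    if (nrow(b$nodes) == 0L || nrow(b$nodes) > 12L) next
    als <- enumerate_alignments(b)
    if (length(als) == 0L) next
    sch <- schedule_pairs(b)
    for (d in 1:5) {
      q <- stats::runif(2, 1, 130)
      expect_equal(compute_pair_dp(b, q[1], q[2], schedule = sch)$total,
                   oracle_pair_min(als, q[1], q[2]))
    }
    done <- done + 1
  }
})

test_that("the grid search fits abundances and respects grid monotonicity", {
  # two isoforms, exclusive peaks 40 and 60, shared peaks 100: exact fit
  g <- build_pmg("SAS", list(mod_phospho("S")), scale = 1)
  f1 <- c(167, 238, 325) # phospho at 1
  f2 <- c(87, 158, 325)  # phospho at 3
  masses <- sort(unique(c(f1, f2)))
  inten <- ifelse(masses %in% intersect(f1, f2), 100,
                  ifelse(masses %in% f1, 60, 40))
  h <- build_smg(tibble::tibble(mass = masses, intensity = inten),
                 precursor_mass = 325 + 18.010565, scale = 1, delta = 0)
  b <- build_backtracking_graph(g, h, delta = 0, mod_counts = c(`21` = 1L))
  res <- quantify_grid_search(b, mod_counts = c(`21` = 1L))
  expect_equal(res$total_error, 0)
  expect_equal(sort(c(res$q1, res$q2)), c(40, 60))
  expect_equal(sort(res$isoforms$abundance), c(0.4, 0.6))
  expect_equal(res$hommtm_type, "phospho-site-only")

  # single-path graph: one isoform at 100%
  gg <- build_pmg("GAV", scale = 1)
  pref <- cumsum(scale_and_round(residue_mass(c("G", "A", "V")), 1))
  hh <- build_smg(tibble::tibble(mass = pref, intensity = 50),
                  precursor_mass = pref[3] + 18.010565, scale = 1, delta = 0)
  bb <- build_backtracking_graph(gg, hh, delta = 0)
  res1 <- quantify_grid_search(bb)
  expect_equal(nrow(res1$isoforms), 1L)
  expect_equal(res1$isoforms$abundance, 1)

  # enlarging the grid never increases the minimum error
  b1 <- example_btg()
  coarse <- quantify_grid_search(b1, q_values = seq(10, 110, by = 20),
                                 mod_counts = c(`21` = 1L))
  fine <- quantify_grid_search(b1, q_values = c(seq(10, 110, by = 20), 1:110),
                               mod_counts = c(`21` = 1L))
  expect_lte(fine$total_error, coarse$total_error)
  expect_lte(fine$total_error, 47) # attained at (70, 30), possibly beaten
})

test_that("abundances always sum to one and lie in (0, 1]", {
  set.seed(303)
  for (rep in 1:8) {
    inst <- random_small_instance()
    b <- build_backtracking_graph(inst$pmg, inst$smg,
                                  delta = inst$delta_ticks, max_missing = 2)
    if (nrow(b$nodes) == 0L) next
    res <- quantify_grid_search(b)
    if (res$status != "ok") next
    expect_equal(sum(res$isoforms$abundance), 1)
    expect_true(all(res$isoforms$abundance > 0))
  }
})
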