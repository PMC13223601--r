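#' Define a peptide isoform (ground truth for simulation)
#'
#' @param peptide Peptide backbone.
#' @param pos Modified positions (may be empty).
#' @param unimod UNIMOD ids, parallel to `pos`.
#' @return Object of class `pep_isoform`.
#' @export
isoform <- function(peptide, pos = integer(), unimod = integer()) {
  split_peptide(peptide)
  stopifnot(length(pos) == length(unimod))
  structure(list(peptide = peptide, pos = as.integer(pos),
                 unimod = as.integer(unimod)),
            class = "pep_isoform")
}

#' @export
print.pep_isoform <- function(x, ...) {
  cat("<isoform>", format_isoform(x$peptide, x$pos, x$unimod), "\n")
  invisible(x)
}

#' Split a total theoretical intensity by desired abundances
#'
#' Given the fitted intensities `q1`, `q2` of a seed identification and a
#' desired abundance split `a1 : a2`, returns intensities with the same sum
#' and the desired ratio: `q1' = a1 (q1 + q2) / (a1 + a2)` and symmetrically
#' for `q2'`.
#'
#' @param q1,q2 Seed theoretical intensities.
#' @param a1,a2 Desired abundances (any non-negative scale, not both 0).
#' @return Named numeric vector `c(q1 = , q2 = )`.
#' @examples
#' split_theoretical_intensities(70, 30, 1, 99)
#' @export
split_theoretical_intensities <- function(q1, q2, a1, a2) {
  if (a1 < 0 || a2 < 0 || a1 + a2 == 0) {
    stop("abundances must be non-negative and not both zero")
  }
  tot <- q1 + q2
  c(q1 = a1 * tot / (a1 + a2), q2 = a2 * tot / (a1 + a2))
}

mass_key <- function(mass) round(mass * 1e4)

#' Generate the sound peaks of a simulated HomMTM spectrum
#'
#' Builds the theoretical prefix-mass lists of both isoforms, drops each
#' mass independently with the missing-peak probability, and assigns
#' intensities: a mass present in both (post-dropout) lists becomes one
#' shared peak of intensity `(q1' + q2')(1 + e)`, an exclusive mass a peak
#' of intensity `q_c'(1 + e)`, with a fresh relative error
#' `e ~ N(mu, sigma^2)` per peak. Intensities are floored at 0.
#'
#' @param f1,f2 [isoform()] objects on the same backbone.
#' @param q1p,q2p Theoretical intensities (post [split_theoretical_intensities()]).
#' @param dropout Missing-peak probability in `[0, 1]`.
#' @param mu,sigma Mean and s.d. of the relative intensity error.
#' @param mods Modification definitions for mass lookup.
#' @return Tibble (`mass`, `intensity`, `label`), label in
#'   `sound-shared`/`sound-1`/`sound-2`.
#' @export
generate_sound_peaks <- function(f1, f2, q1p, q2p, dropout = 0.05,
                                 mu = 0, sigma = 0.1,
                                 mods = default_modifications()) {
  stopifnot(inherits(f1, "pep_isoform"), inherits(f2, "pep_isoform"))
  s1 <- prefix_masses(f1$peptide, f1$pos, f1$unimod, mods)
  s2 <- prefix_masses(f2$peptide, f2$pos, f2$unimod, mods)
  s1 <- s1[stats::runif(length(s1)) >= dropout]
  s2 <- s2[stats::runif(length(s2)) >= dropout]
  in2 <- mass_key(s1) %in% mass_key(s2)
  in1 <- mass_key(s2) %in% mass_key(s1)
  draw <- function(masses, q) {
    if (length(masses) == 0L) return(tibble::tibble(mass = numeric(), intensity = numeric()))
    e <- stats::rnorm(length(masses), mu, sigma)
    tibble::tibble(mass = masses, intensity = pmax(0, q * (1 + e)))
  }
  shared <- draw(s1[in2], q1p + q2p)
  only1 <- draw(s1[!in2], q1p)
  only2 <- draw(s2[!in1], q2p)
  out <- dplyr::bind_rows(
    dplyr::mutate(shared, label = "sound-shared"),
    dplyr::mutate(only1, label = "sound-1"),
    dplyr::mutate(only2, label = "sound-2")
  )
  dplyr::arrange(out, .data$mass)
}

#' Generate noise peaks
#'
#' Noise masses follow a Gaussian centred at half the precursor mass with
#' s.d. a quarter of the precursor mass, truncated (by rejection) to
#' `(0, M_prec - mass(H2O))`; intensities follow a Gaussian truncated at 0.
#'
#' @param n Number of noise peaks.
#' @param precursor_mass Neutral precursor mass (Da).
#' @param mu_inten,sigma_inten Mean and s.d. of noise-peak intensities.
#' @return Tibble (`mass`, `intensity`, `label = "noise"`).
#' @export
generate_noise_peaks <- function(n, precursor_mass, mu_inten, sigma_inten) {
  stopifnot(n >= 0)
  if (n == 0L) {
    return(tibble::tibble(mass = numeric(), intensity = numeric(), label = character()))
  }
  rtrunc <- function(n, mu, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mu, sd)
      out <- c(out, x[x > lo & x < hi])
    }
    out[seq_len(n)]
  }
  mass <- rtrunc(n, precursor_mass / 2, precursor_mass / 4,
                 0, precursor_mass - MASS_H2O)
  inten <- rtrunc(n, mu_inten, sigma_inten, 0, Inf)
  tibble::tibble(mass = mass, intensity = inten, label = "noise")
}

#' Simulate a HomMTM spectrum with known ground truth
#'
#' Combines [generate_sound_peaks()] and [generate_noise_peaks()] for a
#' pair of isoforms of the same peptide, recording the ground-truth
#' isoforms, the abundance split and per-peak labels. Seeded runs are
#' reproducible.
#'
#' @inheritParams generate_sound_peaks
#' @param q1,q2 Seed theoretical intensities (before the abundance split).
#' @param a1,a2 Desired abundance split.
#' @param n_noise Number of noise peaks.
#' @param noise_mu_inten,noise_sigma_inten Noise intensity law; defaults
#'   are `0.2 * (q1' + q2')` and half of that (surrogates for the
#'   statistics of real noise peaks).
#' @param seed Optional integer seed.
#' @return Object of class `sim_spectrum`: `peaks` tibble plus ground
#'   truth and the precursor mass.
#' @export
simulate_spectrum <- function(f1, f2, q1 = 70, q2 = 30, a1 = 50, a2 = 50,
                              dropout = 0.05, mu = 0, sigma = 0.1,
                              n_noise = 10, noise_mu_inten = NULL,
                              noise_sigma_inten = NULL,
                              mods = default_modifications(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(f1$peptide, f2$peptide)) {
    stop("isoforms must share the same peptide backbone")
  }
  m1 <- sum(utils::tail(prefix_masses(f1$peptide, f1$pos, f1$unimod, mods), 1))
  m2 <- sum(utils::tail(prefix_masses(f2$peptide, f2$pos, f2$unimod, mods), 1))
  if (abs(m1 - m2) > 1e-6) stop("isoforms differ in precursor mass")
  precursor_mass <- m1 + MASS_H2O
  qs <- split_theoretical_intensities(q1, q2, a1, a2)
  if (is.null(noise_mu_inten)) noise_mu_inten <- 0.2 * (qs[1] + qs[2])
  if (is.null(noise_sigma_inten)) noise_sigma_inten <- 0.5 * noise_mu_inten
  sound <- generate_sound_peaks(f1, f2, qs[1], qs[2], dropout, mu, sigma, mods)
  noise <- generate_noise_peaks(n_noise, precursor_mass,
                                noise_mu_inten, noise_sigma_inten)
  peaks <- dplyr::arrange(dplyr::bind_rows(sound, noise), .data$mass)
  structure(
    list(peaks = peaks, f1 = f1, f2 = f2,
         q1p = unname(qs[1]), q2p = unname(qs[2]), a1 = a1, a2 = a2,
         precursor_mass = precursor_mass,
         config = list(dropout = dropout, mu = mu, sigma = sigma,
                       n_noise = n_noise, noise_mu_inten = noise_mu_inten,
                       noise_sigma_inten = noise_sigma_inten)),
    class = "sim_spectrum"
  )
}

#' @export
print.sim_spectrum <- function(x, ...) {
  cat(sprintf("<simulated HomMTM spectrum> %s / %s at %g:%g, %d peaks (%d noise)\n",
              format_isoform(x$f1$peptide, x$f1$pos, x$f1$unimod),
              format_isoform(x$f2$peptide, x$f2$pos, x$f2$unimod),
              x$a1, x$a2, nrow(x$peaks), sum(x$peaks$label == "noise")))
  invisible(x)
}

#' @rdname simulate_spectrum
#' @param x A `sim_spectrum`.
#' @param ... Unused.
#' @export
tidy.sim_spectrum <- function(x, ...) x$peaks

#' Random HomMTM test case
#'
#' Draws a random peptide (uniform residues, at least two phospho-acceptor
#' sites forced) and two distinct single-phosphorylation placements on it.
#'
#' @param n_min,n_max Peptide length range.
#' @return List with `peptide`, `f1`, `f2`.
#' @export
random_hommtm_case <- function(n_min = 8, n_max = 11) {
  n <- sample(n_min:n_max, 1)
  res <- sample(names(RESIDUE_MASSES), n, replace = TRUE)
  sty <- which(res %in% c("S", "T", "Y"))
  if (length(sty) < 2L) {
    fix <- sample(setdiff(seq_len(n), sty), 2L - length(sty))
    res[fix] <- sample(c("S", "T", "Y"), length(fix), replace = TRUE)
    sty <- which(res %in% c("S", "T", "Y"))
  }
  sites <- sort(sample(sty, 2L))
  peptide <- paste(res, collapse = "")
  list(peptide = peptide,
       f1 = isoform(peptide, sites[1], 21L),
       f2 = isoform(peptide, sites[2], 21L))
}

#' Accuracy-versus-abundance-ratio benchmark
#'
#' For each abundance ratio, simulates HomMTM spectra from random
#' single-phospho isoform pairs and runs the identification pipeline,
#' reporting the fraction of spectra whose two ground-truth isoforms are
#' both recovered (accuracy), the fraction where two isoforms are called,
#' and the fraction where only one is called.
#'
#' @param ratios Numeric vector of minor-isoform abundances `a1` (the
#'   major abundance is `100 - a1`), e.g. `c(1, 10, 25, 50)`.
#' @param n_psms Simulated PSMs per ratio.
#' @param dropout,sigma,n_noise Simulator settings (see
#'   [simulate_spectrum()]).
#' @param q_total Total theoretical intensity of the seed pair.
#' @param delta,scale,max_missing Identification settings.
#' @param seed Optional integer seed.
#' @return Tibble of class `hommtm_benchmark`: one row per ratio with
#'   `accuracy`, `frac_two`, `frac_one`.
#' @export
run_benchmark <- function(ratios, n_psms = 20, dropout = 0.05, sigma = 0.1,
                          n_noise = 10, q_total = 100, delta = 0.1,
                          scale = 100, max_missing = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(ratios > 0), all(ratios <= 50))
  rows <- lapply(ratios, function(a1) {
    hits <- logical(n_psms); two <- logical(n_psms)
    for (r in seq_len(n_psms)) {
      cs <- random_hommtm_case()
      sim <- simulate_spectrum(cs$f1, cs$f2, q1 = q_total / 2, q2 = q_total / 2,
                               a1 = a1, a2 = 100 - a1, dropout = dropout,
                               mu = 0, sigma = sigma, n_noise = n_noise,
                               mods = list(mod_phospho()))
      res <- identify_isoforms(sim$peaks, cs$peptide, sim$precursor_mass,
                               mods = list(mod_phospho()),
                               mod_counts = c(phospho = 1), delta = delta,
                               scale = scale, max_missing = max_missing)
      two[r] <- res$status == "ok" && nrow(res$isoforms) == 2L
      hits[r] <- isoforms_recovered(res, cs$f1, cs$f2)
    }
    tibble::tibble(a1 = a1, a2 = 100 - a1,
                   ratio = sprintf("%g:%g", a1, 100 - a1),
                   n = n_psms, accuracy = mean(hits),
                   frac_two = mean(two),
                   frac_one = mean(!two))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hommtm_benchmark", class(out))
  out
}

#' Did an identification recover both ground-truth isoforms?
#'
#' @param result An `isoform_quant`.
#' @param f1,f2 Ground-truth [isoform()]s.
#' @return `TRUE` iff the result has two isoforms whose placements equal
#'   the ground-truth pair (in either order).
#' @export
isoforms_recovered <- function(result, f1, f2) {
  if (result$status != "ok" || nrow(result$isoforms) != 2L) return(FALSE)
  t1 <- tibble::tibble(pos = f1$pos, unimod = f1$unimod)
  t2 <- tibble::tibble(pos = f2$pos, unimod = f2$unimod)
  p1 <- result$isoforms$placement[[1]]
  p2 <- result$isoforms$placement[[2]]
  (placements_equal(p1, t1) && placements_equal(p2, t2)) ||
    (placements_equal(p1, t2) && placements_equal(p2, t1))
}
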