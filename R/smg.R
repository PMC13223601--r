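#' Build a spectrum mass graph
#'
#' The spectrum mass graph (SMG) is the ordered peak list of one MS/MS
#' spectrum expressed in neutral prefix-mass space, with a virtual origin
#' peak `y_0` (mass 0, intensity 0) and a terminal peak `y_m` at
#' `M_prec - mass(H2O)` (scaled). If no observed peak falls within `delta`
#' of the terminal mass, a virtual terminal with intensity 0 is created so
#' that alignments can always end at `y_m`; an observed peak within `delta`
#' is snapped onto the terminal node (its intensity kept, the residual mass
#' error being absorbed by the per-peak correction of the alignment stage).
#'
#' Two input spaces are supported. In `"prefix"` space each row of `peaks`
#' already is a neutral prefix mass. In `"mz"` space each observed fragment
#' at `mz` (assumed fragment charge `frag_charge`) contributes both its
#' b-ion interpretation `mz * z - z * proton` and its y-ion interpretation
#' `(M_prec - H2O) - (mz * z - z * proton - H2O)` as candidate prefix
#' masses. Peaks with equal scaled mass are merged, keeping the maximum
#' intensity.
#'
#' @param peaks Data frame with columns `mass` (Da; prefix mass or m/z
#'   depending on `input_space`) and `intensity`. May have zero rows.
#' @param precursor_mass Neutral precursor (molecular) mass in Da.
#' @param scale Integer ticks per Da.
#' @param input_space `"prefix"` or `"mz"`.
#' @param frag_charge Fragment charge assumed in `"mz"` mode.
#' @param delta Mass tolerance in Da used for terminal-peak matching (and
#'   recorded for downstream alignment).
#' @return An object of class `smg`: a peak tibble (`index` 0..m, integer
#'   `mass`, `intensity`) plus precursor/terminal masses, `I_max` and `scale`.
#' @examples
#' pk <- tibble::tibble(mass = c(87, 167, 250), intensity = c(10, 20, 30))
#' build_smg(pk, precursor_mass = 791 + 18.010565, scale = 1)
#' @export
build_smg <- function(peaks, precursor_mass, scale = 100,
                      input_space = c("prefix", "mz"), frag_charge = 1,
                      delta = 0.1) {
  input_space <- match.arg(input_space)
  stopifnot(is.data.frame(peaks), precursor_mass > 0, delta >= 0)
  if (nrow(peaks) > 0 && !all(c("mass", "intensity") %in% names(peaks))) {
    stop("`peaks` needs columns `mass` and `intensity`")
  }
  terminal <- scale_and_round(precursor_mass - MASS_H2O, scale)
  dticks <- as.integer(round(delta * scale))

  if (nrow(peaks) == 0L) {
    prefix <- numeric(); inten <- numeric()
  } else if (input_space == "prefix") {
    prefix <- peaks$mass; inten <- peaks$intensity
  } else {
    z <- frag_charge
    b <- peaks$mass * z - z * MASS_PROTON
    y <- (precursor_mass - MASS_H2O) - (b - MASS_H2O)
    prefix <- c(b, y); inten <- c(peaks$intensity, peaks$intensity)
  }

  keep <- prefix > 0 & is.finite(prefix)
  prefix <- prefix[keep]; inten <- inten[keep]
  mass <- scale_and_round(prefix, scale)
  ok <- mass > 0L & mass <= terminal + dticks
  mass <- mass[ok]; inten <- inten[ok]

  # snap peaks within delta of the terminal mass onto the terminal node
  at_term <- abs(mass - terminal) <= dticks
  term_int <- if (any(at_term)) max(inten[at_term]) else 0
  mass <- c(mass[!at_term], terminal)
  inten <- c(inten[!at_term], term_int)

  tb <- tibble::tibble(mass = c(0L, mass), intensity = c(0, inten))
  tb <- dplyr::summarise(dplyr::group_by(tb, .data$mass),
                         intensity = max(.data$intensity), .groups = "drop")
  tb <- dplyr::arrange(tb, .data$mass)
  tb <- dplyr::mutate(tb, index = dplyr::row_number() - 1L)
  tb <- tb[, c("index", "mass", "intensity")]

  structure(
    list(peaks = tb, precursor_mass = precursor_mass,
         terminal_mass = terminal, m = nrow(tb) - 1L,
         terminal_observed = any(at_term),
         I_max = if (nrow(tb) > 1L) max(tb$intensity) else 0,
         scale = scale, delta = delta),
    class = "smg"
  )
}

#' @export
print.smg <- function(x, ...) {
  cat(sprintf("<spectrum mass graph> %d peaks + origin, terminal %d (scale %g), I_max %g\n",
              x$m, x$terminal_mass, x$scale, x$I_max))
  print(x$peaks, n = 8)
  invisible(x)
}

#' @rdname build_smg
#' @param x An `smg` object.
#' @param ... Unused.
#' @export
tidy.smg <- function(x, ...) x$peaks
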