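#' Peak-support rate of a peptide-spectrum match
#'
#' For a peptide of `n` residues there are `n - 1` peptide bonds; a bond is
#' *supported* when some observed peak matches the theoretical b-ion or
#' y-ion of its cleavage within `tolerance`. The peak-support rate is
#' `r = m / (n - 1)` with `m` the number of supported bonds. Identification
#' quality correlates strongly with this rate, since only b/y ions are used
#' to anchor the alignment.
#'
#' @param spectrum Data frame of peaks (`mass`, `intensity`); `mass` is
#'   fragment m/z at `frag_charge` in `"mz"` mode, or neutral prefix mass
#'   in `"prefix"` mode.
#' @param peptide Peptide sequence (`n >= 2`).
#' @param pos,unimod Modification placement of the matched isoform.
#' @param tolerance Match tolerance in Da (default 0.1).
#' @param mods Modification definitions.
#' @param input_space `"mz"` or `"prefix"`.
#' @param frag_charge Fragment charge assumed in `"mz"` mode.
#' @return Fraction in `[0, 1]`.
#' @export
peak_support_rate <- function(spectrum, peptide, pos = integer(),
                              unimod = integer(), tolerance = 0.1,
                              mods = default_modifications(),
                              input_space = c("mz", "prefix"),
                              frag_charge = 1) {
  input_space <- match.arg(input_space)
  res <- split_peptide(peptide)
  n <- length(res)
  if (n < 2L) stop("peak-support rate needs at least two residues (one bond)")
  pref <- prefix_masses(peptide, pos, unimod, mods)
  total <- pref[n]
  bond_pref <- pref[seq_len(n - 1L)]
  obs <- if (nrow(spectrum)) spectrum$mass else numeric()
  if (length(obs) == 0L) return(0)
  supported <- vapply(bond_pref, function(p) {
    if (input_space == "prefix") {
      theo <- p # prefix-space peaks already encode the cleavage position
    } else {
      z <- frag_charge
      b <- (p + z * MASS_PROTON) / z
      y <- ((total - p) + MASS_H2O + z * MASS_PROTON) / z
      theo <- c(b, y)
    }
    any(vapply(theo, function(t) any(abs(obs - t) <= tolerance), logical(1)))
  }, logical(1))
  sum(supported) / (n - 1L)
}
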