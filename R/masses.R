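#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# Monoisotopic residue masses (Da), standard 20-letter alphabet.
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_PROTON <- 1.00727646688
MASS_H2O <- 18.0105646863

#' Monoisotopic mass of a residue
#'
#' @param symbol One-letter amino-acid code(s).
#' @return Numeric vector of residue masses in Da.
#' @export
residue_mass <- function(symbol) {
  bad <- !symbol %in% names(RESIDUE_MASSES)
  if (any(bad)) {
    stop("unknown residue symbol(s): ", paste(unique(symbol[bad]), collapse = ", "))
  }
  unname(RESIDUE_MASSES[symbol])
}

#' Scale a mass to integer ticks
#'
#' All graph arithmetic is done on integer masses: a mass in Da is multiplied
#' by `scale` (ticks per Da) and rounded half-up. The worked examples in the
#' documentation use `scale = 1` (1 Da ticks); the pipeline default is
#' `scale = 100` (0.01 Da ticks).
#'
#' @param mass Non-negative mass in Da (vectorized).
#' @param scale Integer ticks per Da, `>= 1`.
#' @return Integer tick masses.
#' @examples
#' scale_and_round(87.03203, 1)   # 87
#' scale_and_round(79.96633, 100) # 7997
#' @export
scale_and_round <- function(mass, scale) {
  if (length(scale) != 1L || is.na(scale) || scale < 1) {
    stop("`scale` must be a single value >= 1")
  }
  if (any(mass < 0)) stop("mass must be non-negative")
  as.integer(floor(mass * scale + 0.5)) # half-up, ties away from lower tick
}

#' Define a variable modification
#'
#' @param name Modification name, e.g. `"Phospho"`.
#' @param unimod UNIMOD accession number (integer).
#' @param targets Character vector of one-letter residue codes the
#'   modification can occupy, or `"N-term"` for a protein/peptide N-terminal
#'   modification (applied to residue position 1).
#' @param delta_mass Monoisotopic mass shift in Da (non-zero).
#' @return An object of class `ptm_mod`.
#' @examples
#' modification("Phospho", 21, c("S", "T", "Y"), 79.96633)
#' @export
modification <- function(name, unimod, targets, delta_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(targets) == 0L) stop("`targets` must be nonempty")
  if (delta_mass == 0) stop("`delta_mass` must be non-zero")
  structure(
    list(name = name, unimod = as.integer(unimod),
         targets = targets, delta_mass = delta_mass),
    class = "ptm_mod"
  )
}

#' @export
print.ptm_mod <- function(x, ...) {
  cat(sprintf("<modification> %s (UNIMOD:%d) %+0.5f Da on %s\n",
              x$name, x$unimod, x$delta_mass, paste(x$targets, collapse = "/")))
  invisible(x)
}

#' Bundled modification definitions
#'
#' Phosphorylation of S/T/Y (UNIMOD:21), oxidation of M (UNIMOD:35) and
#' N-terminal acetylation (UNIMOD:1) — the variable modifications used by the
#' phosphoproteome searches this tool consumes.
#'
#' @return Named list of [modification()] objects.
#' @export
default_modifications <- function() {
  list(
    phospho   = modification("Phospho", 21, c("S", "T", "Y"), 79.96633),
    oxidation = modification("Oxidation", 35, "M", 15.99491),
    acetyl    = modification("Acetyl", 1, "N-term", 42.01057)
  )
}

#' Phosphorylation modification
#'
#' Convenience constructor for UNIMOD:21 with a configurable target set.
#'
#' @param targets Residues that can carry the phosphate (default S/T/Y).
#' @return A `ptm_mod` object.
#' @export
mod_phospho <- function(targets = c("S", "T", "Y")) {
  modification("Phospho", 21, targets, 79.96633)
}

#' Oxidation modification (UNIMOD:35, methionine)
#' @return A `ptm_mod` object.
#' @export
mod_oxidation <- function() default_modifications()$oxidation

split_peptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  residue_mass(res) # validates alphabet
  res
}
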