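#' Build a peptide isoform mass graph
#'
#' The peptide isoform mass graph (PMG) is a linear DAG with `n + 1` nodes
#' `x_0 .. x_n` for a peptide of `n` residues. Each residue contributes one
#' black edge weighted by its (scaled, integer) monoisotopic mass; every
#' variable modification applicable to a residue adds a red edge weighted by
#' the modified residue mass. Every source-to-sink path through the graph is
#' one isoform, i.e. one assignment of modifications to positions.
#'
#' @param peptide Peptide sequence (one-letter codes).
#' @param mods List of [modification()] objects (or a single one) treated as
#'   variable modifications. N-terminal modifications attach to position 1.
#' @param scale Integer ticks per Da (see [scale_and_round()]).
#' @return An object of class `pmg`.
#' @examples
#' build_pmg("SYLDR", list(mod_phospho(c("S", "Y"))), scale = 1)
#' @export
build_pmg <- function(peptide, mods = list(), scale = 100) {
  if (inherits(mods, "ptm_mod")) mods <- list(mods)
  residues <- split_peptide(peptide)
  n <- length(residues)
  black <- scale_and_round(residue_mass(residues), scale)
  red <- list()
  for (mod in mods) {
    stopifnot(inherits(mod, "ptm_mod"))
    pos <- if (identical(mod$targets, "N-term")) 1L else which(residues %in% mod$targets)
    if (length(pos) == 0L) next
    # the delta is rounded once (not per residue) so that isoforms with the
    # same modification multiset always share one integer total mass
    mod_name <- mod$name; mod_unimod <- mod$unimod
    red[[length(red) + 1L]] <- tibble::tibble(
      pos = as.integer(pos),
      mass = black[pos] + scale_and_round(mod$delta_mass, scale),
      mod = mod_name,
      unimod = mod_unimod
    )
  }
  red <- if (length(red)) dplyr::bind_rows(red) else
    tibble::tibble(pos = integer(), mass = integer(), mod = character(), unimod = integer())
  if (any(c(black, red$mass) <= 0L)) stop("all scaled edge masses must be positive")
  structure(
    list(peptide = peptide, residues = residues, n = n,
         black = black, red = red, scale = scale, mods = mods),
    class = "pmg"
  )
}

#' Build a PMG from explicit edge weights
#'
#' Low-level constructor used for toy graphs and tests: edge weights are given
#' directly as integer tick masses rather than derived from a sequence.
#'
#' @param black Integer vector, one black edge mass per position.
#' @param red Data frame with columns `pos` and `mass` (optional `mod`,
#'   `unimod`) giving additional edges.
#' @param scale Ticks per Da recorded on the graph.
#' @return A `pmg` object with no associated sequence.
#' @export
pmg_from_edges <- function(black, red = NULL, scale = 1) {
  n <- length(black)
  if (is.null(red)) {
    red <- tibble::tibble(pos = integer(), mass = integer(),
                          mod = character(), unimod = integer())
  } else {
    red <- tibble::as_tibble(red)
    if (!"mod" %in% names(red)) red$mod <- "mod"
    if (!"unimod" %in% names(red)) red$unimod <- NA_integer_
    red$pos <- as.integer(red$pos)
    red$mass <- as.integer(red$mass)
  }
  stopifnot(all(red$pos >= 1L), all(red$pos <= n))
  structure(
    list(peptide = NA_character_, residues = rep(NA_character_, n), n = n,
         black = as.integer(black), red = red, scale = scale, mods = list()),
    class = "pmg"
  )
}

#' Build the mass graph of one fixed isoform
#'
#' A linear chain whose edge masses are the residue masses with the given
#' modification placement baked in (no alternative edges): the graph of a
#' single isoform rather than of all isoforms.
#'
#' @inheritParams build_pmg
#' @param pos,unimod Modification placement (see [format_isoform()]).
#' @param mods Modification definitions used to resolve UNIMOD ids.
#' @return A `pmg` object with no red edges.
#' @export
isoform_pmg <- function(peptide, pos = integer(), unimod = integer(),
                        mods = default_modifications(), scale = 100) {
  residues <- split_peptide(peptide)
  m <- scale_and_round(residue_mass(residues), scale)
  if (length(pos)) {
    m[pos] <- m[pos] + vapply(unimod, function(u) {
      scale_and_round(unimod_delta(u, mods), scale)
    }, integer(1))
  }
  g <- pmg_from_edges(m, scale = scale)
  g$peptide <- peptide
  g$residues <- residues
  g
}

#' @export
print.pmg <- function(x, ...) {
  cat(sprintf("<peptide isoform mass graph> %s: %d nodes, %d black + %d red edges (scale %g)\n",
              ifelse(is.na(x$peptide), "(custom)", x$peptide),
              x$n + 1L, x$n, nrow(x$red), x$scale))
  invisible(x)
}

# Edge options for step x_{i-1} -> x_i: black mass first, then red masses.
pmg_edge_options <- function(g, i) {
  r <- g$red[g$red$pos == i, , drop = FALSE]
  tibble::tibble(
    mass = c(g$black[i], r$mass),
    mod = c(NA_character_, r$mod),
    unimod = c(NA_integer_, r$unimod)
  )
}

#' Distinct path masses between two PMG nodes
#'
#' `d(s, i)`: the set of total masses over all edge-choice paths from node
#' `x_s` to node `x_i`. `d(i, i) = {0}`.
#'
#' @param g A [build_pmg()] graph.
#' @param s,i Node indices, `0 <= s <= i <= n`.
#' @return Sorted integer vector of distinct path masses.
#' @export
path_mass_set <- function(g, s, i) {
  stopifnot(inherits(g, "pmg"))
  if (s > i) stop("`s` must not exceed `i`")
  if (s < 0 || i > g$n) stop("node index out of range")
  masses <- 0L
  if (i > s) {
    for (pos in (s + 1L):i) {
      opts <- pmg_edge_options(g, pos)$mass
      masses <- unique(as.vector(outer(masses, opts, `+`)))
    }
  }
  sort(masses)
}

#' Paths realizing a given mass between two PMG nodes
#'
#' `P(s, i, m)`: every edge-choice path from `x_s` to `x_i` whose total mass
#' equals `m`. Each path is a tibble with one row per position giving the
#' chosen edge (black: `mod` is `NA`; red: the modification placed there).
#'
#' @inheritParams path_mass_set
#' @param m Integer tick mass to realize.
#' @return List of tibbles (possibly empty).
#' @export
realizing_paths <- function(g, s, i, m) {
  stopifnot(inherits(g, "pmg"), s <= i)
  if (i == s) {
    if (m == 0L) return(list(tibble::tibble(pos = integer(), mass = integer(),
                                            mod = character(), unimod = integer())))
    return(list())
  }
  out <- list()
  recurse <- function(pos, acc, rows) {
    if (pos > i) {
      if (acc == m) out[[length(out) + 1L]] <<- dplyr::bind_rows(rows)
      return(invisible())
    }
    # prune: remaining mass must be attainable
    opts <- pmg_edge_options(g, pos)
    for (r in seq_len(nrow(opts))) {
      nxt <- acc + opts$mass[r]
      if (nxt > m) next
      recurse(pos + 1L, nxt,
              c(rows, list(tibble::tibble(pos = pos, mass = opts$mass[r],
                                          mod = opts$mod[r], unimod = opts$unimod[r]))))
    }
  }
  recurse(s + 1L, 0L, list())
  out
}

# Cumulative prefix positions (after the chosen start mass) for one realized
# path; used by the missing-peak admissibility test.
path_intermediate_masses <- function(path) {
  if (nrow(path) <= 1L) return(integer())
  cumsum(path$mass)[seq_len(nrow(path) - 1L)]
}

#' Format an isoform as a modified-peptide string
#'
#' Modified residues are annotated with their UNIMOD id in parentheses,
#' e.g. `"S(21)YSDMK"` for a phosphoserine at position 1.
#'
#' @param peptide Peptide backbone.
#' @param pos Integer positions carrying modifications (may be empty).
#' @param unimod UNIMOD ids, parallel to `pos`.
#' @return A single string.
#' @export
format_isoform <- function(peptide, pos, unimod) {
  res <- split_peptide(peptide)
  ord <- order(pos)
  pos <- pos[ord]; unimod <- unimod[ord]
  tag <- rep("", length(res))
  tag[pos] <- sprintf("(%d)", unimod)
  paste0(res, tag, collapse = "")
}

#' Parse a modified-peptide string
#'
#' Inverse of [format_isoform()].
#'
#' @param x String such as `"S(21)YSDMK"`.
#' @return List with `peptide`, `pos`, `unimod`.
#' @export
parse_isoform <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- regmatches(x, gregexpr("[A-Z](\\([0-9]+\\))?", x))[[1]]
  if (!nzchar(x) || nchar(paste(toks, collapse = "")) != nchar(x)) {
    stop("malformed isoform string: ", x)
  }
  peptide <- paste(substr(toks, 1L, 1L), collapse = "")
  has_mod <- nchar(toks) > 1L
  list(
    peptide = peptide,
    pos = which(has_mod),
    unimod = as.integer(gsub("[^0-9]", "", toks[has_mod]))
  )
}

unimod_delta <- function(unimod, mods) {
  for (mod in mods) if (mod$unimod == unimod) return(mod$delta_mass)
  stop("no modification definition for UNIMOD:", unimod)
}

#' Theoretical prefix masses of an isoform
#'
#' Neutral b-type prefix masses (Da) at positions `1..n`; position `n` equals
#' the isoform's molecular mass minus water.
#'
#' @param peptide Peptide backbone.
#' @param pos,unimod Modification placement as in [format_isoform()].
#' @param mods Modification definitions used to resolve UNIMOD ids.
#' @return Numeric vector of length `nchar(peptide)`.
#' @export
prefix_masses <- function(peptide, pos = integer(), unimod = integer(),
                          mods = default_modifications()) {
  res <- split_peptide(peptide)
  m <- residue_mass(res)
  if (length(pos)) {
    m[pos] <- m[pos] + vapply(unimod, unimod_delta, numeric(1), mods = mods)
  }
  cumsum(m)
}
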