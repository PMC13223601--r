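# Lexicographic comparison of two sorted integer vectors; TRUE if a < b.
lex_less <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(FALSE)
  a2 <- c(a, rep(Inf, n - length(a)))
  b2 <- c(b, rep(Inf, n - length(b)))
  d <- which(a2 != b2)
  length(d) > 0L && a2[d[1]] < b2[d[1]]
}

# Resolve one alignment into a modification placement: each step's corrected
# mass difference is realized by a concrete choice of PMG edges. Among the
# realizations consistent with `mod_counts` (when given), the one with
# lexicographically smallest modified positions is reported.
alignment_placements <- function(alignment, pmg, mod_counts = NULL) {
  nodes <- alignment$nodes
  step_paths <- vector("list", nrow(nodes) - 1L)
  for (q in seq_len(nrow(nodes) - 1L)) {
    m <- nodes$corrected[q + 1L] - nodes$corrected[q]
    step_paths[[q]] <- realizing_paths(pmg, nodes$i[q], nodes$i[q + 1L], m)
  }
  ids <- names(mod_counts)
  best <- NULL
  recurse <- function(q, rows, counts) {
    if (!is.null(mod_counts) && any(counts > unlist(mod_counts))) return(invisible())
    if (q > length(step_paths)) {
      if (!is.null(mod_counts) && !all(counts == unlist(mod_counts))) return(invisible())
      placement <- dplyr::bind_rows(rows)
      placement <- placement[!is.na(placement$mod), , drop = FALSE]
      if (is.null(best) || lex_less(placement$pos, best$pos)) best <<- placement
      return(invisible())
    }
    for (p in step_paths[[q]]) {
      counts2 <- counts
      if (!is.null(mod_counts)) {
        used <- p$unimod[!is.na(p$unimod)]
        for (id in as.character(used)) {
          if (!id %in% ids) counts2 <- counts2 + Inf else counts2[id] <- counts2[id] + 1L
        }
      }
      recurse(q + 1L, c(rows, list(p)), counts2)
    }
  }
  counts0 <- if (is.null(mod_counts)) NULL else
    stats::setNames(numeric(length(ids)), ids)
  recurse(1L, list(), counts0)
  if (is.null(best)) stop("no placement realizes the alignment under the modification counts")
  best[, c("pos", "mod", "unimod")]
}

placements_equal <- function(p1, p2) {
  key <- function(p) sort(paste(p$pos, p$unimod))
  identical(key(p1), key(p2))
}

#' Classify a two-isoform identification by what differs between isoforms
#'
#' HomMTM identifications are typed by which modification sites move
#' between the two isoforms: only phosphorylation sites, only
#' oxidation/other sites, or both. The number of differing phosphorylation
#' sites (a phosphate moved between two positions counts as one differing
#' site) is reported as well.
#'
#' @param result An `isoform_quant` result.
#' @return List with `type` (`"single"`, `"phospho-site-only"`,
#'   `"oxidation-site-only"` or `"both"`) and `n_diff_phospho`.
#' @export
classify_hommtm_type <- function(result) {
  stopifnot(inherits(result, "isoform_quant"))
  if (nrow(result$isoforms) < 2L) return(list(type = "single", n_diff_phospho = 0L))
  p1 <- result$isoforms$placement[[1]]
  p2 <- result$isoforms$placement[[2]]
  diff_sites <- function(unimod_filter) {
    a <- p1$pos[p1$unimod %in% unimod_filter]
    b <- p2$pos[p2$unimod %in% unimod_filter]
    max(length(setdiff(a, b)), length(setdiff(b, a)))
  }
  n_ph <- diff_sites(21L)
  all_ids <- union(p1$unimod, p2$unimod)
  n_other <- sum(vapply(setdiff(all_ids, 21L), diff_sites, integer(1)))
  type <- if (n_ph > 0L && n_other > 0L) "both"
    else if (n_ph > 0L) "phospho-site-only"
    else if (n_other > 0L) "oxidation-site-only"
    else "single"
  list(type = type, n_diff_phospho = n_ph)
}

#' Fit the isoform pair and theoretical intensities by grid search
#'
#' Runs the two-path dynamic program for every candidate intensity pair
#' `(q1, q2)` on a grid (`I_max * x%`, `x = 1..100` by default, restricted
#' to `q1 <= q2` by swap symmetry; `I_max` is the largest intensity among
#' peaks used by the backtracking graph) and returns the pair of isoform
#' paths and intensities with the global minimum total intensity error.
#' Ties are broken by (i) more matched peaks, (ii) lexicographically
#' smallest modification positions, (iii) smaller `|q1 - q2|`.
#'
#' @param btg A backtracking graph.
#' @param q_values Optional explicit grid of candidate intensities
#'   (replaces the percent grid).
#' @param grid_step Percent step of the default grid.
#' @param mod_counts Optional modification-count constraint used when
#'   resolving alignments into placements (names = UNIMOD ids).
#' @param max_pairs Complexity guard for [schedule_pairs()].
#' @param chunk_cells Grid evaluation is chunked so the DP table never
#'   exceeds roughly this many cells.
#' @return An `isoform_quant` object (see [identify_isoforms()]).
#' @export
quantify_grid_search <- function(btg, q_values = NULL, grid_step = 1,
                                 mod_counts = NULL, max_pairs = 2e6,
                                 chunk_cells = 2e7) {
  stopifnot(inherits(btg, "btg"))
  peptide <- btg$pmg$peptide
  if (btg_is_empty(btg)) {
    return(new_isoform_quant(peptide, btg, status = "no_isoform"))
  }
  involved <- btg$nodes$j > 0L
  I_max <- max(btg$nodes$intensity[involved])
  if (I_max <= 0) I_max <- 1
  if (is.null(q_values)) q_values <- I_max * seq(grid_step, 100, by = grid_step) / 100
  q_values <- sort(unique(q_values[q_values > 0]))
  grid <- expand.grid(q1 = q_values, q2 = q_values)
  grid <- grid[grid$q1 <= grid$q2, , drop = FALSE]

  schedule <- schedule_pairs(btg, max_pairs = max_pairs)
  chunk <- max(1L, floor(chunk_cells / max(1L, nrow(schedule))))
  total <- numeric(nrow(grid))
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    dp <- compute_pair_dp(btg, grid$q1[idx], grid$q2[idx], schedule = schedule)
    total[idx] <- dp$total
  }
  best_err <- min(total)
  if (!is.finite(best_err)) {
    return(new_isoform_quant(peptide, btg, status = "no_isoform"))
  }
  tied <- which(total <= best_err + 1e-9)
  if (length(tied) > 50L) tied <- tied[seq_len(50L)]
  cand <- lapply(tied, function(g) {
    dp <- compute_pair_dp(btg, grid$q1[g], grid$q2[g], schedule = schedule)
    pair <- backtrack_pair(dp)
    pl1 <- alignment_placements(pair$P1, btg$pmg, mod_counts)
    pl2 <- alignment_placements(pair$P2, btg$pmg, mod_counts)
    list(q1 = grid$q1[g], q2 = grid$q2[g], err = dp$total,
         P1 = pair$P1, P2 = pair$P2, pl1 = pl1, pl2 = pl2,
         n_matched = nrow(pair$P1$nodes) + nrow(pair$P2$nodes) - 2L,
         pos_key = sort(c(pl1$pos, pl2$pos)))
  })
  pick <- 1L
  if (length(cand) > 1L) {
    for (i in seq_along(cand)[-1L]) {
      a <- cand[[i]]; b <- cand[[pick]]
      better <- a$n_matched > b$n_matched ||
        (a$n_matched == b$n_matched && lex_less(a$pos_key, b$pos_key)) ||
        (a$n_matched == b$n_matched && identical(a$pos_key, b$pos_key) &&
           abs(a$q1 - a$q2) < abs(b$q1 - b$q2))
      if (better) pick <- i
    }
  }
  w <- cand[[pick]]
  new_isoform_quant(peptide, btg, status = "ok", winner = w,
                    I_max = I_max, mod_counts = mod_counts)
}

new_isoform_quant <- function(peptide, btg, status, winner = NULL,
                              I_max = NA_real_, mod_counts = NULL) {
  if (status != "ok") {
    res <- structure(
      list(peptide = peptide, status = status,
           isoforms = tibble::tibble(isoform = character(), placement = list(),
                                     q = numeric(), abundance = numeric(),
                                     n_peaks = integer(), n_missing = integer()),
           alignments = list(), q1 = NA_real_, q2 = NA_real_,
           total_error = NA_real_, I_max = I_max,
           hommtm_type = "none", n_diff_phospho = 0L),
      class = "isoform_quant")
    return(res)
  }
  # one isoform is called when the optimal pair's placements coincide
  single <- placements_equal(winner$pl1, winner$pl2)
  iso_str <- function(pl) {
    if (is.na(peptide)) paste0("pos:", paste(pl$pos, "(", pl$unimod, ")", sep = "", collapse = "+"))
    else format_isoform(peptide, pl$pos, pl$unimod)
  }
  if (single) {
    isoforms <- tibble::tibble(
      isoform = iso_str(winner$pl1), placement = list(winner$pl1),
      q = winner$q1 + winner$q2, abundance = 1,
      n_peaks = nrow(winner$P1$nodes) - 1L,
      n_missing = winner$P1$n_missing_total)
  } else {
    isoforms <- tibble::tibble(
      isoform = c(iso_str(winner$pl1), iso_str(winner$pl2)),
      placement = list(winner$pl1, winner$pl2),
      q = c(winner$q1, winner$q2),
      abundance = c(winner$q1, winner$q2) / (winner$q1 + winner$q2),
      n_peaks = c(nrow(winner$P1$nodes), nrow(winner$P2$nodes)) - 1L,
      n_missing = c(winner$P1$n_missing_total, winner$P2$n_missing_total))
  }
  res <- structure(
    list(peptide = peptide, status = status, isoforms = isoforms,
         alignments = list(P1 = winner$P1, P2 = winner$P2),
         q1 = winner$q1, q2 = winner$q2, total_error = winner$err,
         I_max = I_max, hommtm_type = NA_character_, n_diff_phospho = NA_integer_),
    class = "isoform_quant")
  cls <- classify_hommtm_type(res)
  res$hommtm_type <- cls$type
  res$n_diff_phospho <- cls$n_diff_phospho
  res
}

#' @export
print.isoform_quant <- function(x, ...) {
  if (x$status != "ok") {
    cat("<isoform identification> no isoform matches precursor mass\n")
    return(invisible(x))
  }
  cat(sprintf("<isoform identification> %s: %d isoform(s), total intensity error %g (q1 = %g, q2 = %g)\n",
              ifelse(is.na(x$peptide), "(custom)", x$peptide),
              nrow(x$isoforms), x$total_error, x$q1, x$q2))
  for (r in seq_len(nrow(x$isoforms))) {
    cat(sprintf("  %s  abundance %.1f%%  (%d peaks, %d missing)\n",
                x$isoforms$isoform[r], 100 * x$isoforms$abundance[r],
                x$isoforms$n_peaks[r], x$isoforms$n_missing[r]))
  }
  if (nrow(x$isoforms) == 2L) cat("  type:", x$hommtm_type, "\n")
  invisible(x)
}

#' @rdname identify_isoforms
#' @param x An `isoform_quant` object.
#' @param ... Unused.
#' @export
tidy.isoform_quant <- function(x, ...) {
  dplyr::select(x$isoforms, -"placement")
}

#' @rdname identify_isoforms
#' @export
glance.isoform_quant <- function(x, ...) {
  tibble::tibble(
    peptide = x$peptide, status = x$status, n_isoforms = nrow(x$isoforms),
    q1 = x$q1, q2 = x$q2, total_error = x$total_error,
    hommtm_type = x$hommtm_type, n_diff_phospho = x$n_diff_phospho
  )
}

# Normalise user modification counts (named by lowercase modification name
# or by UNIMOD id) to UNIMOD-id keys.
normalise_mod_counts <- function(mod_counts, mods) {
  if (is.null(mod_counts)) return(NULL)
  nm <- names(mod_counts)
  if (is.null(nm)) stop("`mod_counts` must be named")
  ids <- vapply(nm, function(x) {
    if (grepl("^[0-9]+$", x)) return(as.integer(x))
    for (mod in mods) if (tolower(mod$name) == tolower(x)) return(mod$unimod)
    stop("unknown modification name in `mod_counts`: ", x)
  }, integer(1))
  out <- as.integer(mod_counts)
  names(out) <- as.character(ids)
  out[out > 0L]
}

#' Identify up to two coexisting isoforms in one spectrum
#'
#' The full pipeline for one peptide-spectrum match: build the peptide
#' isoform mass graph, cast the spectrum as a mass graph, compute the
#' peak-error-correction table, backtrack it into the graph of all
#' candidate isoform-spectrum matches, and fit the pair of isoform paths
#' and theoretical intensities minimizing the total peak-intensity error.
#' One isoform is reported when the optimal pair collapses onto a single
#' path, two otherwise; abundances are `q_i / (q1 + q2)`.
#'
#' @param spectrum Data frame of peaks (`mass`, `intensity`), in neutral
#'   prefix-mass space by default (see `input_space`).
#' @param peptide Peptide sequence reported by the upstream search.
#' @param precursor_mass Neutral precursor mass in Da.
#' @param mods Variable modifications ([modification()] list).
#' @param mod_counts Optional named counts (e.g. `c(phospho = 1)`)
#'   restricting isoforms to the modification multiplicities reported by
#'   the search.
#' @param delta Per-peak mass tolerance in Da.
#' @param scale Integer ticks per Da.
#' @param max_missing Maximum consecutive missing peaks per alignment step.
#' @param input_space,frag_charge Passed to [build_smg()].
#' @param q_values,grid_step,max_pairs Passed to [quantify_grid_search()].
#' @return An `isoform_quant` object; use [tidy()] / [glance()] to extract
#'   tables, `$status` is `"no_isoform"` when no isoform matches the
#'   precursor mass.
#' @export
identify_isoforms <- function(spectrum, peptide, precursor_mass,
                              mods = default_modifications(),
                              mod_counts = NULL, delta = 0.1, scale = 100,
                              max_missing = 2,
                              input_space = c("prefix", "mz"),
                              frag_charge = 1, q_values = NULL,
                              grid_step = 1, max_pairs = 2e6) {
  input_space <- match.arg(input_space)
  if (inherits(mods, "ptm_mod")) mods <- list(mods)
  mc <- normalise_mod_counts(mod_counts, mods)
  g <- build_pmg(peptide, mods, scale = scale)
  h <- build_smg(spectrum, precursor_mass, scale = scale,
                 input_space = input_space, frag_charge = frag_charge,
                 delta = delta)
  b <- build_backtracking_graph(g, h, delta = delta, max_missing = max_missing,
                                mod_counts = mc)
  quantify_grid_search(b, q_values = q_values, grid_step = grid_step,
                       mod_counts = mc, max_pairs = max_pairs)
}

#' Compare an identification with the isoform reported by a search engine
#'
#' A *common identification*: the upstream engine's reported isoform equals
#' one of the isoforms identified here (either of the two for a HomMTM
#' call, the single isoform otherwise).
#'
#' @param result An `isoform_quant`.
#' @param reported Reported isoform as a modified-peptide string, e.g.
#'   `"SYS(21)DMK"` (see [format_isoform()]).
#' @return `TRUE` or `FALSE`.
#' @export
compare_with_reported <- function(result, reported) {
  stopifnot(inherits(result, "isoform_quant"))
  rep_iso <- parse_isoform(reported)
  if (!identical(rep_iso$peptide, result$peptide)) {
    stop("reported isoform has a different peptide backbone")
  }
  if (result$status != "ok") return(FALSE)
  rep_pl <- tibble::tibble(pos = rep_iso$pos, unimod = rep_iso$unimod)
  any(vapply(result$isoforms$placement, placements_equal, logical(1), p2 = rep_pl))
}
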