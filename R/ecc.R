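triple_key <- function(i, j, k) paste(i, j, k, sep = ",")

# Total isoform masses reachable in the PMG, optionally restricted to exact
# modification counts (named by UNIMOD id, e.g. c(`21` = 1)).
pmg_total_masses <- function(g, mod_counts = NULL) {
  if (is.null(mod_counts)) return(path_mass_set(g, 0L, g$n))
  ids <- names(mod_counts)
  # states: (total mass, count per constrained modification)
  st <- matrix(0L, nrow = 1L, ncol = 1L + length(ids))
  for (pos in seq_len(g$n)) {
    opts <- pmg_edge_options(g, pos)
    pieces <- list()
    for (r in seq_len(nrow(opts))) {
      s2 <- st
      s2[, 1L] <- s2[, 1L] + opts$mass[r]
      if (!is.na(opts$unimod[r])) {
        id <- match(as.character(opts$unimod[r]), ids)
        if (is.na(id)) next # modification not allowed by the reported counts
        s2[, 1L + id] <- s2[, 1L + id] + 1L
        s2 <- s2[s2[, 1L + id] <= mod_counts[[id]], , drop = FALSE]
      }
      if (nrow(s2)) pieces[[length(pieces) + 1L]] <- s2
    }
    if (length(pieces) == 0L) return(integer())
    st <- unique(do.call(rbind, pieces))
  }
  want <- as.integer(unlist(mod_counts))
  ok <- apply(st[, -1L, drop = FALSE], 1L, function(x) all(x == want))
  sort(unique(st[ok, 1L]))
}

#' Compute the peak-error-correction table E(i, j, k)
#'
#' For each reachable triple `(i, j, k)` — PMG node `x_i` matched to peak
#' `y_j` with additive mass correction `k` (integer ticks, `|k| <= delta`) —
#' the set `E(i, j, k)` contains every admissible predecessor triple
#' `(i', j', k')` such that the corrected mass difference
#' `(m_j + k) - (m_j' + k')` equals the mass of some path from `x_i'` to
#' `x_i`. The table is grown backwards from the terminal set: triples
#' `(n, m, k)` whose corrected terminal mass `m_m + k` equals a realizable
#' isoform mass (molecular mass minus water).
#'
#' Predecessors that skip PMG nodes (`i - i' > 1`) model missing peaks and
#' are admitted only when some realizing path's intermediate theoretical
#' positions are all absent from the spectrum (within `delta`): a skipped
#' node whose peak is actually present is not a missing peak.
#'
#' @param pmg A [build_pmg()] graph.
#' @param smg A [build_smg()] spectrum, same scale.
#' @param delta Per-peak mass tolerance in Da (`delta = 0` forces all
#'   corrections to 0).
#' @param max_missing Maximum number of consecutive skipped PMG nodes per
#'   alignment step.
#' @param mod_counts Optional named integer vector (names = UNIMOD ids)
#'   restricting the terminal set to isoforms with exactly these
#'   modification counts, as reported by the upstream search.
#' @return An object of class `ecc_table` with the visited triples, their
#'   predecessor sets and the terminal set. Query it with [correction_set()].
#' @export
compute_correction_sets <- function(pmg, smg, delta = 0.1, max_missing = 2,
                                    mod_counts = NULL) {
  stopifnot(inherits(pmg, "pmg"), inherits(smg, "smg"))
  if (delta < 0) stop("`delta` must be non-negative")
  if (pmg$scale != smg$scale) stop("PMG and SMG must share the same scale")
  dticks <- as.integer(round(delta * pmg$scale))
  n <- pmg$n
  m_idx <- smg$m
  pk_mass <- smg$peaks$mass # position t+1 holds peak t
  obs_mass <- pk_mass[-1L]
  if (!isTRUE(smg$terminal_observed)) obs_mass <- obs_mass[-length(obs_mass)]

  dmemo <- new.env(parent = emptyenv())
  dset <- function(s, i) {
    key <- paste(s, i)
    v <- get0(key, envir = dmemo)
    if (is.null(v)) {
      v <- path_mass_set(pmg, s, i)
      assign(key, v, envir = dmemo)
    }
    v
  }

  # A skip x_i' -> x_i of mass m starting at corrected mass `start` is a
  # genuine missing-peak step if some realizing path's intermediate
  # positions all lack a matching observed peak.
  skip_ok <- function(ip, i, m, start) {
    for (p in realizing_paths(pmg, ip, i, m)) {
      pos <- start + path_intermediate_masses(p)
      hit <- vapply(pos, function(x) any(abs(obs_mass - x) <= dticks), logical(1))
      if (!any(hit)) return(TRUE)
    }
    FALSE
  }

  preds_of <- function(i, j, k) {
    out <- list()
    target <- pk_mass[j + 1L] + k
    for (ip in seq(i - 1L, max(0L, i - 1L - max_missing))) {
      nmiss <- i - ip - 1L
      if (ip == 0L) {
        # first triple is (x_0, y_0, 0): step mass must be the full target
        if (j > 0L && target %in% dset(0L, i) &&
            (nmiss == 0L || skip_ok(0L, i, target, 0L))) {
          out[[length(out) + 1L]] <- c(0L, 0L, 0L, target, nmiss)
        }
      } else {
        for (m in dset(ip, i)) {
          want <- target - m # corrected mass required of the predecessor peak
          js <- which(abs(pk_mass - want) <= dticks) - 1L
          js <- js[js >= 1L & js < j]
          for (jp in js) {
            kp <- want - pk_mass[jp + 1L]
            if (nmiss > 0L && !skip_ok(ip, i, m, want)) next
            out[[length(out) + 1L]] <- c(ip, jp, kp, m, nmiss)
          }
        }
      }
    }
    out
  }

  # terminal set: k fixed by isoform molecular mass
  term_mass <- pk_mass[m_idx + 1L]
  tot <- pmg_total_masses(pmg, mod_counts)
  term_k <- (tot - term_mass)
  term_k <- sort(term_k[abs(term_k) <= dticks])
  terminals <- lapply(term_k, function(k) c(n, m_idx, as.integer(k)))

  visited <- new.env(parent = emptyenv())
  edges <- list()
  queue <- terminals
  for (t in terminals) assign(triple_key(t[1], t[2], t[3]), t, envir = visited)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    if (u[1] == 0L) next
    for (p in preds_of(u[1], u[2], u[3])) {
      edges[[length(edges) + 1L]] <- c(u[1], u[2], u[3], p)
      pk <- triple_key(p[1], p[2], p[3])
      if (is.null(get0(pk, envir = visited))) {
        assign(pk, p[1:3], envir = visited)
        queue[[length(queue) + 1L]] <- p[1:3]
      }
    }
  }

  vis <- as.list(visited)
  nodes <- if (length(vis)) {
    do.call(rbind, lapply(vis, function(v) v[1:3]))
  } else {
    matrix(integer(), ncol = 3)
  }
  nodes <- tibble::tibble(i = as.integer(nodes[, 1]), j = as.integer(nodes[, 2]),
                          k = as.integer(nodes[, 3]))
  nodes <- dplyr::arrange(nodes, .data$i, .data$j, .data$k)
  ed <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), ncol = 8)
  edges <- tibble::tibble(
    i = as.integer(ed[, 1]), j = as.integer(ed[, 2]), k = as.integer(ed[, 3]),
    pred_i = as.integer(ed[, 4]), pred_j = as.integer(ed[, 5]),
    pred_k = as.integer(ed[, 6]), m = as.integer(ed[, 7]),
    n_missing = as.integer(ed[, 8])
  )
  structure(
    list(pmg = pmg, smg = smg, delta = delta, dticks = dticks,
         max_missing = max_missing, mod_counts = mod_counts,
         nodes = nodes, edges = edges,
         terminals = tibble::tibble(
           i = vapply(terminals, `[`, integer(1), 1),
           j = vapply(terminals, `[`, integer(1), 2),
           k = vapply(terminals, `[`, integer(1), 3))),
    class = "ecc_table"
  )
}

#' @export
print.ecc_table <- function(x, ...) {
  cat(sprintf("<error-correction table> %d triples, %d predecessor entries, %d terminal(s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$terminals)))
  invisible(x)
}

#' Query a predecessor set E(i, j, k)
#'
#' @param table An `ecc_table` from [compute_correction_sets()].
#' @param i,j,k Triple to query (`k` defaults to 0, the only value when
#'   `delta = 0`).
#' @return Tibble with one row per predecessor: `pred_i`, `pred_j`,
#'   `pred_k`, the realized step mass `m` and `n_missing`.
#' @export
correction_set <- function(table, i, j, k = 0L) {
  stopifnot(inherits(table, "ecc_table"))
  e <- table$edges
  e <- e[e$i == i & e$j == j & e$k == k,
         c("pred_i", "pred_j", "pred_k", "m", "n_missing")]
  dplyr::arrange(e, .data$pred_i, .data$pred_j, .data$pred_k)
}

#' Build the backtracking graph of all candidate alignments
#'
#' Prunes the error-correction table to the triples lying on some path from
#' a terminal triple to the origin `(0, 0, 0)`. Every terminal-to-origin
#' path in the result is one valid peak-error-correction alignment (one
#' candidate isoform-spectrum match). Edges between adjacent PMG nodes are
#' blue; edges skipping PMG nodes are red and carry the number of missing
#' peaks they imply.
#'
#' @param table An `ecc_table`, or a `pmg` (then `smg` etc. are used to
#'   compute the table first).
#' @param smg,delta,max_missing,mod_counts Passed to
#'   [compute_correction_sets()] when `table` is a `pmg`.
#' @return An object of class `btg` with `nodes` and `edges` tibbles. A
#'   graph with zero nodes means no isoform matches the precursor mass.
#' @export
build_backtracking_graph <- function(table, smg = NULL, delta = 0.1,
                                     max_missing = 2, mod_counts = NULL) {
  if (inherits(table, "pmg")) {
    table <- compute_correction_sets(table, smg, delta = delta,
                                     max_missing = max_missing,
                                     mod_counts = mod_counts)
  }
  stopifnot(inherits(table, "ecc_table"))
  nodes <- table$nodes
  edges <- table$edges
  empty <- function() {
    structure(
      list(nodes = tibble::tibble(id = integer(), i = integer(), j = integer(),
                                  k = integer(), mass = integer(),
                                  corrected = integer(), intensity = numeric(),
                                  is_origin = logical(), is_terminal = logical()),
           edges = tibble::tibble(from = integer(), to = integer(), m = integer(),
                                  color = character(), n_missing = integer()),
           pmg = table$pmg, smg = table$smg, delta = table$delta,
           dticks = table$dticks, max_missing = table$max_missing,
           message = "no isoform matches precursor mass"),
      class = "btg")
  }
  if (nrow(nodes) == 0L || !any(nodes$i == 0L)) return(empty())

  # keep only triples from which the origin is reachable
  nkey <- triple_key(nodes$i, nodes$j, nodes$k)
  idx <- stats::setNames(seq_len(nrow(nodes)), nkey)
  from <- idx[triple_key(edges$i, edges$j, edges$k)]
  to <- idx[triple_key(edges$pred_i, edges$pred_j, edges$pred_k)]
  reaches <- rep(FALSE, nrow(nodes))
  reaches[nodes$i == 0L & nodes$j == 0L & nodes$k == 0L] <- TRUE
  repeat {
    new <- reaches | seq_len(nrow(nodes)) %in% from[reaches[to]]
    if (identical(new, reaches)) break
    reaches <- new
  }
  keep <- which(reaches)
  if (length(keep) == 0L) return(empty())
  nodes <- nodes[keep, , drop = FALSE]
  sel <- from %in% keep & to %in% keep
  edges <- edges[sel, , drop = FALSE]

  pk <- table$smg$peaks
  nodes <- dplyr::arrange(nodes, .data$i, .data$j, .data$k)
  nodes$id <- seq_len(nrow(nodes))
  nodes$mass <- pk$mass[nodes$j + 1L]
  nodes$corrected <- nodes$mass + nodes$k
  nodes$intensity <- pk$intensity[nodes$j + 1L]
  nodes$is_origin <- nodes$i == 0L & nodes$j == 0L & nodes$k == 0L
  tk <- triple_key(table$terminals$i, table$terminals$j, table$terminals$k)
  nodes$is_terminal <- triple_key(nodes$i, nodes$j, nodes$k) %in% tk
  idx2 <- stats::setNames(nodes$id, triple_key(nodes$i, nodes$j, nodes$k))
  out_edges <- tibble::tibble(
    from = unname(idx2[triple_key(edges$i, edges$j, edges$k)]),
    to = unname(idx2[triple_key(edges$pred_i, edges$pred_j, edges$pred_k)]),
    m = edges$m,
    color = ifelse(edges$n_missing > 0L, "red", "blue"),
    n_missing = edges$n_missing
  )
  out_edges <- dplyr::arrange(out_edges, .data$from, .data$to)
  structure(
    list(nodes = nodes[, c("id", "i", "j", "k", "mass", "corrected", "intensity",
                           "is_origin", "is_terminal")],
         edges = out_edges,
         pmg = table$pmg, smg = table$smg, delta = table$delta,
         dticks = table$dticks, max_missing = table$max_missing,
         message = NULL),
    class = "btg"
  )
}

#' @export
print.btg <- function(x, ...) {
  if (nrow(x$nodes) == 0L) {
    cat("<backtracking graph> empty:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<backtracking graph> %d nodes, %d blue + %d red edges, %d terminal(s)\n",
              nrow(x$nodes), sum(x$edges$color == "blue"),
              sum(x$edges$color == "red"), sum(x$nodes$is_terminal)))
  invisible(x)
}

btg_is_empty <- function(b) nrow(b$nodes) == 0L

# successor map: ids u such that v is in E(u) (edge u -> v)
btg_successors <- function(b, v_id) sort(b$edges$from[b$edges$to == v_id])

new_alignment <- function(nodes, btg) {
  steps <- if (nrow(nodes) > 1L) {
    tibble::tibble(
      from_i = nodes$i[-nrow(nodes)], to_i = nodes$i[-1L],
      from_j = nodes$j[-nrow(nodes)], to_j = nodes$j[-1L],
      m = nodes$corrected[-1L] - nodes$corrected[-nrow(nodes)],
      n_missing = nodes$i[-1L] - nodes$i[-nrow(nodes)] - 1L
    )
  } else {
    tibble::tibble(from_i = integer(), to_i = integer(), from_j = integer(),
                   to_j = integer(), m = integer(), n_missing = integer())
  }
  structure(
    list(nodes = nodes, steps = steps,
         n_missing_total = sum(steps$n_missing),
         smg_peaks = btg$smg$peaks,
         scale = btg$pmg$scale),
    class = "ecc_alignment"
  )
}

#' Enumerate every alignment contained in a backtracking graph
#'
#' One alignment per terminal-to-origin path, emitted origin-first.
#'
#' @param btg A [build_backtracking_graph()] result.
#' @param max_alignments Safety cap on the number of emitted alignments.
#' @return List of `ecc_alignment` objects.
#' @export
enumerate_alignments <- function(btg, max_alignments = 100000L) {
  stopifnot(inherits(btg, "btg"))
  if (btg_is_empty(btg)) return(list())
  nd <- btg$nodes
  adj <- split(btg$edges$to, btg$edges$from) # from -> preds (toward origin)
  origin <- nd$id[nd$is_origin]
  out <- list()
  walk <- function(path) {
    head_id <- path[length(path)]
    if (head_id == origin) {
      if (length(out) >= max_alignments) {
        stop("more than ", max_alignments, " alignments; raise `max_alignments`")
      }
      rows <- nd[match(rev(path), nd$id), , drop = FALSE]
      out[[length(out) + 1L]] <<- new_alignment(rows, btg)
      return(invisible())
    }
    for (nxt in sort(adj[[as.character(head_id)]])) walk(c(path, nxt))
  }
  for (t in nd$id[nd$is_terminal]) walk(t)
  out
}

#' @export
print.ecc_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d matched peaks, %d missing peak(s)\n",
              nrow(x$nodes) - 1L, x$n_missing_total))
  print(tidy(x))
  invisible(x)
}

#' Tidy an alignment into an exportable table
#'
#' @param x An `ecc_alignment`.
#' @param ... Unused.
#' @return Tibble with peak index, observed and corrected mass, PMG node,
#'   correction and intensity, origin-first.
#' @export
tidy.ecc_alignment <- function(x, ...) {
  tibble::tibble(
    pmg_node = x$nodes$i, peak_index = x$nodes$j,
    peak_mass = x$nodes$mass, correction = x$nodes$k,
    corrected_mass = x$nodes$corrected, intensity = x$nodes$intensity
  )
}

#' Validate a peak-error-correction alignment
#'
#' Checks every alignment invariant directly against the graphs: endpoint
#' conditions (starts at `(x_0, y_0, 0)`, ends at `y_m` on `x_n`), strictly
#' increasing indices, corrections within tolerance, each consecutive
#' corrected mass difference realizable as a PMG path mass, and skip steps
#' corresponding to genuinely missing peaks.
#'
#' @param alignment An `ecc_alignment`, or a data frame with columns
#'   `i`, `j`, `k` (origin-first).
#' @param pmg,smg The graphs the alignment refers to.
#' @param delta Tolerance in Da.
#' @param max_missing Maximum skipped PMG nodes per step.
#' @return `TRUE`, or `FALSE` with the violated clause in
#'   `attr(, "reason")`.
#' @export
validate_alignment <- function(alignment, pmg, smg, delta = 0.1, max_missing = 2) {
  fail <- function(reason) structure(FALSE, reason = reason)
  a <- if (inherits(alignment, "ecc_alignment")) alignment$nodes else
    tibble::as_tibble(alignment)
  if (nrow(a) == 0L) return(fail("empty alignment"))
  if (!all(c("i", "j", "k") %in% names(a))) return(fail("need columns i, j, k"))
  dticks <- as.integer(round(delta * pmg$scale))
  pk <- smg$peaks$mass
  if (a$i[1] != 0L || a$j[1] != 0L || a$k[1] != 0L) {
    return(fail("must start at (x_0, y_0, 0)"))
  }
  if (a$j[nrow(a)] != smg$m) return(fail("must end at the terminal peak y_m"))
  if (a$i[nrow(a)] != pmg$n) return(fail("must end at PMG node x_n"))
  if (any(diff(a$i) <= 0L) || any(diff(a$j) <= 0L)) {
    return(fail("node and peak indices must be strictly increasing"))
  }
  if (any(abs(a$k) > dticks)) return(fail("correction exceeds tolerance"))
  corrected <- pk[a$j + 1L] + a$k
  dticks_env <- dticks
  obs_mass <- pk[-1L]
  if (!isTRUE(smg$terminal_observed)) obs_mass <- obs_mass[-length(obs_mass)]
  for (q in 2:nrow(a)) {
    m <- corrected[q] - corrected[q - 1L]
    dm <- path_mass_set(pmg, a$i[q - 1L], a$i[q])
    if (!m %in% dm) {
      return(fail(sprintf("step %d: corrected mass difference %d is not a path mass", q - 1L, m)))
    }
    nmiss <- a$i[q] - a$i[q - 1L] - 1L
    if (nmiss > max_missing) return(fail(sprintf("step %d: %d missing peaks exceeds cap", q - 1L, nmiss)))
    if (nmiss > 0L) {
      ok <- FALSE
      for (p in realizing_paths(pmg, a$i[q - 1L], a$i[q], m)) {
        pos <- corrected[q - 1L] + path_intermediate_masses(p)
        hit <- vapply(pos, function(x) any(abs(obs_mass - x) <= dticks_env), logical(1))
        if (!any(hit)) { ok <- TRUE; break }
      }
      if (!ok) return(fail(sprintf("step %d: skipped peaks are present in the spectrum", q - 1L)))
    }
  }
  TRUE
}
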