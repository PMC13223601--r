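#' Peak intensity error of one backtracking-graph node
#'
#' A peak used by both isoform paths at the same position and correction is
#' a shared peak with error `|I - q1 - q2|`; a peak used by only one path
#' has error `|I - q_role|`. The virtual origin peak carries no error.
#'
#' @param u Observed intensity of the peak (or a node row with an
#'   `intensity` field).
#' @param v `NULL` for an unshared peak; anything else marks the peak as
#'   shared between both paths.
#' @param q1,q2 Theoretical peak intensities of the two isoforms
#'   (vectorized).
#' @param role 1 or 2: which theoretical intensity an unshared peak is
#'   compared against.
#' @return Numeric error(s).
#' @examples
#' node_intensity_error(99, v = TRUE, q1 = 70, q2 = 30) # shared: 1
#' node_intensity_error(39, q1 = 70, q2 = 30, role = 2) # unshared: 9
#' @export
node_intensity_error <- function(u, v = NULL, q1, q2, role = 1) {
  I <- if (is.list(u) && !is.null(u$intensity)) u$intensity else u
  if (!is.null(v)) return(abs(I - q1 - q2))
  if (length(role) != 1L || !role %in% c(1, 2)) stop("`role` must be 1 or 2")
  if (role == 1) abs(I - q1) else abs(I - q2)
}

#' Intensity penalty for missing peaks
#'
#' A theoretical peak of an isoform absent from the spectrum is scored as a
#' peak of intensity 0 at its theoretical position: each missing peak on an
#' alignment step costs the isoform's full theoretical intensity.
#'
#' @param n_missing Number of missing peaks (skipped PMG nodes) on the step.
#' @param q Theoretical intensity of the isoform the step belongs to.
#' @return `n_missing * q`.
#' @examples
#' missing_peak_penalty(1, 30) # 30
#' @export
missing_peak_penalty <- function(n_missing, q) {
  if (any(n_missing < 0)) stop("`n_missing` must be non-negative")
  n_missing * q
}

#' Total intensity error of a pair of alignments
#'
#' Direct evaluation of the pair objective: shared peaks (same peak index
#' and correction in both alignments) contribute `|I - q1 - q2|` once,
#' unshared peaks contribute `|I - q_role|`, and each missing peak
#' contributes the corresponding theoretical intensity. A pair in which the
#' same peak is used with two different corrections is invalid (`Inf`): a
#' peak has only one correct position.
#'
#' @param a1,a2 `ecc_alignment` objects on the same spectrum (the pair may
#'   be the same alignment twice: a single-isoform explanation).
#' @param q1,q2 Theoretical intensities (vectorized, equal length).
#' @param smg Optional spectrum; when given, both alignments are checked
#'   against it.
#' @return Numeric vector of total errors, one per `(q1, q2)` pair.
#' @export
pair_error_total <- function(a1, a2, q1, q2, smg = NULL) {
  stopifnot(inherits(a1, "ecc_alignment"), inherits(a2, "ecc_alignment"))
  if (!identical(a1$smg_peaks, a2$smg_peaks)) {
    stop("alignments refer to different spectra")
  }
  if (!is.null(smg) && !identical(smg$peaks, a1$smg_peaks)) {
    stop("alignments do not belong to `smg`")
  }
  L <- max(length(q1), length(q2))
  q1 <- rep_len(q1, L); q2 <- rep_len(q2, L)
  n1 <- a1$nodes[a1$nodes$j > 0L, , drop = FALSE]
  n2 <- a2$nodes[a2$nodes$j > 0L, , drop = FALSE]
  overlap_j <- intersect(n1$j, n2$j)
  k1 <- n1$k[match(overlap_j, n1$j)]
  k2 <- n2$k[match(overlap_j, n2$j)]
  if (any(k1 != k2)) return(rep(Inf, L))
  shared_j <- overlap_j
  I_sh <- n1$intensity[match(shared_j, n1$j)]
  I_e1 <- n1$intensity[!n1$j %in% shared_j]
  I_e2 <- n2$intensity[!n2$j %in% shared_j]
  err <- numeric(L)
  if (length(I_sh)) err <- err + colSums(abs(outer(I_sh, q1 + q2, `-`)))
  if (length(I_e1)) err <- err + colSums(abs(outer(I_e1, q1, `-`)))
  if (length(I_e2)) err <- err + colSums(abs(outer(I_e2, q2, `-`)))
  err + a1$n_missing_total * q1 + a2$n_missing_total * q2
}

#' Schedule the node pairs needed by the two-path dynamic program
#'
#' Frontier expansion from the origin pair: when both frontier nodes sit on
#' the same peak both advance (through the successor map `f`); otherwise
#' only the side on the earlier peak advances; a pair of terminal nodes is
#' a sink. Pairs are deduplicated; the returned order is insertion order.
#'
#' @param btg A backtracking graph.
#' @param max_pairs Abort (with a diagnostic) if more pairs than this are
#'   scheduled.
#' @return Tibble of scheduled ordered pairs (`u`, `v` node ids).
#' @export
schedule_pairs <- function(btg, max_pairs = 2e6) {
  stopifnot(inherits(btg, "btg"))
  if (btg_is_empty(btg)) return(tibble::tibble(u = integer(), v = integer()))
  nd <- btg$nodes
  nmax <- max(nd$id) + 1L
  succ <- lapply(nd$id, function(v) btg_successors(btg, v))
  jv_ <- nd$j; kv_ <- nd$k; term <- nd$is_terminal
  origin <- nd$id[nd$is_origin]
  seen <- new.env(parent = emptyenv())
  qu <- integer(0); qv <- integer(0); head <- 1L
  push <- function(u, v) {
    key <- as.character(u * nmax + v)
    if (is.null(get0(key, envir = seen))) {
      assign(key, TRUE, envir = seen)
      qu[length(qu) + 1L] <<- u
      qv[length(qv) + 1L] <<- v
    }
  }
  push(origin, origin)
  while (head <= length(qu)) {
    if (length(qu) > max_pairs) {
      stop("pair schedule exceeds ", max_pairs,
           " pairs; raise `max_pairs` or reduce `max_missing`/peak count")
    }
    u <- qu[head]; v <- qv[head]; head <- head + 1L
    ju <- jv_[u]; jvv <- jv_[v]
    if (term[u] && term[v]) next
    if (ju == jvv) {
      if (kv_[u] != kv_[v]) next                  # invalid: one correct position per peak
      if (term[u] || term[v]) next                # one path stuck at the last peak
      for (up in succ[[u]]) for (vp in succ[[v]]) push(up, vp)
    } else if (ju < jvv) {
      for (up in succ[[u]]) push(up, v)
    } else {
      for (vp in succ[[v]]) push(u, vp)
    }
  }
  tibble::tibble(u = qu, v = qv)
}

# n_missing of the B edge (from = up, to = u); up is terminal-ward of u.
btg_edge_missing <- function(btg) {
  e <- btg$edges
  stats::setNames(e$n_missing, paste(e$from, e$to))
}

#' Two-path dynamic program over the backtracking graph
#'
#' Computes `D(u, v)`: the minimum total intensity error of completing two
#' valid paths from frontier nodes `u` and `v` to the terminal set, for
#' fixed theoretical intensities `q1` (path 1) and `q2` (path 2). The value
#' at the origin pair is the minimum total error over all valid ordered
#' path pairs; a backtrack reconstructs the optimal pair. `q1`/`q2` may be
#' vectors, in which case the whole table is evaluated for every
#' `(q1, q2)` combination at once.
#'
#' Pairs are evaluated terminal-ward first (decreasing sum of peak
#' indices), a topological order of the pair dependencies.
#'
#' @param btg A backtracking graph.
#' @param q1,q2 Theoretical intensities, `> 0` (equal-length vectors).
#' @param schedule Optional precomputed [schedule_pairs()] result.
#' @param max_pairs Passed to [schedule_pairs()].
#' @return Object of class `pair_dp`: the schedule, the table `D`, and
#'   `total` (= `D` at the origin pair, one value per `(q1, q2)`).
#' @export
compute_pair_dp <- function(btg, q1, q2, schedule = NULL, max_pairs = 2e6) {
  stopifnot(inherits(btg, "btg"))
  if (btg_is_empty(btg)) stop("empty backtracking graph: no isoform matches precursor mass")
  if (any(q1 <= 0) || any(q2 <= 0)) stop("theoretical intensities must be positive")
  L <- max(length(q1), length(q2))
  q1 <- rep_len(q1, L); q2 <- rep_len(q2, L)
  if (is.null(schedule)) schedule <- schedule_pairs(btg, max_pairs = max_pairs)
  nd <- btg$nodes
  nmax <- max(nd$id) + 1L
  succ <- lapply(nd$id, function(v) btg_successors(btg, v))
  miss <- btg_edge_missing(btg)
  jv_ <- nd$j; kv_ <- nd$k; term <- nd$is_terminal; Iv <- nd$intensity
  np <- nrow(schedule)
  row_of <- stats::setNames(seq_len(np), schedule$u * nmax + schedule$v)
  D <- matrix(Inf, nrow = np, ncol = L)
  ord <- order(jv_[schedule$u] + jv_[schedule$v], decreasing = TRUE)
  for (p in ord) {
    u <- schedule$u[p]; v <- schedule$v[p]
    ju <- jv_[u]; jvv <- jv_[v]
    if (ju == jvv) {
      if (kv_[u] != kv_[v]) next # Inf: same peak, different corrections
      err <- if (ju > 0L) abs(Iv[u] - q1 - q2) else numeric(L)
      if (term[u] && term[v]) {
        D[p, ] <- err
      } else if (term[u] || term[v]) {
        # the non-terminal side can never advance past the last peak
      } else {
        best <- rep(Inf, L)
        for (up in succ[[u]]) {
          pen_u <- miss[[paste(up, u)]] * q1
          for (vp in succ[[v]]) {
            r <- row_of[[as.character(up * nmax + vp)]]
            cand <- pen_u + miss[[paste(vp, v)]] * q2 + D[r, ]
            best <- pmin(best, cand)
          }
        }
        D[p, ] <- err + best
      }
    } else if (ju < jvv) {
      err <- if (ju > 0L) abs(Iv[u] - q1) else numeric(L)
      best <- rep(Inf, L)
      for (up in succ[[u]]) {
        r <- row_of[[as.character(up * nmax + v)]]
        best <- pmin(best, miss[[paste(up, u)]] * q1 + D[r, ])
      }
      D[p, ] <- err + best
    } else {
      err <- if (jvv > 0L) abs(Iv[v] - q2) else numeric(L)
      best <- rep(Inf, L)
      for (vp in succ[[v]]) {
        r <- row_of[[as.character(u * nmax + vp)]]
        best <- pmin(best, miss[[paste(vp, v)]] * q2 + D[r, ])
      }
      D[p, ] <- err + best
    }
  }
  origin <- nd$id[nd$is_origin]
  orow <- row_of[[as.character(origin * nmax + origin)]]
  structure(
    list(schedule = schedule, D = D, total = D[orow, ], q1 = q1, q2 = q2,
         origin_row = orow, btg = btg),
    class = "pair_dp"
  )
}

#' @export
print.pair_dp <- function(x, ...) {
  cat(sprintf("<two-path DP> %d scheduled pairs, %d intensity combination(s); min total error %g\n",
              nrow(x$schedule), length(x$total), min(x$total)))
  invisible(x)
}

# Reconstruct the argmin pair of paths for a scalar-(q1, q2) pair_dp.
backtrack_pair <- function(dp) {
  stopifnot(length(dp$q1) == 1L)
  btg <- dp$btg
  nd <- btg$nodes
  nmax <- max(nd$id) + 1L
  succ <- lapply(nd$id, function(v) btg_successors(btg, v))
  miss <- btg_edge_missing(btg)
  jv_ <- nd$j; term <- nd$is_terminal
  row_of <- stats::setNames(seq_len(nrow(dp$schedule)),
                            dp$schedule$u * nmax + dp$schedule$v)
  Dcol <- dp$D[, 1L]
  q1 <- dp$q1; q2 <- dp$q2
  origin <- nd$id[nd$is_origin]
  u <- origin; v <- origin
  p1 <- u; p2 <- v
  repeat {
    if (term[u] && term[v]) break
    ju <- jv_[u]; jvv <- jv_[v]
    if (ju == jvv) {
      best <- Inf; pick <- NULL
      for (up in succ[[u]]) for (vp in succ[[v]]) {
        r <- row_of[[as.character(up * nmax + vp)]]
        cand <- miss[[paste(up, u)]] * q1 + miss[[paste(vp, v)]] * q2 + Dcol[r]
        if (cand < best) { best <- cand; pick <- c(up, vp) }
      }
      if (is.null(pick)) stop("backtrack failed: dead frontier pair")
      u <- pick[1]; v <- pick[2]
      p1 <- c(p1, u); p2 <- c(p2, v)
    } else if (ju < jvv) {
      best <- Inf; pick <- NULL
      for (up in succ[[u]]) {
        r <- row_of[[as.character(up * nmax + v)]]
        cand <- miss[[paste(up, u)]] * q1 + Dcol[r]
        if (cand < best) { best <- cand; pick <- up }
      }
      u <- pick; p1 <- c(p1, u)
    } else {
      best <- Inf; pick <- NULL
      for (vp in succ[[v]]) {
        r <- row_of[[as.character(u * nmax + vp)]]
        cand <- miss[[paste(vp, v)]] * q2 + Dcol[r]
        if (cand < best) { best <- cand; pick <- vp }
      }
      v <- pick; p2 <- c(p2, v)
    }
  }
  a1 <- new_alignment(nd[match(p1, nd$id), , drop = FALSE], btg)
  a2 <- new_alignment(nd[match(p2, nd$id), , drop = FALSE], btg)
  list(P1 = a1, P2 = a2)
}
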