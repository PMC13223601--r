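# Independent brute-force oracles: exhaustive enumeration over concrete
# edge-choice paths, peak subsequences and induced correction values.
# Deliberately naive; none of the production E-table / DP code is reused.

# every concrete edge-choice path x_s -> x_i as a vector of edge masses
oracle_paths <- function(g, s, i) {
  if (s == i) return(list(integer()))
  opts <- hommtm:::pmg_edge_options(g, s + 1L)
  out <- list()
  for (m in opts$mass) {
    for (p in oracle_paths(g, s + 1L, i)) {
      out[[length(out) + 1L]] <- c(m, p)
    }
  }
  out
}

align_key <- function(nodes) {
  paste(apply(nodes, 1L, paste, collapse = ":"), collapse = " ")
}

# the full set of valid alignments, as canonical "i:j:k ..." strings
oracle_alignment_set <- function(g, h, delta_ticks, max_missing) {
  pk <- h$peaks$mass
  obs <- pk[-1L]
  if (!isTRUE(h$terminal_observed)) obs <- obs[-length(obs)]
  n <- g$n; m <- h$m
  found <- character()
  extend <- function(rows) {
    last <- rows[nrow(rows), ]
    if (last[1] == n && last[2] == m) {
      found[length(found) + 1L] <<- align_key(rows)
      return(invisible())
    }
    if (last[1] == n || last[2] == m) return(invisible())
    for (i2 in (last[1] + 1L):min(n, last[1] + 1L + max_missing)) {
      for (j2 in (last[2] + 1L):m) {
        tried <- integer()
        for (p in oracle_paths(g, last[1], i2)) {
          mass <- sum(p)
          k2 <- (pk[last[2] + 1L] + last[3]) + mass - pk[j2 + 1L]
          if (abs(k2) > delta_ticks || k2 %in% tried) next
          if (i2 - last[1] > 1L) {
            inter <- (pk[last[2] + 1L] + last[3]) + cumsum(p)[-length(p)]
            blocked <- any(vapply(inter, function(x) {
              any(abs(obs - x) <= delta_ticks)
            }, logical(1)))
            if (blocked) next
          }
          tried <- c(tried, k2)
          extend(rbind(rows, c(i2, j2, k2)))
        }
      }
    }
  }
  extend(matrix(c(0L, 0L, 0L), nrow = 1))
  sort(unique(found))
}

# random small instance: a peptide, its PMG and a spectrum assembled from
# one or two isoform paths with jitter, dropouts and decoy masses
random_small_instance <- function(delta_ticks = sample(0:1, 1)) {
  n <- sample(3:6, 1)
  res <- sample(c("A", "G", "S", "T", "V", "L", "D", "K"), n, replace = TRUE)
  sty <- which(res %in% c("S", "T"))
  if (length(sty) < 2L) {
    res[sample(n, 2)] <- "S"
  }
  peptide <- paste(res, collapse = "")
  g <- build_pmg(peptide, list(mod_phospho()), scale = 1)
  sites <- which(res %in% c("S", "T", "Y"))
  nmod <- sample(0:min(1, length(sites)), 1)
  place <- function() sort(sample(sites, nmod))
  pm <- function(pos) {
    m <- hommtm:::scale_and_round(residue_mass(res), 1)
    m[pos] <- m[pos] + 80L
    cumsum(m)
  }
  p1 <- place(); p2 <- place()
  pref <- sort(unique(c(pm(p1), pm(p2))))
  total <- pref[length(pref)]
  keep <- stats::runif(length(pref)) > 0.25
  keep[length(pref)] <- TRUE # keep the terminal observed
  masses <- pref[keep] + sample((-delta_ticks):delta_ticks, sum(keep), replace = TRUE)
  decoys <- sample(5:(total - 5), sample(0:2, 1))
  masses <- sort(unique(c(masses, decoys)))
  masses <- masses[masses > 0 & masses <= total]
  h <- build_smg(tibble::tibble(mass = masses,
                                intensity = stats::runif(length(masses), 1, 120)),
                 precursor_mass = total + hommtm:::MASS_H2O, scale = 1,
                 delta = delta_ticks)
  list(pmg = g, smg = h, delta_ticks = delta_ticks)
}

# brute-force minimum pair error over all ordered alignment pairs
oracle_pair_min <- function(alignments, q1, q2) {
  best <- Inf
  for (a in alignments) for (b in alignments) {
    best <- min(best, pair_error_total(a, b, q1, q2))
  }
  best
}
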