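#' Read an MGF (Mascot Generic Format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`, `CHARGE`
#' and peak lines (`m/z intensity`). Blocks missing `PEPMASS` (or without
#' peaks) are skipped with a warning. The neutral precursor mass is derived
#' as `pepmass * z - z * proton` (charge defaults to 1 when absent).
#'
#' @param path Path to an MGF file.
#' @return Tibble with one row per spectrum: `spectrum_id`, `pepmass`,
#'   `charge`, `precursor_mass` and a `peaks` list-column of
#'   (`mass`, `intensity`) tibbles.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L; blk <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      blk <- blk + 1L
      title <- NA_character_; pepmass <- NA_real_; charge <- 1L
      mz <- numeric(); inten <- numeric()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          title <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- suppressWarnings(as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1]))
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- suppressWarnings(as.integer(gsub("[^0-9]", "", ln)))
        } else if (grepl("^[0-9]", ln)) {
          xs <- suppressWarnings(as.numeric(strsplit(ln, "[\\t ]+")[[1]]))
          if (length(xs) >= 2 && !anyNA(xs[1:2])) {
            mz <- c(mz, xs[1]); inten <- c(inten, xs[2])
          }
        }
        i <- i + 1L
      }
      if (is.na(pepmass)) {
        warning("MGF block ", blk, " skipped: missing PEPMASS")
      } else {
        if (is.na(charge) || charge < 1L) charge <- 1L
        recs[[length(recs) + 1L]] <- tibble::tibble(
          spectrum_id = ifelse(is.na(title), paste0("spectrum_", blk), title),
          pepmass = pepmass, charge = charge,
          precursor_mass = pepmass * charge - charge * MASS_PROTON,
          peaks = list(tibble::tibble(mass = mz, intensity = inten))
        )
      }
    }
    i <- i + 1L
  }
  if (length(recs) == 0L) {
    return(tibble::tibble(spectrum_id = character(), pepmass = numeric(),
                          charge = integer(), precursor_mass = numeric(),
                          peaks = list()))
  }
  dplyr::bind_rows(recs)
}

#' Write spectra to an MGF file
#'
#' Accepts either a tibble shaped like [read_mgf()] output or a list of
#' [simulate_spectrum()] results (whose prefix-space peak lists are written
#' as-is, with a `SPACE=prefix` tag in the title).
#'
#' @param x Spectra (see Details).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  if (inherits(x, "sim_spectrum")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "sim_spectrum")) {
    x <- dplyr::bind_rows(lapply(seq_along(x), function(s) {
      sim <- x[[s]]
      tibble::tibble(
        spectrum_id = sprintf("sim_%d SPACE=prefix", s),
        pepmass = sim$precursor_mass + MASS_PROTON, charge = 1L,
        precursor_mass = sim$precursor_mass,
        peaks = list(sim$peaks[, c("mass", "intensity")])
      )
    }))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(x))) {
    pk <- x$peaks[[r]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", x$spectrum_id[r]),
      sprintf("PEPMASS=%.6f", x$pepmass[r]),
      sprintf("CHARGE=%d+", x$charge[r]),
      sprintf("%.6f %.6g", pk$mass, pk$intensity),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Read a PSM table
#'
#' Tab-separated with header columns `spectrum_id`, `peptide`,
#' `mod_counts`; the latter holds `name:count` pairs separated by
#' semicolons (e.g. `"phospho:1;oxidation:0"`, empty for none). Rows with
#' unknown residues or malformed counts are rejected with a warning.
#'
#' @param path Path to the TSV file.
#' @return Tibble (`spectrum_id`, `peptide`, `mod_counts` list-column of
#'   named integer vectors).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("cannot read PSM table: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("spectrum_id", "peptide", "mod_counts")
  if (!all(need %in% names(df))) {
    stop("PSM table must have columns: ", paste(need, collapse = ", "))
  }
  keep <- logical(nrow(df)); counts <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    ok <- tryCatch({
      split_peptide(df$peptide[r])
      counts[[r]] <- parse_mod_counts(df$mod_counts[r])
      TRUE
    }, error = function(e) {
      warning("PSM row ", r, " rejected: ", conditionMessage(e))
      FALSE
    })
    keep[r] <- ok
  }
  tibble::tibble(
    spectrum_id = df$spectrum_id[keep],
    peptide = df$peptide[keep],
    mod_counts = counts[keep]
  )
}

parse_mod_counts <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(stats::setNames(integer(), character()))
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed mod_counts: ", x)
  cnt <- suppressWarnings(as.integer(vapply(kv, `[`, character(1), 2)))
  if (anyNA(cnt)) stop("malformed mod_counts: ", x)
  stats::setNames(cnt, trimws(vapply(kv, `[`, character(1), 1)))
}

results_table <- function(results, spectrum_ids = NULL) {
  if (inherits(results, "isoform_quant")) results <- list(results)
  if (length(results) == 0L) {
    return(tibble::tibble(
      spectrum_id = character(), status = character(),
      isoform_1 = character(), isoform_2 = character(),
      abundance_1 = numeric(), abundance_2 = numeric(),
      q1 = numeric(), q2 = numeric(), total_error = numeric(),
      hommtm_type = character(), n_missing_peaks = integer()
    ))
  }
  if (is.null(spectrum_ids)) spectrum_ids <- paste0("spectrum_", seq_along(results))
  rows <- lapply(seq_along(results), function(s) {
    x <- results[[s]]
    iso <- x$isoforms
    tibble::tibble(
      spectrum_id = spectrum_ids[s],
      status = x$status,
      isoform_1 = if (nrow(iso) >= 1) iso$isoform[1] else NA_character_,
      isoform_2 = if (nrow(iso) >= 2) iso$isoform[2] else NA_character_,
      abundance_1 = if (nrow(iso) >= 1) iso$abundance[1] else NA_real_,
      abundance_2 = if (nrow(iso) >= 2) iso$abundance[2] else NA_real_,
      q1 = x$q1, q2 = x$q2, total_error = x$total_error,
      hommtm_type = x$hommtm_type,
      n_missing_peaks = if (nrow(iso)) sum(iso$n_missing) else NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

#' Write identification results
#'
#' TSV output prints abundances as one-decimal percentages (`"18.2%"`);
#' JSON keeps full numeric precision. [read_results()] reads either back.
#'
#' @param results A list of `isoform_quant` objects (or one), or an
#'   already-built results tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param spectrum_ids Optional ids, parallel to `results`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json"),
                          spectrum_ids = NULL) {
  format <- match.arg(format)
  tb <- if (is.data.frame(results)) results else results_table(results, spectrum_ids)
  if (format == "json") {
    jsonlite::write_json(tb, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- tb
    out$abundance_1 <- ifelse(is.na(tb$abundance_1), "",
                              sprintf("%.1f%%", 100 * tb$abundance_1))
    out$abundance_2 <- ifelse(is.na(tb$abundance_2), "",
                              sprintf("%.1f%%", 100 * tb$abundance_2))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read results file: ", path)
  if (format == "json") {
    tb <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tb <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                              stringsAsFactors = FALSE))
    pct <- function(x) ifelse(is.na(x) | x == "", NA_real_,
                              as.numeric(sub("%", "", x, fixed = TRUE)) / 100)
    tb$abundance_1 <- pct(as.character(tb$abundance_1))
    tb$abundance_2 <- pct(as.character(tb$abundance_2))
  }
  tb
}

#' Read a modification configuration file
#'
#' Tab-separated with header `name`, `unimod`, `targets`, `delta_mass`;
#' `targets` lists one-letter codes without separators (e.g. `STY`) or the
#' literal `N-term`.
#'
#' @param path Path to the TSV file.
#' @return Named list of [modification()] objects.
#' @export
read_mod_config <- function(path) {
  if (!file.exists(path)) stop("cannot read modification config: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "unimod", "targets", "delta_mass")
  if (!all(need %in% names(df))) {
    stop("modification config must have columns: ", paste(need, collapse = ", "))
  }
  mods <- lapply(seq_len(nrow(df)), function(r) {
    tg <- df$targets[r]
    targets <- if (identical(tg, "N-term")) "N-term" else
      strsplit(tg, "", fixed = TRUE)[[1]]
    modification(df$name[r], df$unimod[r], targets, df$delta_mass[r])
  })
  stats::setNames(mods, tolower(df$name))
}

#' Read or write a flat key-value run configuration
#'
#' Lines of the form `key = value`; numbers are coerced. Unknown keys are
#' kept, so the file can carry tool-specific settings.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[`, character(1), 1)))
}

#' @rdname read_run_config
#' @param config Named list to write.
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' Default run configuration
#'
#' The tolerances and knobs of the pipeline with their defaults: `scale`
#' (ticks per Da), `delta` (per-peak tolerance, Da), `frag_charge`,
#' `max_missing`, `grid_step` (percent), `support_tolerance` (Da) and
#' `seed`.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(scale = 100, delta = 0.1, frag_charge = 1, max_missing = 2,
       grid_step = 1, support_tolerance = 0.1, seed = 1)
}
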