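## Reference peak-list libraries: construction, validation, indexing,
## filtering.  A library is a tibble with one row per metabolite record and a
## `peaks` list-column of (ppm, height) tibbles; a peak index (canonical ppm
## coordinate -> record ids) is kept as an attribute for fast lookup.

#' Canonicalize a chemical shift to 0.01 ppm precision
#'
#' Reference peak lists and query peaks are stored on a common 0.01 ppm grid
#' so that exact matching is well defined.  Rounding uses
#' round-half-away-from-zero, so the result is reproducible across platforms
#' (unlike IEEE round-half-even).
#'
#' @param x Numeric vector of chemical shifts in ppm.  Must be finite.
#' @return Numeric vector of the same length, each value a multiple of 0.01.
#'   Idempotent: canonical input is returned unchanged.
#' @examples
#' canonicalize_ppm(c(1.004, 1.005, -1.005))
#' @export
canonicalize_ppm <- function(x) {
  if (!is.numeric(x)) {
    abort("`x` must be numeric.", class = "specmatch_invalid_value")
  }
  if (length(x) && any(!is.finite(x))) {
    abort("chemical shifts must be finite.", class = "specmatch_invalid_value")
  }
  ## small eps guards against binary representation of exact halves
  ## (e.g. 1.005 is stored just below 1.005)
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

## integer centi-ppm used internally for exact coordinate comparison
cppm <- function(ppm) as.integer(round(ppm * 100))

format_ppm <- function(ppm) sprintf("%.2f", ppm)

#' Build a canonical peak table
#'
#' Canonicalizes ppm values and collapses peaks that land on the same 0.01 ppm
#' coordinate, keeping the larger height (matching is coordinate-based, so
#' duplicates would double-count).
#'
#' @param ppm Numeric vector of chemical shifts (ppm).
#' @param height Numeric vector of nonnegative relative intensities; recycled
#'   to `length(ppm)` if scalar.  Defaults to 1.
#' @param warn_duplicates Warn when canonicalization collapses peaks.
#' @return A tibble with columns `ppm` (canonical, unique, ascending) and
#'   `height`.
#' @export
peak_tbl <- function(ppm, height = 1, warn_duplicates = FALSE) {
  ppm <- canonicalize_ppm(ppm)
  if (length(height) == 1L) height <- rep(height, length(ppm))
  if (length(height) != length(ppm)) {
    abort("`ppm` and `height` must have the same length.",
          class = "specmatch_invalid_value")
  }
  if (length(height) && (any(!is.finite(height)) || any(height < 0))) {
    abort("peak heights must be finite and nonnegative.",
          class = "specmatch_invalid_value")
  }
  tb <- tibble(ppm = ppm, height = as.numeric(height))
  key <- cppm(tb$ppm)
  if (anyDuplicated(key)) {
    if (warn_duplicates) {
      warn("duplicate canonical ppm coordinates collapsed; larger height kept.")
    }
    tb <- tb |>
      dplyr::group_by(key = cppm(.data$ppm)) |>
      dplyr::summarise(ppm = .data$ppm[1], height = max(.data$height),
                       .groups = "drop") |>
      dplyr::select("ppm", "height")
  }
  dplyr::arrange(tb, .data$ppm)
}

#' Create a single metabolite record
#'
#' A record is one curated reference peak list plus its acquisition metadata.
#'
#' @param id Unique identifier string.
#' @param name Display name.
#' @param peaks A two-column data frame (`ppm`, `height`) or numeric vector of
#'   ppm values; canonicalized via [peak_tbl()].  Must be nonempty.
#' @param source Provenance label, one of `"HMDB-like"`, `"MMCD-like"`,
#'   `"user"`.
#' @param mtype Metabolite type, one of drug, food additive, mammalian,
#'   microbial, plant, synthetic/industrial chemical.
#' @param ph Sample pH in \[3, 10\].
#' @param solvent One of water, CDCl3, CD3OD, 5% DMSO.
#' @param frequency Spectrometer frequency in MHz (400/500/600 or a user
#'   value).
#' @return A one-row tibble with a `peaks` list-column.
#' @examples
#' metabolite_record("M1", "alanine", peaks = c(1.48, 3.78))
#' @export
metabolite_record <- function(id, name = id, peaks,
                              source = "user", mtype = "mammalian",
                              ph = 7.00, solvent = "water",
                              frequency = 500) {
  if (is.numeric(peaks)) peaks <- peak_tbl(peaks)
  if (is.data.frame(peaks)) peaks <- peak_tbl(peaks$ppm, peaks$height)
  validate_record_fields(id, name, source, mtype, ph, solvent, frequency, peaks)
  tibble(
    id = as.character(id), name = as.character(name),
    source = source, mtype = mtype, ph = as.numeric(ph),
    solvent = solvent, frequency = as.numeric(frequency),
    peaks = list(peaks)
  )
}

validate_record_fields <- function(id, name, source, mtype, ph, solvent,
                                   frequency, peaks) {
  bad <- function(msg) abort(msg, class = "specmatch_validation_error")
  if (length(id) != 1L || !nzchar(id)) bad("record `id` must be a nonempty string.")
  if (!source %in% source_levels) {
    bad(sprintf("record '%s': unknown source '%s'.", id, source))
  }
  if (!mtype %in% mtype_levels) {
    bad(sprintf("record '%s': unknown mtype '%s'.", id, mtype))
  }
  if (!is.numeric(ph) || ph < ph_range_allowed[1] || ph > ph_range_allowed[2]) {
    bad(sprintf("record '%s': ph must lie in [%.2f, %.2f].",
                id, ph_range_allowed[1], ph_range_allowed[2]))
  }
  if (!solvent %in% solvent_levels) {
    bad(sprintf("record '%s': unknown solvent '%s'.", id, solvent))
  }
  if (!is.numeric(frequency) || frequency <= 0) {
    bad(sprintf("record '%s': frequency must be a positive MHz value.", id))
  }
  if (!is.data.frame(peaks) || nrow(peaks) == 0L) {
    bad(sprintf("record '%s': peak list must be nonempty.", id))
  }
  invisible(TRUE)
}

#' Assemble a reference library from metabolite records
#'
#' Validates every record, checks id uniqueness, and builds the peak index
#' (canonical ppm coordinate to the ids of all records with a peak there).
#'
#' @param records A tibble of records (rows as produced by
#'   [metabolite_record()]), or a list of such one-row tibbles.
#' @return A `ref_library`: a tibble of records carrying a `peak_index`
#'   attribute.
#' @examples
#' lib <- ref_library(list(
#'   metabolite_record("A", peaks = c(1.00, 2.00)),
#'   metabolite_record("B", peaks = 3.00)
#' ))
#' library_size(lib)
#' @export
ref_library <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- dplyr::bind_rows(records)
  }
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    abort("a reference library must contain at least one record.",
          class = "specmatch_validation_error")
  }
  for (i in seq_len(nrow(records))) {
    validate_record_fields(
      records$id[i], records$name[i], records$source[i], records$mtype[i],
      records$ph[i], records$solvent[i], records$frequency[i],
      records$peaks[[i]]
    )
  }
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    abort(sprintf("duplicate record id(s): %s.", paste(dup, collapse = ", ")),
          class = "specmatch_validation_error")
  }
  records <- dplyr::arrange(records, .data$id)
  new_ref_library(records)
}

new_ref_library <- function(records) {
  structure(records,
            peak_index = build_peak_index(records),
            class = c("ref_library", class(tibble())))
}

build_peak_index <- function(records) {
  long <- tidyr::unnest(records[, c("id", "peaks")], "peaks")
  split(long$id, format_ppm(long$ppm))
}

#' @rdname ref_library
#' @param lib A `ref_library`.
#' @export
library_size <- function(lib) nrow(lib)

#' @rdname ref_library
#' @export
peak_index <- function(lib) attr(lib, "peak_index")

#' @export
print.ref_library <- function(x, ...) {
  npk <- sum(vapply(x$peaks, nrow, integer(1)))
  cat(sprintf("# Reference library: %d records, %d peaks, %d indexed coordinates\n",
              nrow(x), npk, length(peak_index(x))))
  NextMethod()
}

#' Filter library records by metadata features
#'
#' Returns the sub-library of records satisfying every stated constraint, the
#' screening step applied by all search methods ("features obey F").
#'
#' @param lib A [ref_library()].
#' @param features Named list of constraints.  Recognised keys: `mtype`,
#'   `solvent`, `source`, `frequency` (each a vector of allowed values) and
#'   `ph` (length-2 numeric range, inclusive).  An empty list returns the
#'   library unchanged.
#' @return A `ref_library` view containing exactly the matching records (its
#'   peak index rebuilt).  May be empty (0 rows); searches treat that as a
#'   configuration error.
#' @examples
#' lib <- ref_library(list(
#'   metabolite_record("A", peaks = 1, solvent = "water", ph = 7),
#'   metabolite_record("B", peaks = 2, solvent = "CDCl3", ph = 3)
#' ))
#' filter_records(lib, list(solvent = "water"))
#' @export
filter_records <- function(lib, features = list()) {
  stopifnot(inherits(lib, "ref_library"))
  if (is.null(features)) features <- list()
  if (!length(features)) return(lib)
  known <- c("mtype", "ph", "solvent", "frequency", "source")
  unknown <- setdiff(names(features), known)
  if (length(unknown)) {
    abort(sprintf("unknown feature filter key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "specmatch_config_error")
  }
  keep <- rep(TRUE, nrow(lib))
  for (key in names(features)) {
    val <- features[[key]]
    if (key == "ph") {
      if (length(val) != 2L || !is.numeric(val)) {
        abort("`ph` filter must be a numeric range c(min, max).",
              class = "specmatch_config_error")
      }
      keep <- keep & lib$ph >= val[1] & lib$ph <= val[2]
    } else {
      keep <- keep & lib[[key]] %in% val
    }
  }
  out <- as_tibble(lib)[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    ## an empty view is representable (searches reject it), so bypass the
    ## k > 0 constructor check but keep the class and (empty) index
    return(structure(out, peak_index = list(),
                     class = c("ref_library", class(tibble()))))
  }
  new_ref_library(out)
}
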