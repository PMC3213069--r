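## Text serialization for reference libraries.
##
## Native format (UTF-8, TAB-separated, '#' comments):
##   one block per metabolite; a header line
##     >id <TAB> name <TAB> source <TAB> mtype <TAB> ph <TAB> solvent <TAB> frequency
##   followed by one "ppm<TAB>height" line per peak.  Records are written
##   sorted by id and heights at full precision, so save -> load -> save is
##   byte-stable.

parse_num <- function(tok, path, lineno, what) {
  x <- suppressWarnings(as.numeric(tok))
  if (any(is.na(x))) {
    abort(sprintf("%s: line %d: expected numeric %s, got '%s'.",
                  path, lineno, what, paste(tok, collapse = " ")),
          class = "specmatch_parse_error")
  }
  x
}

#' Read a reference library from a text file
#'
#' @param path File to read.
#' @param dialect `"native"` for the package's block format (see
#'   [write_library()]), or `"hmdb-peaklist"` for a directory-of-peak-files
#'   layout: `path` is then a TAB-separated metadata sidecar with columns
#'   `id`, `name`, `source`, `mtype`, `ph`, `solvent`, `frequency`, `file`,
#'   where `file` names a two-column (ppm, height) text file relative to the
#'   sidecar's directory (comma or whitespace separated, blank lines and
#'   `#` comments tolerated).
#' @return A validated [ref_library()]; all ppm canonicalized and the peak
#'   index built.
#' @export
read_library <- function(path, dialect = c("native", "hmdb-peaklist")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("library file '%s' does not exist.", path),
          class = "specmatch_io_error")
  }
  if (dialect == "native") read_library_native(path) else read_library_hmdb(path)
}

read_library_native <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list()
  cur <- NULL
  flush_record <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (length(cur$ppm) == 0L) {
      abort(sprintf("%s: record '%s' has an empty peak list.", path, cur$id),
            class = "specmatch_validation_error")
    }
    metabolite_record(
      id = cur$id, name = cur$name, source = cur$source, mtype = cur$mtype,
      ph = cur$ph, solvent = cur$solvent, frequency = cur$frequency,
      peaks = peak_tbl(cur$ppm, cur$height, warn_duplicates = TRUE)
    )
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i], which = "right")
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) {
      records <- c(records, list(flush_record(cur)))
      fields <- strsplit(substring(ln, 2L), "\t", fixed = TRUE)[[1]]
      if (length(fields) != 7L) {
        abort(sprintf("%s: line %d: header needs 7 TAB-separated fields, got %d.",
                      path, i, length(fields)),
              class = "specmatch_parse_error")
      }
      cur <- list(id = fields[1], name = fields[2], source = fields[3],
                  mtype = fields[4],
                  ph = parse_num(fields[5], path, i, "ph"),
                  solvent = fields[6],
                  frequency = parse_num(fields[7], path, i, "frequency"),
                  ppm = numeric(), height = numeric())
    } else {
      if (is.null(cur)) {
        abort(sprintf("%s: line %d: peak line before any record header.", path, i),
              class = "specmatch_parse_error")
      }
      tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(tok) != 2L) {
        abort(sprintf("%s: line %d: expected 'ppm<TAB>height'.", path, i),
              class = "specmatch_parse_error")
      }
      cur$ppm <- c(cur$ppm, parse_num(tok[1], path, i, "ppm"))
      cur$height <- c(cur$height, parse_num(tok[2], path, i, "height"))
    }
  }
  records <- c(records, list(flush_record(cur)))
  records <- records[!vapply(records, is.null, logical(1))]
  if (!length(records)) {
    abort(sprintf("%s: no records found.", path),
          class = "specmatch_validation_error")
  }
  ref_library(records)
}

read_library_hmdb <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                            fileEncoding = "UTF-8")
  need <- c("id", "name", "source", "mtype", "ph", "solvent", "frequency", "file")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("%s: sidecar is missing column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")),
          class = "specmatch_parse_error")
  }
  base <- dirname(path)
  records <- lapply(seq_len(nrow(meta)), function(i) {
    pk_path <- file.path(base, meta$file[i])
    if (!file.exists(pk_path)) {
      abort(sprintf("%s: peak file '%s' does not exist.", path, pk_path),
            class = "specmatch_io_error")
    }
    pk <- read_two_columns(pk_path)
    metabolite_record(
      id = meta$id[i], name = meta$name[i], source = meta$source[i],
      mtype = meta$mtype[i], ph = meta$ph[i], solvent = meta$solvent[i],
      frequency = meta$frequency[i],
      peaks = peak_tbl(pk$x, pk$y, warn_duplicates = TRUE)
    )
  })
  ref_library(records)
}

## shared lenient two-numeric-column reader (whitespace or comma separated,
## '#' comments and blank lines skipped); used by the hmdb-peaklist dialect
## and by the spectrum/peak-list readers
read_two_columns <- function(path, min_rows = 0L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  xs <- numeric(); ys <- numeric()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) != 2L) {
      abort(sprintf("%s: line %d: expected two numeric columns.", path, i),
            class = "specmatch_parse_error")
    }
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v))) {
      abort(sprintf("%s: line %d: non-numeric token '%s'.",
                    path, i, tok[which(is.na(v))[1]]),
            class = "specmatch_parse_error")
    }
    xs <- c(xs, v[1]); ys <- c(ys, v[2])
  }
  if (length(xs) < min_rows) {
    abort(sprintf("%s: needs at least %d data rows, found %d.",
                  path, min_rows, length(xs)),
          class = "specmatch_parse_error")
  }
  list(x = xs, y = ys)
}

#' Write a reference library to the native text format
#'
#' Records are sorted by id and written with full-precision heights, so that
#' [read_library()] reproduces the library exactly and re-saving is
#' byte-stable.
#'
#' @param lib A valid, nonempty [ref_library()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "ref_library"))
  if (nrow(lib) == 0L) {
    abort("refusing to write an empty library.",
          class = "specmatch_validation_error")
  }
  ord <- order(lib$id)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) {
                    abort(sprintf("cannot open '%s' for writing: %s",
                                  path, conditionMessage(e)),
                          class = "specmatch_io_error")
                  })
  on.exit(close(con))
  writeLines("# specmatch reference library v1", con)
  for (i in ord) {
    writeLines(sprintf(">%s\t%s\t%s\t%s\t%.2f\t%s\t%s",
                       lib$id[i], lib$name[i], lib$source[i], lib$mtype[i],
                       lib$ph[i], lib$solvent[i],
                       formatC(lib$frequency[i], format = "g", digits = 15)),
               con)
    pk <- lib$peaks[[i]]
    writeLines(sprintf("%s\t%s", format_ppm(pk$ppm),
                       formatC(pk$height, format = "g", digits = 17)),
               con)
  }
  invisible(path)
}
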