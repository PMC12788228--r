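#' Read a digitizer spiral trajectory file
#'
#' Reads one drawing from a plain-text trajectory file. Two dialects are
#' supported. `"svc"` is whitespace-separated with seven columns in the order
#' `x y t pen_state azimuth altitude pressure`, optionally preceded by
#' `#`-prefixed header lines of `key=value` pairs (`subject_id`, `hand`,
#' `sampling_rate`). `"csv"` is comma-separated with those column names in a
#' header row; `#` lines are treated the same way.
#'
#' @param path file to read.
#' @param dialect `"svc"` (whitespace table) or `"csv"`.
#' @param sampling_rate fallback sampling rate in Hz when the file header does
#'   not state one.
#' @return a [spiral_record()].
#' @export
read_spiral <- function(path, dialect = c("svc", "csv"), sampling_rate = 200) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  header <- parse_svc_header(lines[startsWith(trimws(lines), "#")])
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  body_lineno <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))

  if (length(body) < 2L) {
    rlang::abort(sprintf("file %s too short: fewer than 2 data rows.", path))
  }

  if (dialect == "svc") {
    nf <- utils::count.fields(textConnection(body))
    bad <- which(is.na(nf) | nf != 7L)
    if (length(bad) > 0L) {
      rlang::abort(sprintf(
        "malformed row in %s at line %d: expected 7 whitespace-separated fields.",
        path, body_lineno[bad[1L]]))
    }
    df <- utils::read.table(textConnection(body), header = FALSE,
                            colClasses = "numeric",
                            col.names = svc_columns())
  } else {
    df <- utils::read.csv(textConnection(body), header = TRUE)
    missing <- setdiff(svc_columns(), names(df))
    if (length(missing) > 0L) {
      rlang::abort(paste0("csv trajectory file is missing columns: ",
                          paste(missing, collapse = ", ")))
    }
    df <- df[svc_columns()]
    not_num <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(not_num) > 0L) {
      rlang::abort(paste0("non-numeric values in columns: ",
                          paste(not_num, collapse = ", ")))
    }
  }

  spiral_record(
    x = df$x, y = df$y, t = df$t, pen_state = df$pen_state,
    azimuth = df$azimuth, altitude = df$altitude, pressure = df$pressure,
    subject_id = header$subject_id %||% tools::file_path_sans_ext(basename(path)),
    hand = header$hand %||% "right",
    sampling_rate = header$sampling_rate %||% sampling_rate
  )
}

svc_columns <- function() {
  c("x", "y", "t", "pen_state", "azimuth", "altitude", "pressure")
}

parse_svc_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    for (kv in strsplit(ln, "\\s+")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L) out[[parts[1L]]] <- parts[2L]
    }
  }
  if (!is.null(out$sampling_rate)) {
    out$sampling_rate <- suppressWarnings(as.numeric(out$sampling_rate))
  }
  out
}

#' Write a spiral record to a trajectory file
#'
#' Inverse of [read_spiral()]: numbers are printed with enough digits that a
#' write/read round trip reproduces every channel to better than 1e-9 relative
#' precision.
#'
#' @param record a valid [spiral_record()].
#' @param path output file.
#' @param dialect `"svc"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spiral <- function(record, path, dialect = c("svc", "csv")) {
  dialect <- match.arg(dialect)
  validate_spiral_record(record)
  header <- sprintf("# subject_id=%s hand=%s sampling_rate=%s",
                    subject_id(record), record_hand(record),
                    format(sampling_rate(record), digits = 15))
  df <- tibble::as_tibble(record)[svc_columns()]
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  if (dialect == "svc") {
    body <- do.call(paste, c(lapply(df, format_numeric), list(sep = " ")))
    writeLines(body, con)
  } else {
    writeLines(paste(svc_columns(), collapse = ","), con)
    body <- do.call(paste, c(lapply(df, format_numeric), list(sep = ",")))
    writeLines(body, con)
  }
  invisible(path)
}

format_numeric <- function(v) {
  formatC(v, format = "g", digits = 15)
}

#' Load a spiral dataset from a directory of trajectory files
#'
#' Joins a subject metadata table (CSV with columns `subject_id`, `group`,
#' `trs_score`, `tremor_level`, `age`, `sex`) with one trajectory file per
#' subject (`<subject_id>.svc` or `<subject_id>.csv` inside `data_dir`).
#' Subjects with no trajectory file are dropped with a warning; the returned
#' rows preserve the metadata row order.
#'
#' @param data_dir directory containing trajectory files.
#' @param metadata_file path to the metadata CSV.
#' @return a `spiral_dataset`: a tibble with the metadata columns plus a
#'   `spiral` list-column of [spiral_record()]s.
#' @export
load_dataset <- function(data_dir, metadata_file) {
  meta <- utils::read.csv(metadata_file, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "trs_score", "tremor_level", "age", "sex")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0L) {
    rlang::abort(paste0("metadata is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  dup <- meta$subject_id[duplicated(meta$subject_id)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("duplicate subject_id in metadata: ",
                        paste(unique(dup), collapse = ", ")))
  }
  bad <- meta$subject_id[(meta$group == "control") != (meta$tremor_level == 0)]
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "inconsistent metadata (group/tremor_level mismatch) for: ",
      paste(bad, collapse = ", ")))
  }
  paths <- vapply(meta$subject_id, function(id) {
    for (ext in c("svc", "csv")) {
      p <- file.path(data_dir, paste0(id, ".", ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  if (anyNA(paths)) {
    dropped <- meta$subject_id[is.na(paths)]
    rlang::warn(paste0("no trajectory file for, dropping: ",
                       paste(dropped, collapse = ", ")))
    meta <- meta[!is.na(paths), , drop = FALSE]
    paths <- paths[!is.na(paths)]
  }
  records <- purrr::map2(paths, meta$subject_id, function(p, id) {
    dialect <- if (grepl("\\.csv$", p)) "csv" else "svc"
    rec <- read_spiral(p, dialect = dialect)
    attr(rec, "subject_id") <- id
    rec
  })
  spiral_dataset(records, tibble::as_tibble(meta))
}

#' Assemble a spiral dataset from records and metadata
#'
#' @param records list of [spiral_record()]s.
#' @param meta tibble of subject metadata, one row per record, in the same
#'   order; every record's subject id must resolve to exactly one row.
#' @return a `spiral_dataset` tibble.
#' @export
spiral_dataset <- function(records, meta) {
  ids <- vapply(records, subject_id, character(1))
  if (!setequal(ids, meta$subject_id) || length(ids) != nrow(meta)) {
    rlang::abort("records and metadata subject ids do not match one-to-one.")
  }
  records <- records[match(meta$subject_id, ids)]
  out <- tibble::as_tibble(meta)
  out$tremor_level <- as.integer(out$tremor_level)
  if (!all(out$tremor_level %in% 0:2)) {
    rlang::abort("`tremor_level` must be 0, 1 or 2.")
  }
  if (any(out$trs_score < 0)) {
    rlang::abort("`trs_score` must be nonnegative.")
  }
  bad <- out$subject_id[(out$group == "control") != (out$tremor_level == 0L)]
  if (length(bad) > 0L) {
    rlang::abort(paste0(
      "inconsistent metadata (group/tremor_level mismatch) for: ",
      paste(bad, collapse = ", ")))
  }
  out$spiral <- records
  class(out) <- c("spiral_dataset", class(tibble::tibble()))
  out
}

#' Write a spiral dataset to a directory
#'
#' Writes one `<subject_id>.svc` trajectory file per record plus a
#' `metadata.csv` table, the layout that [load_dataset()] reads back.
#'
#' @param dataset a `spiral_dataset`.
#' @param dir output directory (created if needed).
#' @param dialect trajectory file dialect.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = c("svc", "csv")) {
  dialect <- match.arg(dialect)
  ext <- dialect
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$spiral) {
    write_spiral(rec, file.path(dir, paste0(subject_id(rec), ".", ext)),
                 dialect = dialect)
  }
  meta <- tibble::as_tibble(dataset)
  meta$spiral <- NULL
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.spiral_dataset <- function(x, ...) {
  cat(sprintf("<spiral_dataset> %d drawings (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  NextMethod()
}
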