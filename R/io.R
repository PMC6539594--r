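#' Read a compound table from CSV
#'
#' Reads a headered UTF-8 CSV (the Greek `Ψ` in sequences is preserved) with
#' mandatory columns `id` and `sequence`; any other columns are kept as
#' passthrough metadata. Duplicate ids, an empty table and malformed numeric
#' fields are rejected with messages naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return Data frame of compound records.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("no records in ", path, call. = FALSE)
  for (col in c("id", "sequence")) {
    if (!col %in% names(df)) {
      stop("missing mandatory column '", col, "' in ", path, call. = FALSE)
    }
  }
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicate compound id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("charge", "inh", "inh_sd", "logIC50", "logIC50_se",
                          "calc_mz_printed", "meas_mz_printed", "rt_min",
                          "dr_r2", "ic50_uM_printed"), names(df))
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      bad <- nzchar(v) & is.na(suppressWarnings(as.numeric(v)))
      if (any(bad)) {
        stop("malformed number in column '", col, "', line(s) ",
             paste(which(bad) + 1L, collapse = ", "), " of ", path,
             call. = FALSE)
      }
      df[[col]] <- suppressWarnings(as.numeric(v))
    }
  }
  df
}

#' Validate a compound table against its printed formulas and masses
#'
#' For every record carrying a printed formula and/or calculated m/z, the
#' sequence is parsed and assembled, and the computed formula and
#' monoisotopic m/z (at the record's charge state) are compared with the
#' printed values (m/z tolerance 0.00005 Da, i.e. agreement at 4 decimal
#' places). Failures are report rows, not errors.
#'
#' @param records Data frame with `id`, `sequence` and optionally
#'   `formula_printed`, `calc_mz_printed`, `charge`.
#' @return Data frame with per-compound computed values and `formula_ok` /
#'   `mz_ok` flags; attribute `summary` holds the pass counts.
#' @export
validate_panel <- function(records) {
  records <- as_compound_table(records)
  charge <- if ("charge" %in% names(records)) records$charge else rep(1, nrow(records))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    seq <- parse_sequence(records$sequence[i])
    f <- additive_formula(seq)
    fg <- formula_from_graph(assemble_graph(seq))
    stopifnot(identical(as.integer(f), as.integer(fg)))
    z <- if (is.na(charge[i])) 1 else charge[i]
    mz <- monoisotopic_mz(f, z = z)$mz_4dp
    fp <- if ("formula_printed" %in% names(records)) records$formula_printed[i] else NA
    mp <- if ("calc_mz_printed" %in% names(records)) records$calc_mz_printed[i] else NA
    data.frame(id = records$id[i],
               formula_computed = formula_string(f),
               formula_printed = as.character(fp),
               formula_ok = if (is.na(fp)) NA else formula_string(f) == fp,
               mz_computed = mz,
               calc_mz_printed = as.numeric(mp),
               mz_ok = if (is.na(mp)) NA else abs(mz - as.numeric(mp)) <= 0.00005,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    n = nrow(out),
    formula_pass = sum(out$formula_ok, na.rm = TRUE),
    mz_pass = sum(out$mz_ok, na.rm = TRUE))
  out
}

#' Write a result table with a plain-text summary
#'
#' Writes `x` as CSV and a sibling `.txt` summary (dimensions, columns, any
#' attributes recorded by the producing function, package version, seed).
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param title Short description used in the text summary.
#' @param seed Seed to log, if the producing computation was seeded.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, title = deparse(substitute(x)), seed = NULL) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c(
    paste0("report: ", title),
    paste0("rows: ", nrow(x), ", columns: ", paste(names(x), collapse = ", ")),
    paste0("package: trzsar ",
           as.character(utils::packageVersion("trzsar"))),
    if (!is.null(seed)) paste0("seed: ", seed),
    if (!is.null(attr(x, "summary")))
      paste0("summary: ", paste(names(attr(x, "summary")), attr(x, "summary"),
                                sep = "=", collapse = ", ")),
    if (!is.null(attr(x, "norm_range")))
      paste0("normalisation range: ", paste(attr(x, "norm_range"), collapse = "-")))
  writeLines(lines, txt)
  invisible(path)
}
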