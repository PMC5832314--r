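#' Read a tracer table
#'
#' Reads a comma-separated sample table (UTF-8, "." decimal separator, one
#' header row) and validates it against a tracer panel. Required columns:
#' `sample_id`, `role`, `category`, `subcatchment`; an optional
#' `replicate_index` column (default 1); every remaining column must name a
#' tracer in the panel. Tracer names are matched case-sensitively after
#' trimming whitespace. Missing tracer cells are an error — the mixing model
#' needs complete vectors and imputation is unsupported.
#'
#' @param path path to a CSV file.
#' @param panel a [tracer_panel()].
#' @return a `sample_table`: a data.frame with the metadata columns above
#'   followed by one numeric column per panel tracer present in the file.
#' @export
read_tracer_table <- function(path, panel) {
  stopifnot(inherits(panel, "tracer_panel"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  names(df) <- trimws(names(df))
  req <- c("sample_id", "role", "category", "subcatchment")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("tracer table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"replicate_index" %in% names(df)) df$replicate_index <- 1L
  tracer_cols <- setdiff(names(df), c(req, "replicate_index"))
  unknown <- setdiff(tracer_cols, panel$names)
  if (length(unknown)) {
    stop("tracer table schema error: column(s) not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (tc in tracer_cols) {
    v <- df[[tc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                     v[bad[1]], bad[1], tc), call. = FALSE)
      }
      v <- vn
    }
    df[[tc]] <- v
  }
  df <- df[c(req, "replicate_index", tracer_cols)]
  validate_sample_table(df, panel)
}

#' Validate a sample table against a panel
#'
#' Enforces the record invariants: roles are `source` or `sediment`; source
#' records carry one of the four known categories and sediment records none;
#' all tracer values are finite and inside the panel's physically valid
#' ranges.
#'
#' @param df data.frame shaped as returned by [read_tracer_table()].
#' @param panel a [tracer_panel()].
#' @return the validated `sample_table` (invisibly the same data).
#' @export
validate_sample_table <- function(df, panel) {
  tracer_cols <- intersect(names(df), panel$names)
  if (!all(df$role %in% c("source", "sediment"))) {
    stop("validation error: role must be 'source' or 'sediment'",
         call. = FALSE)
  }
  cat_blank <- is.na(df$category) | trimws(as.character(df$category)) == ""
  src <- df$role == "source"
  if (any(src & cat_blank)) {
    stop("validation error: source record without a category (sample_id ",
         df$sample_id[which(src & cat_blank)[1]], ")", call. = FALSE)
  }
  if (any(!src & !cat_blank)) {
    stop("validation error: sediment record carries a category (sample_id ",
         df$sample_id[which(!src & !cat_blank)[1]], ")", call. = FALSE)
  }
  bad_cat <- src & !df$category %in% SOURCE_CATEGORIES
  if (any(bad_cat)) {
    stop("validation error: unknown source category '",
         df$category[which(bad_cat)[1]], "' (expected one of ",
         paste(SOURCE_CATEGORIES, collapse = ", "), ")", call. = FALSE)
  }
  df$category[!src] <- NA_character_
  if (any(df$replicate_index < 1)) {
    stop("validation error: replicate_index must be >= 1", call. = FALSE)
  }
  for (tc in tracer_cols) {
    v <- df[[tc]]
    if (anyNA(v) || any(!is.finite(v))) {
      stop("validation error: missing or non-finite value for tracer '", tc,
           "' (row ", which(!is.finite(v))[1], "); imputation is not supported",
           call. = FALSE)
    }
    rng <- panel$valid_range[tc, ]
    out <- v < rng[1] | v > rng[2]
    if (any(out)) {
      stop(sprintf(
        "validation error: tracer '%s' value %g outside physical range [%g, %g]",
        tc, v[which(out)[1]], rng[1], rng[2]), call. = FALSE)
    }
  }
  class(df) <- c("sample_table", "data.frame")
  attr(df, "tracers") <- tracer_cols
  df
}

#' Write a tracer table
#'
#' Inverse of [read_tracer_table()]; round-trips finite values losslessly at
#' full double precision (15 significant digits).
#'
#' @param df a `sample_table`.
#' @param path output CSV path.
#' @export
write_tracer_table <- function(df, path) {
  out <- as.data.frame(df)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Tracer columns of a sample table
#' @param df a `sample_table`.
#' @return character vector of tracer column names.
#' @export
tracer_names <- function(df) {
  tr <- attr(df, "tracers")
  if (is.null(tr)) {
    tr <- setdiff(names(df), c("sample_id", "role", "category",
                               "subcatchment", "replicate_index"))
  }
  tr
}

#' Read an oxygen incubation table
#'
#' CSV columns: `flask_id`, `time_days`, `o2_mass_mg`, `temperature_c`,
#' `is_blank`, `dry_mass_g` (blank for blank flasks). Returns one
#' [oxygen_series()] per flask.
#'
#' @param path CSV path.
#' @return named list of `oxygen_series`.
#' @export
read_oxygen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("flask_id", "time_days", "o2_mass_mg", "temperature_c", "is_blank")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("oxygen table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"dry_mass_g" %in% names(df)) df$dry_mass_g <- NA_real_
  out <- lapply(split(df, df$flask_id), function(d) {
    d <- d[order(d$time_days), ]
    blank <- isTRUE(as.logical(d$is_blank[1])) || d$is_blank[1] %in% c(1, "true", "TRUE")
    oxygen_series(flask_id = d$flask_id[1],
                  times = d$time_days,
                  o2_mass = d$o2_mass_mg,
                  temperature_c = d$temperature_c[1],
                  is_blank = blank,
                  dry_mass_g = if (blank) NA_real_ else d$dry_mass_g[1])
  })
  out[unique(df$flask_id)]
}

#' Write oxygen series to an incubation table
#' @param series list of `oxygen_series` (or a single one).
#' @param path output CSV path.
#' @export
write_oxygen_table <- function(series, path) {
  if (inherits(series, "oxygen_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(flask_id = s$flask_id, time_days = s$times,
               o2_mass_mg = s$o2_mass, temperature_c = s$temperature_c,
               is_blank = s$is_blank,
               dry_mass_g = if (is.na(s$dry_mass_g)) "" else s$dry_mass_g,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
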