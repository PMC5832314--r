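#' Average laboratory replicates
#'
#' All samples are run in triplicate on the analytical instruments; the
#' average of the repeat runs is what enters the statistical and numerical
#' modelling. Records are grouped by `sample_id` (ignoring
#' `replicate_index`) and each tracer value is replaced by the arithmetic
#' mean over the group's replicates.
#'
#' @param df a `sample_table`.
#' @return a `sample_table` with one record per `sample_id` and
#'   `replicate_index` set to 1.
#' @export
average_replicates <- function(df) {
  tr <- tracer_names(df)
  groups <- split(seq_len(nrow(df)), df$sample_id)
  rows <- lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    if (length(unique(g$role)) != 1L ||
        length(unique(ifelse(is.na(g$category), "", g$category))) != 1L ||
        length(unique(g$subcatchment)) != 1L) {
      stop("validation error: replicates of '", g$sample_id[1],
           "' disagree on role/category/subcatchment", call. = FALSE)
    }
    out <- g[1, , drop = FALSE]
    out$replicate_index <- 1L
    for (tc in tr) out[[tc]] <- mean(g[[tc]])
    out
  })
  res <- do.call(rbind, rows)
  # preserve first-appearance order of sample ids
  res <- res[match(unique(df$sample_id), res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("sample_table", "data.frame")
  attr(res, "tracers") <- tr
  res
}

#' Summarize a group of samples per tracer
#'
#' Computes, for one source category (or for the sediment samples), the
#' per-tracer statistics the mixing model consumes: the median (the S_si or
#' C_i of the mass balance), the Qn robust scale (used to spread the Monte
#' Carlo parameter distributions), the coefficient of variation (whose
#' inverse is the within-source variability weighting SV_si), the observed
#' minimum/maximum (truncation bounds for deviates) and the sample count.
#'
#' Qn and CV need at least two samples and are `NA` below that. A tracer
#' whose group mean is zero has an undefined CV; it is flagged (`cv = NA`)
#' and later receives a neutral SV weight of 1.
#'
#' @param df a `sample_table` whose rows all share one role (and one
#'   category, for sources).
#' @return a `group_summary`: data.frame with columns `tracer`, `median`,
#'   `qn`, `cv`, `mean`, `min`, `max`, `n`; attributes `role` and
#'   `category`.
#' @export
summarize_group <- function(df) {
  if (nrow(df) == 0L) stop("empty group", call. = FALSE)
  if (length(unique(df$role)) != 1L) {
    stop("summarize_group: mixed roles in one group", call. = FALSE)
  }
  if (df$role[1] == "source" && length(unique(df$category)) != 1L) {
    stop("summarize_group: mixed source categories in one group", call. = FALSE)
  }
  tr <- tracer_names(df)
  n <- nrow(df)
  stats_one <- function(v) {
    m <- mean(v)
    cv <- if (n >= 2) {
      if (m == 0) NA_real_ else stats::sd(v) / abs(m)
    } else NA_real_
    c(median = stats::median(v),
      qn = if (n >= 2) qn_scale(v) else NA_real_,
      cv = cv, mean = m, min = min(v), max = max(v), n = n)
  }
  tab <- t(vapply(tr, function(tc) stats_one(df[[tc]]), numeric(7)))
  out <- data.frame(tracer = tr, tab, row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "role") <- df$role[1]
  attr(out, "category") <- if (df$role[1] == "source") df$category[1] else NA_character_
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Within-source variability weights (inverse coefficient of variation)
#'
#' SV_si = 1/CV for each tracer of a source summary, so tracers with smaller
#' within-source variance exert more influence on the mixing-model solution.
#' Undefined CVs (zero mean) fall back to a neutral weight of 1 with a
#' warning; zero CVs (no variation at all) are capped at `sv_cap` to keep
#' the objective finite.
#'
#' @param summary a `group_summary` from [summarize_group()].
#' @param sv_cap upper cap on the weight (default 1e6).
#' @return named numeric vector of SV weights per tracer.
#' @export
sv_weights <- function(summary, sv_cap = 1e6) {
  cv <- summary$cv
  sv <- numeric(length(cv))
  undef <- is.na(cv)
  if (any(undef)) {
    warning("SV weight undefined (zero mean or n < 2) for tracer(s) ",
            paste(summary$tracer[undef], collapse = ", "),
            "; using neutral weight 1", call. = FALSE)
    sv[undef] <- 1
  }
  sv[!undef] <- pmin(1 / pmax(cv[!undef], 1 / sv_cap), sv_cap)
  stats::setNames(sv, summary$tracer)
}
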