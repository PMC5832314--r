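#' Mass-conservation (bracket) screening of candidate tracers
#'
#' A tracer can only enter a linear mixing model if the sediment values it
#' takes are reachable as a mixture of the source values — a necessary
#' condition checked per tracer as an interval test: the sediment range
#' \[min, max\] must lie inside the envelope spanned by all source samples
#' of all categories (the axis-aligned bounding box of the mixing polygon).
#' Boundary equality counts as a pass. Tracers failing the test may have
#' been transformed in transit and are screened out before signature
#' selection.
#'
#' The test is applied per subcatchment to replicate-averaged samples; pass
#' it the samples of one subcatchment.
#'
#' @param sources `sample_table` of source samples (>= 2 categories).
#' @param sediments `sample_table` of sediment samples.
#' @param panel a [tracer_panel()]; the test covers every panel tracer
#'   present in both tables (all must be present in each).
#' @return a `range_test_report`: data.frame with columns `tracer`, `pass`,
#'   `sed_min`, `sed_max`, `src_min`, `src_max`.
#' @export
bracket_test <- function(sources, sediments, panel) {
  if (nrow(sediments) < 1L) stop("bracket_test: no sediment samples", call. = FALSE)
  if (length(unique(sources$category)) < 2L) {
    stop("bracket_test: need source samples from at least 2 categories",
         call. = FALSE)
  }
  tr <- panel$names
  missing_src <- setdiff(tr, tracer_names(sources))
  missing_sed <- setdiff(tr, tracer_names(sediments))
  if (length(missing_src) || length(missing_sed)) {
    stop("bracket_test: tracer(s) absent from records: ",
         paste(union(missing_src, missing_sed), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(tr, function(tc) {
    sed <- range(sediments[[tc]])
    src <- range(sources[[tc]])
    data.frame(tracer = tc,
               pass = sed[1] >= src[1] && sed[2] <= src[2],
               sed_min = sed[1], sed_max = sed[2],
               src_min = src[1], src_max = src[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("range_test_report", "data.frame")
  out
}

#' Tracers passing the bracket test
#' @param report a `range_test_report`.
#' @return character vector of passing tracer names.
#' @export
passing_tracers <- function(report) report$tracer[report$pass]
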