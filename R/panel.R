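#' Tracer panel
#'
#' A tracer panel declares the fingerprint properties a study measures: stable
#' isotope ratios (per mille), elemental contents (percent) and near-infrared
#' constituent band intensities (arbitrary units). Every sample table is
#' validated against a panel, and each tracer carries a physically valid
#' range used to reject impossible values at read time.
#'
#' @param names character vector of unique tracer identifiers.
#' @param kind character vector, one of `"isotope"`, `"elemental"`,
#'   `"nir_band"` per tracer (recycled if length 1).
#' @param valid_range two-column matrix (or NULL) of closed lower/upper
#'   physical bounds per tracer; `-Inf`/`Inf` mark unbounded sides. Defaults:
#'   isotopes unbounded, elemental contents in \[0, 100\], NIR bands
#'   in \[0, Inf).
#' @return an object of class `tracer_panel`.
#' @export
tracer_panel <- function(names, kind = "nir_band", valid_range = NULL) {
  names <- trimws(as.character(names))
  if (anyDuplicated(names)) {
    stop("tracer names must be unique", call. = FALSE)
  }
  if (length(names) == 0L) stop("panel needs at least one tracer", call. = FALSE)
  kind <- vapply(kind, function(k) {
    match.arg(k, c("isotope", "elemental", "nir_band"))
  }, character(1), USE.NAMES = FALSE)
  kind <- rep_len(kind, length(names))
  if (is.null(valid_range)) {
    valid_range <- t(vapply(kind, function(k) {
      switch(k,
             isotope = c(-Inf, Inf),
             elemental = c(0, 100),
             nir_band = c(0, Inf))
    }, numeric(2)))
  }
  valid_range <- matrix(as.numeric(valid_range), ncol = 2)
  if (nrow(valid_range) != length(names)) {
    stop("valid_range must have one row per tracer", call. = FALSE)
  }
  if (any(valid_range[, 1] > valid_range[, 2])) {
    stop("valid_range lower bounds exceed upper bounds", call. = FALSE)
  }
  dimnames(valid_range) <- list(names, c("lower", "upper"))
  structure(list(names = names,
                 kind = stats::setNames(kind, names),
                 valid_range = valid_range),
            class = "tracer_panel")
}

#' Default tracer panel
#'
#' Two bulk stable isotopes, total organic carbon and total nitrogen
#' contents, and sixteen NIR constituent bands — the quantities a
#' sediment-associated organic matter fingerprinting campaign measures.
#'
#' @return a `tracer_panel` with 20 tracers.
#' @export
default_tracer_panel <- function() {
  nir <- c("ArOH", "ArNH2", "Aromatic", "CH", "CH2", "CH3", "CONH2",
           "CONHR", "HC=CH", "Protein", "Cellulose", "RNH2", "ROH",
           "Starch", "Starch, glucose", "H2O")
  tracer_panel(c("d13C", "d15N", "TOC_pct", "TN_pct", nir),
               kind = c("isotope", "isotope", "elemental", "elemental",
                        rep("nir_band", length(nir))))
}

#' @export
print.tracer_panel <- function(x, ...) {
  cat("<tracer_panel> ", length(x$names), " tracers: ",
      paste(utils::head(x$names, 6), collapse = ", "),
      if (length(x$names) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

SOURCE_CATEGORIES <- c("farmyard", "road_verge", "instream_veg", "septic")

#' Source categories recognised by the pipeline
#'
#' Farmyard manures or slurries, damaged road verges, decaying instream
#' vegetation and human septic waste point-source discharges.
#' @return character vector of the four category labels.
#' @export
source_categories <- function() SOURCE_CATEGORIES
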