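#' Van der Waals radii (Bondi set)
#'
#' The package ships the Bondi van der Waals radii as a plain-text table in
#' `inst/extdata/bondi_radii.csv` so that all clearance and bottleneck
#' diameters are reproducible bit-for-bit. The table is read once per session
#' and is immutable at run time.
#'
#' @return A tibble with columns `element` and `radius` (Angstrom).
#' @export
#' @examples
#' vdw_radii_table()
vdw_radii_table <- function() {
  tbl <- .chokepoint_cache$radii
  if (is.null(tbl)) {
    path <- system.file("extdata", "bondi_radii.csv", package = "chokepoint",
                        mustWork = TRUE)
    tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    .chokepoint_cache$radii <- tbl
  }
  tbl
}

.chokepoint_cache <- new.env(parent = emptyenv())

#' Van der Waals radius of an element
#'
#' Looks up the Bondi radius. Unknown elements are an explicit error, never a
#' silent default, so that a mistyped element cannot corrupt a clearance map.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius(c("C", "N", "O"))
vdw_radius <- function(element) {
  tbl <- vdw_radii_table()
  key <- toupper(trimws(element))
  # normalise two-letter symbols ("CL" -> "Cl") against the table
  idx <- match(key, toupper(tbl$element))
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "),
         " (unknown elements are flagged, not defaulted)", call. = FALSE)
  }
  tbl$radius[idx]
}
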