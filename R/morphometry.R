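# Contour morphometry: area/perimeter metrics, the rectangle-equivalent
# length/diameter estimator, and the per-specimen morphometry record.

#' Area and circumference of a contour
#'
#' @param poly closed contour as an n x 2 vertex matrix (first vertex not
#'   repeated)
#' @return list with `A` (shoelace area, mm^2) and `C` (perimeter of the
#'   closed vertex cycle, mm)
#' @export
contour_metrics <- function(poly) {
  poly <- as_xy(poly)
  if (nrow(poly) < 3) stop("invalid geometry: polygon needs >= 3 vertices")
  A <- poly_area(poly)
  if (A <= 0) stop("invalid geometry: polygon area must be > 0")
  list(A = A, C = poly_perimeter(poly))
}

#' Rectangle-equivalent length and diameter of a contour
#'
#' Estimates the length L and diameter D of an irregular contour as the side
#' lengths of the rectangle with the same area A and circumference C:
#' \deqn{L = (C + \sqrt{C^2 - 16A})/4, \quad D = (C - \sqrt{C^2 - 16A})/4.}
#' The pair satisfies L*D = A and L + D = C/2 and inverts the forward map
#' exactly for every true rectangle. The approximation is intended for short
#' and/or thin elongated contours such as PM segments.
#'
#' When C^2 < 16A no rectangle has that (A, C) pair (the contour is rounder
#' than any rectangle of its perimeter; the square is the limit case). The
#' estimate is then clamped to the square limit L = D = C/4, the `clamped`
#' flag is set and a warning is emitted.
#'
#' @param A contour area (mm^2), > 0
#' @param C contour circumference (mm), > 0
#' @return list with `A`, `C`, `L`, `D`, `clamped`
#' @export
rect_equivalent <- function(A, C) {
  if (!is.finite(A) || !is.finite(C) || A <= 0 || C <= 0)
    stop("rect_equivalent: A and C must be positive and finite")
  disc <- C^2 - 16 * A
  if (disc < 0) {
    warning(sprintf("C^2 < 16A (disc = %.3g): contour rounder than any rectangle; clamping L = D = C/4", disc))
    return(list(A = A, C = C, L = C / 4, D = C / 4, clamped = TRUE))
  }
  s <- sqrt(disc)
  list(A = A, C = C, L = (C + s) / 4, D = (C - s) / 4, clamped = FALSE)
}

#' Rectangle-equivalent metrics of a contour polygon
#'
#' Convenience wrapper: [contour_metrics()] followed by [rect_equivalent()].
#' @param poly closed contour (n x 2 matrix)
#' @return list with `A`, `C`, `L`, `D`, `clamped`
#' @export
contour_rect_metrics <- function(poly) {
  m <- contour_metrics(poly)
  rect_equivalent(m$A, m$C)
}

#' Per-specimen morphometry record
#'
#' Computes the specimen-level morphometric summary:
#' \itemize{
#'   \item `CTI_A`: area of the CTI boundary polygon.
#'   \item `CTI_m`: muscular area — area of the geometric union of the
#'     included PM segment contours clipped to the CTI boundary (overlaps at
#'     ramifications counted once; set `sum_overlaps = TRUE` for the naive
#'     summed-area variant).
#'   \item `CTI_nm`: non-muscular area — `CTI_A - CTI_m` minus the parts of
#'     the TC and VB contours lying within the CTI boundary; floored at 0
#'     with a warning if the subtraction goes negative.
#'   \item `CTI_nm_ratio`: `CTI_nm / CTI_m` (NA with a warning when
#'     `CTI_m = 0`).
#'   \item isthmus lengths `ILI_L`, `CI_L`, `PSI_L` (polyline arc lengths)
#'     and their pairwise ratios `ratio_CI_ILI`, `ratio_PSI_CI`,
#'     `ratio_PSI_ILI` describing the trapezoidal CTI shape.
#'   \item `TC_A`, `TC_L`, `TC_D` and `VB_A`, `VB_L`, `VB_D`: full-contour
#'     area plus rectangle-equivalent length/diameter of the terminal crest
#'     and vestibule.
#' }
#' Ratios are stored as plain quotients (multiply by 100 for percent).
#'
#' @param spec a `cti_specimen`
#' @param included_segments segment data.frame as returned in
#'   `filter_segments(spec)$included`; defaults to applying
#'   [filter_segments()] with default settings
#' @param sum_overlaps if `TRUE`, `CTI_m` is the sum of individual clipped
#'   contour areas instead of their union (sensitivity check)
#' @return one-row data.frame (class `cti_morphometry`)
#' @export
specimen_morphometry <- function(spec, included_segments = NULL,
                                 sum_overlaps = FALSE) {
  if (is.null(included_segments)) included_segments <- filter_segments(spec)$included
  cti <- spec$cti_boundary
  CTI_A <- poly_area(cti)

  contours <- included_segments$contour
  if (length(contours) == 0) {
    CTI_m <- 0
  } else if (sum_overlaps) {
    CTI_m <- sum(vapply(contours, function(p) poly_intersect_area(p, cti), numeric(1)))
  } else {
    CTI_m <- poly_union_area(contours, clip = cti)
  }

  tc_in <- poly_intersect_area(spec$tc_contour, cti)
  vb_in <- poly_intersect_area(spec$vb_contour, cti)
  CTI_nm <- CTI_A - CTI_m - tc_in - vb_in
  if (CTI_nm < 0) {
    warning(sprintf("CTI_nm negative (%.3g mm^2); floored at 0 — TC/VB/PM coverage overlaps or exceeds the CTI area", CTI_nm))
    CTI_nm <- 0
  }
  if (CTI_m > 0) {
    CTI_nm_ratio <- CTI_nm / CTI_m
  } else {
    warning("no muscular area (CTI_m = 0); CTI_nm_ratio undefined")
    CTI_nm_ratio <- NA_real_
  }

  ILI_L <- polyline_length(spec$ili_line)
  CI_L <- polyline_length(spec$ci_line)
  PSI_L <- polyline_length(spec$psi_line)

  tc <- contour_rect_metrics(spec$tc_contour)
  vb <- contour_rect_metrics(spec$vb_contour)

  out <- data.frame(
    specimen_id = spec$specimen_id,
    CTI_A = CTI_A, CTI_m = CTI_m, CTI_nm = CTI_nm, CTI_nm_ratio = CTI_nm_ratio,
    ILI_L = ILI_L, CI_L = CI_L, PSI_L = PSI_L,
    TC_A = tc$A, TC_L = tc$L, TC_D = tc$D,
    VB_A = vb$A, VB_L = vb$L, VB_D = vb$D,
    ratio_CI_ILI = CI_L / ILI_L,
    ratio_PSI_CI = PSI_L / CI_L,
    ratio_PSI_ILI = PSI_L / ILI_L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cti_morphometry", "data.frame")
  out
}

#' Rectangle-equivalent metrics for every included PM segment
#'
#' @param spec a `cti_specimen`
#' @param included_segments as in [specimen_morphometry()]
#' @return data.frame with one row per segment: id, start, end, A, C, L, D,
#'   clamped
#' @export
segment_morphometry <- function(spec, included_segments = NULL) {
  if (is.null(included_segments)) included_segments <- filter_segments(spec)$included
  s <- included_segments
  rows <- lapply(seq_len(nrow(s)), function(i) {
    m <- suppressWarnings(contour_rect_metrics(s$contour[[i]]))
    data.frame(id = s$id[i], start = s$start[i], end = s$end[i],
               A = m$A, C = m$C, L = m$L, D = m$D, clamped = m$clamped,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(id = character(), start = character(), end = character(),
                      A = numeric(), C = numeric(), L = numeric(), D = numeric(),
                      clamped = logical()))
  do.call(rbind, rows)
}
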