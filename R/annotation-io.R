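# Reading, writing and validating the specimen annotation format.
#
# One specimen is a `cti_specimen` object: metadata, the six boundary corner
# points (intersections of the ILI/CI/PSI isthmus lines with the vestibule VB
# and the terminal crest TC), boundary contours/lines, labelled ramification
# sites and pectinate-muscle (PM) segment records. All geometry is held in mm;
# files written in px are converted at read time using the stored image
# resolution (um/px).

#' Ramification level symbols in anatomical order
#'
#' The six levels divide the CTI from the terminal crest (c) to the vestibule
#' (v): c < p < x < y < a < v. `x` and `y` are optional sublevels between the
#' first posterior branching level `p` and the last anterior merging level `a`.
#' @export
CTI_LEVELS <- c("c", "p", "x", "y", "a", "v")

#' Integer order of a ramification level (c = 0 ... v = 5)
#' @param level character vector of level symbols
#' @return integer vector
#' @export
level_order <- function(level) {
  o <- match(level, CTI_LEVELS) - 1L
  if (anyNA(o)) stop("unknown ramification level(s): ",
                     paste(unique(level[is.na(o)]), collapse = ", "),
                     " (allowed: ", paste(CTI_LEVELS, collapse = ", "), ")")
  o
}

CORNER_NAMES <- c("ilV", "cV", "cC", "ilC", "psV", "psC")

#' Construct a specimen annotation object
#'
#' Low-level constructor; [read_specimen()] is the usual entry point. All
#' coordinates must already be in mm.
#'
#' @param specimen_id identifier string
#' @param species one of "NZ", "Dom", "unknown"
#' @param sex one of "m", "f", "unknown"
#' @param body_weight body weight in kg
#' @param resolution image resolution in um/px
#' @param corners named list with points ilV, cV, cC, ilC, psV, psC (each
#'   numeric length 2, mm)
#' @param tc_contour,vb_contour closed contours (n x 2 matrices, mm)
#' @param ili_line,ci_line,psi_line open isthmus polylines (n x 2, mm)
#' @param cti_boundary closed CTI boundary polygon (n x 2, mm)
#' @param ramifications data.frame with columns id, level, index, x, y, virtual
#' @param segments data.frame with columns id, start, end, endocardial,
#'   orthogonal_epicardial and a list column `contour` of n x 2 matrices
#' @return an object of class `cti_specimen`
#' @export
new_cti_specimen <- function(specimen_id, species = "unknown", sex = "unknown",
                             body_weight = NA_real_, resolution = 10,
                             corners, tc_contour, vb_contour,
                             ili_line, ci_line, psi_line, cti_boundary,
                             ramifications, segments) {
  obj <- list(
    specimen_id = as.character(specimen_id),
    species = species, sex = sex,
    body_weight = as.numeric(body_weight),
    resolution = as.numeric(resolution),
    corners = lapply(corners[CORNER_NAMES], as.numeric),
    tc_contour = as_xy(tc_contour), vb_contour = as_xy(vb_contour),
    ili_line = as_xy(ili_line), ci_line = as_xy(ci_line),
    psi_line = as_xy(psi_line), cti_boundary = as_xy(cti_boundary),
    ramifications = ramifications,
    segments = segments
  )
  class(obj) <- "cti_specimen"
  obj
}

#' @export
print.cti_specimen <- function(x, ...) {
  cat("<cti_specimen> ", x$specimen_id,
      sprintf(" (%s, %s, %.2f kg)\n", x$species, x$sex, x$body_weight))
  cat("  ramifications:", nrow(x$ramifications),
      " (virtual:", sum(x$ramifications$virtual), ")\n")
  cat("  PM segments:  ", nrow(x$segments), "\n")
  cat("  CTI boundary area:", signif(poly_area(x$cti_boundary), 5), "mm^2\n")
  invisible(x)
}

stop_io <- function(field, msg) {
  stop(sprintf("annotation error at '%s': %s", field, msg), call. = FALSE)
}

need <- function(lst, key, field) {
  if (is.null(lst[[key]])) stop_io(paste0(field, key), "missing required field")
  lst[[key]]
}

coords_to_matrix <- function(v, field) {
  m <- try(matrix(as.numeric(unlist(v)), ncol = 2, byrow = TRUE), silent = TRUE)
  if (inherits(m, "try-error") || any(!is.finite(m)))
    stop_io(field, "not a finite [x, y] coordinate list")
  m
}

#' Read a specimen annotation file
#'
#' Parses the annotation JSON dialect, validates it and returns a
#' `cti_specimen` with all coordinates in mm. Files stored with
#' `"units": "px"` are converted by multiplying with resolution/1000.
#'
#' @param path path to an annotation JSON file
#' @param strict if `TRUE` (default) validation errors abort; warnings are
#'   reported either way
#' @return a validated [new_cti_specimen()] object
#' @seealso [write_specimen()], [validate_specimen()]
#' @export
read_specimen <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_io(path, "file does not exist")
  raw <- try(jsonlite::fromJSON(path, simplifyVector = FALSE), silent = TRUE)
  if (inherits(raw, "try-error")) stop_io(path, "JSON parse failure")
  spec_from_list(raw, strict = strict)
}

# build a cti_specimen from the parsed JSON list
spec_from_list <- function(raw, strict = TRUE) {
  if (is.null(raw$format_version)) stop_io("format_version", "missing")
  units <- if (is.null(raw$units)) "mm" else raw$units
  if (!units %in% c("mm", "px")) stop_io("units", "must be 'mm' or 'px'")
  meta <- need(raw, "specimen", "")
  res <- as.numeric(need(meta, "resolution_um_per_px", "specimen/"))
  if (!is.finite(res) || res <= 0) stop_io("specimen/resolution_um_per_px", "must be > 0")
  scale <- if (units == "px") res / 1000 else 1

  bnd <- need(raw, "boundary", "")
  crn <- need(bnd, "corners", "boundary/")
  corners <- lapply(CORNER_NAMES, function(nm) {
    as.numeric(unlist(need(crn, nm, "boundary/corners/"))) * scale
  })
  names(corners) <- CORNER_NAMES

  geom <- function(key, min_n) {
    m <- coords_to_matrix(need(bnd, key, "boundary/"), paste0("boundary/", key)) * scale
    if (nrow(m) < min_n)
      stop_io(paste0("boundary/", key), sprintf("needs at least %d vertices", min_n))
    m
  }

  rams <- raw$ramifications
  if (is.null(rams)) rams <- list()
  ram_df <- do.call(rbind, lapply(seq_along(rams), function(i) {
    r <- rams[[i]]
    fld <- sprintf("ramifications[%d]/", i)
    lev <- as.character(need(r, "level", fld))
    if (!lev %in% CTI_LEVELS)
      stop_io(paste0(fld, "level"),
              paste0("'", lev, "' not in allowed set {", paste(CTI_LEVELS, collapse = ","), "}"))
    pos <- as.numeric(unlist(need(r, "pos", fld))) * scale
    data.frame(id = as.character(need(r, "id", fld)), level = lev,
               index = as.integer(need(r, "index", fld)),
               x = pos[1], y = pos[2],
               virtual = isTRUE(r$virtual), stringsAsFactors = FALSE)
  }))
  if (is.null(ram_df))
    ram_df <- data.frame(id = character(), level = character(), index = integer(),
                         x = numeric(), y = numeric(), virtual = logical())

  segs <- raw$segments
  if (is.null(segs)) segs <- list()
  seg_df <- do.call(rbind, lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    fld <- sprintf("segments[%d]/", i)
    ct <- coords_to_matrix(need(s, "contour", fld), paste0(fld, "contour")) * scale
    d <- data.frame(id = as.character(need(s, "id", fld)),
                    start = as.character(need(s, "start", fld)),
                    end = as.character(need(s, "end", fld)),
                    endocardial = isTRUE(s$endocardial),
                    orthogonal_epicardial = isTRUE(s$orthogonal_epicardial),
                    stringsAsFactors = FALSE)
    d$contour <- list(ct)
    d
  }))
  if (is.null(seg_df)) {
    seg_df <- data.frame(id = character(), start = character(), end = character(),
                         endocardial = logical(), orthogonal_epicardial = logical())
    seg_df$contour <- list()
  }

  spec <- new_cti_specimen(
    specimen_id = need(meta, "id", "specimen/"),
    species = if (is.null(meta$species)) "unknown" else meta$species,
    sex = if (is.null(meta$sex)) "unknown" else meta$sex,
    body_weight = if (is.null(meta$body_weight_kg)) NA_real_ else meta$body_weight_kg,
    resolution = res,
    corners = corners,
    tc_contour = geom("tc_contour", 3), vb_contour = geom("vb_contour", 3),
    ili_line = geom("ili_line", 2), ci_line = geom("ci_line", 2),
    psi_line = geom("psi_line", 2), cti_boundary = geom("cti_boundary", 3)
  , ramifications = ram_df, segments = seg_df)

  diag <- validate_specimen(spec)
  errs <- diag[diag$severity == "error", , drop = FALSE]
  if (strict && nrow(errs) > 0)
    stop(sprintf("specimen '%s' failed validation:\n%s", spec$specimen_id,
                 paste(sprintf("  [%s] %s: %s", errs$severity, errs$field, errs$message),
                       collapse = "\n")), call. = FALSE)
  spec
}

#' Write a specimen annotation file
#'
#' Serializes a `cti_specimen` back to the annotation JSON dialect (always in
#' mm, full double precision). `write_specimen()` followed by
#' [read_specimen()] round-trips all coordinates to within 1e-9 mm.
#'
#' @param spec a `cti_specimen`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_specimen <- function(spec, path) {
  segs <- lapply(seq_len(nrow(spec$segments)), function(i) {
    s <- spec$segments[i, ]
    list(id = s$id, start = s$start, end = s$end,
         contour = unclass(s$contour[[1]]),
         endocardial = s$endocardial,
         orthogonal_epicardial = s$orthogonal_epicardial)
  })
  rams <- lapply(seq_len(nrow(spec$ramifications)), function(i) {
    r <- spec$ramifications[i, ]
    list(id = r$id, level = r$level, index = r$index,
         pos = c(r$x, r$y), virtual = r$virtual)
  })
  out <- list(
    format_version = "1.0",
    units = "mm",
    specimen = list(id = spec$specimen_id, species = spec$species, sex = spec$sex,
                    body_weight_kg = spec$body_weight,
                    resolution_um_per_px = spec$resolution),
    boundary = list(
      corners = spec$corners,
      tc_contour = spec$tc_contour, vb_contour = spec$vb_contour,
      ili_line = spec$ili_line, ci_line = spec$ci_line, psi_line = spec$psi_line,
      cti_boundary = spec$cti_boundary),
    ramifications = rams,
    segments = segs
  )
  json <- jsonlite::toJSON(out, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

diag_row <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a specimen annotation
#'
#' Checks all structural invariants and returns a diagnostics table rather
#' than throwing: each row has a severity ("error" or "warning"), the field
#' path and a message. An empty table means the specimen is fully valid.
#' Level-ordering issues in the PM network (see [level_order_validate()]) are
#' surfaced here as warnings.
#'
#' @param spec a `cti_specimen`
#' @param tol tolerance (mm) for the boundary-encloses-ramifications check
#' @return data.frame with columns severity, field, message
#' @export
validate_specimen <- function(spec, tol = 0.5) {
  d <- diag_row(character(0), character(0), character(0))

  if (!is.finite(spec$resolution) || spec$resolution <= 0)
    d <- rbind(d, diag_row("error", "specimen/resolution_um_per_px", "must be > 0"))

  # corners distinct and quadrilaterals convex
  cm <- do.call(rbind, spec$corners)
  if (nrow(unique(round(cm, 9))) < 6)
    d <- rbind(d, diag_row("error", "boundary/corners", "six corner points must be distinct"))
  lq <- rbind(spec$corners$ilV, spec$corners$cV, spec$corners$cC, spec$corners$ilC)
  rq <- rbind(spec$corners$cV, spec$corners$psV, spec$corners$psC, spec$corners$cC)
  if (!quad_is_convex(lq))
    d <- rbind(d, diag_row("error", "boundary/corners", "degenerate left quadrilateral (ilV,cV,cC,ilC not convex)"))
  if (!quad_is_convex(rq))
    d <- rbind(d, diag_row("error", "boundary/corners", "degenerate right quadrilateral (cV,psV,psC,cC not convex)"))

  for (key in c("tc_contour", "vb_contour", "cti_boundary")) {
    p <- spec[[key]]
    fld <- paste0("boundary/", key)
    if (nrow(p) < 3)
      d <- rbind(d, diag_row("error", fld, "polygon needs >= 3 vertices"))
    else if (poly_area(p) <= 0)
      d <- rbind(d, diag_row("error", fld, "polygon area must be > 0"))
    else if (!poly_is_simple(p))
      d <- rbind(d, diag_row("error", fld, "polygon is self-intersecting"))
  }
  for (key in c("ili_line", "ci_line", "psi_line")) {
    if (nrow(spec[[key]]) < 2)
      d <- rbind(d, diag_row("error", paste0("boundary/", key), "polyline needs >= 2 vertices"))
  }

  r <- spec$ramifications
  if (nrow(r) > 0) {
    bad_lvl <- !r$level %in% CTI_LEVELS
    if (any(bad_lvl))
      d <- rbind(d, diag_row("error", "ramifications/level",
                             paste0("unknown level(s): ", paste(unique(r$level[bad_lvl]), collapse = ","),
                                    " (allowed: ", paste(CTI_LEVELS, collapse = ","), ")")))
    mism <- (r$index == 0) != r$virtual
    if (any(mism))
      d <- rbind(d, diag_row("error", "ramifications",
                             paste0("index 0 must coincide with virtual flag: ",
                                    paste(r$id[mism], collapse = ","))))
    if (anyDuplicated(r$id))
      d <- rbind(d, diag_row("error", "ramifications/id", "duplicate ramification ids"))
    # boundary must enclose all real (non-virtual) ramifications
    real <- r[!r$virtual, , drop = FALSE]
    if (nrow(real) > 0 && nrow(spec$cti_boundary) >= 3) {
      inside <- point_in_poly(real$x, real$y, spec$cti_boundary) |
        near_polygon(real$x, real$y, spec$cti_boundary, tol)
      if (any(!inside))
        d <- rbind(d, diag_row("warning", "ramifications",
                               paste0("outside CTI boundary: ", paste(real$id[!inside], collapse = ","))))
    }
  }

  s <- spec$segments
  if (nrow(s) > 0) {
    dangling <- !(s$start %in% r$id) | !(s$end %in% r$id)
    if (any(dangling))
      d <- rbind(d, diag_row("error", "segments",
                             paste0("dangling ramification reference in: ",
                                    paste(s$id[dangling], collapse = ","))))
    loops <- s$start == s$end
    if (any(loops))
      d <- rbind(d, diag_row("error", "segments",
                             paste0("segment start equals end: ", paste(s$id[loops], collapse = ","))))
    for (i in seq_len(nrow(s))) {
      ct <- s$contour[[i]]
      if (nrow(ct) < 3 || poly_area(ct) <= 0)
        d <- rbind(d, diag_row("error", sprintf("segments[%d]/contour", i),
                               "invalid contour (needs >= 3 vertices and area > 0)"))
    }
    # level-order sanity as warnings (only when references resolve)
    if (!any(dangling) && !any(loops) && nrow(r) > 0 && !any(!r$level %in% CTI_LEVELS)) {
      g <- try(suppressWarnings(build_graph(spec, spec$segments)), silent = TRUE)
      if (!inherits(g, "try-error")) {
        lw <- level_order_validate(g)
        if (nrow(lw) > 0)
          d <- rbind(d, diag_row("warning", "segments/levels", lw$message))
      }
    }
  }
  d
}

# is a point within tol of any edge of a closed polygon?
near_polygon <- function(px, py, xy, tol) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  vapply(seq_along(px), function(i) {
    dx <- xy[j, 1] - xy[, 1]; dy <- xy[j, 2] - xy[, 2]
    len2 <- dx^2 + dy^2
    t <- pmin(pmax(((px[i] - xy[, 1]) * dx + (py[i] - xy[, 2]) * dy) / pmax(len2, 1e-300), 0), 1)
    d2 <- (xy[, 1] + t * dx - px[i])^2 + (xy[, 2] + t * dy - py[i])^2
    min(d2) <= tol^2
  }, logical(1))
}

#' Apply the PM segment inclusion filters
#'
#' Partitions the specimen's segments into included and excluded sets using
#' the analysis inclusion rules: rectangle-equivalent diameter at least
#' `min_diameter` (default 0.1 mm), endocardial location, and not flagged as
#' an orthogonally oriented epicardial strand. Degenerate contours are routed
#' to the excluded set with reason "invalid_contour" rather than erroring.
#'
#' @param spec a `cti_specimen`
#' @param min_diameter minimum rectangle-equivalent diameter in mm
#' @param require_endocardial drop segments not flagged endocardial
#' @return list with `included` (segment data.frame) and `excluded`
#'   (data.frame of id, reason); together they partition the input
#' @export
filter_segments <- function(spec, min_diameter = 0.1, require_endocardial = TRUE) {
  s <- spec$segments
  if (nrow(s) == 0)
    return(list(included = s, excluded = data.frame(id = character(), reason = character())))
  reason <- rep(NA_character_, nrow(s))
  for (i in seq_len(nrow(s))) {
    ct <- s$contour[[i]]
    if (nrow(ct) < 3 || poly_area(ct) <= 0) { reason[i] <- "invalid_contour"; next }
    if (s$orthogonal_epicardial[i]) { reason[i] <- "epicardial_orthogonal"; next }
    if (require_endocardial && !s$endocardial[i]) { reason[i] <- "not_endocardial"; next }
    rm_ <- rect_equivalent(poly_area(ct), poly_perimeter(ct))
    if (rm_$D < min_diameter) reason[i] <- "below_min_diameter"
  }
  keep <- is.na(reason)
  list(included = s[keep, , drop = FALSE],
       excluded = data.frame(id = s$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
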