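# Two-patch bilinear normalization of the CTI onto the unit square (NCTI).
#
# The CTI quadrilateral is split by the central isthmus CI into a left
# (inferolateral, l in [0, 0.5]) and a right (paraseptal, l in [0.5, 1])
# patch. Each patch is an irregular quadrilateral mapped by a bilinear
# function
#     x = a1 + a2 l + a3 m + a4 l m
#     y = b1 + b2 l + b3 m + b4 l m
# whose coefficients are fixed by the four corner points. TC is the m = 1
# edge, VB the m = 0 edge. The inverse map solves a quadratic in m.
#
# Note on the inverse: substituting l(x, m) into the y equation gives the
# quadratic a m^2 + b m + c = 0 with
#     a = a4 b3 - a3 b4
#     b = a4 b1 - a1 b4 + a2 b3 - a3 b2 + x b4 - y a4
#     c = a2 b1 - a1 b2 + x b2 - y a2
# (the sign of the a3 b2 term is negative; the forward/inverse round-trip
# property test pins this down).

# (l, m) positions of the corner points of each half-patch
CORNER_LM <- list(
  left  = list(names = c("ilV", "cV", "cC", "ilC"),
               l = c(0, 0.5, 0.5, 0), m = c(0, 0, 1, 1)),
  right = list(names = c("cV", "psV", "psC", "cC"),
               l = c(0.5, 1, 1, 0.5), m = c(0, 0, 1, 1))
)

#' Corner design matrix of a half-patch
#'
#' Rows are (1, l, m, l*m) evaluated at the half's four corner points in
#' order. Its inverse is the solve matrix mapping corner x- (or y-)
#' coordinates to the bilinear coefficients; for the left half the inverse is
#' the constant matrix with rows (1,0,0,0), (-2,2,0,0), (-1,0,0,1),
#' (2,-2,2,-2), independent of the corner layout.
#'
#' @param half "left" or "right"
#' @return 4 x 4 numeric matrix
#' @export
bilinear_corner_matrix <- function(half = c("left", "right")) {
  half <- match.arg(half)
  lm <- CORNER_LM[[half]]
  cbind(1, lm$l, lm$m, lm$l * lm$m, deparse.level = 0)
}

#' Solve matrix of a half-patch (inverse corner matrix)
#' @inheritParams bilinear_corner_matrix
#' @return 4 x 4 numeric matrix M^-1 with coefficients = M^-1 %*% corner_coords
#' @export
bilinear_solve_matrix <- function(half = c("left", "right")) {
  solve(bilinear_corner_matrix(half))
}

fit_half <- function(corners, half) {
  lm <- CORNER_LM[[half]]
  pts <- do.call(rbind, corners[lm$names])
  scale <- max(abs(pts)) + 1
  if (nrow(unique(round(pts / scale, 12))) < 4 ||
      poly_area(pts) < 1e-12 * scale^2)
    stop(sprintf("degenerate %s quadrilateral: coincident or collinear corners", half))
  Minv <- bilinear_solve_matrix(half)
  M <- bilinear_corner_matrix(half)
  if (abs(det(M)) < 1e-12) stop("degenerate quadrilateral: singular corner matrix")
  alpha <- as.numeric(Minv %*% pts[, 1])
  beta <- as.numeric(Minv %*% pts[, 2])
  # corner reconstruction must be exact
  rec <- cbind(M %*% alpha, M %*% beta)
  if (max(abs(rec - pts)) > 1e-9 * (max(abs(pts)) + 1))
    stop("degenerate quadrilateral: corner constraints not satisfied")
  list(alpha = alpha, beta = beta, half = half,
       l_range = if (half == "left") c(0, 0.5) else c(0.5, 1))
}

#' Fit the two-patch bilinear map from the six boundary corners
#'
#' Builds the image <-> normalized ("unit space") mapping for a specimen from
#' its six corner points. Left patch corners map to (l, m) = ilV (0,0),
#' cV (0.5,0), cC (0.5,1), ilC (0,1); right patch cV (0.5,0), psV (1,0),
#' psC (1,1), cC (0.5,1). The two patches agree along the shared CI edge
#' l = 0.5 by construction.
#'
#' @param corners named list with points ilV, cV, cC, ilC, psV, psC (numeric
#'   length-2 each), e.g. `spec$corners`
#' @return object of class `cti_bilinear` with elements `left` and `right`
#'   (each: alpha, beta, half, l_range)
#' @export
fit_bilinear <- function(corners) {
  corners <- lapply(corners, as.numeric)
  missing <- setdiff(CORNER_NAMES, names(corners))
  if (length(missing) > 0)
    stop("missing corner point(s): ", paste(missing, collapse = ", "))
  obj <- list(left = fit_half(corners, "left"),
              right = fit_half(corners, "right"))
  class(obj) <- "cti_bilinear"
  obj
}

#' @export
print.cti_bilinear <- function(x, ...) {
  cat("<cti_bilinear> two-patch bilinear map (image mm <-> unit square)\n")
  for (h in c("left", "right")) {
    cat(sprintf("  %-5s alpha: %s\n", h,
                paste(signif(x[[h]]$alpha, 5), collapse = " ")))
    cat(sprintf("        beta:  %s\n",
                paste(signif(x[[h]]$beta, 5), collapse = " ")))
  }
  invisible(x)
}

eval_half <- function(hm, l, m) {
  cbind(hm$alpha[1] + hm$alpha[2] * l + hm$alpha[3] * m + hm$alpha[4] * l * m,
        hm$beta[1] + hm$beta[2] * l + hm$beta[3] * m + hm$beta[4] * l * m)
}

#' Map normalized coordinates to image coordinates
#'
#' Evaluates the bilinear map of the half whose l-range contains each point
#' (l = 0.5 lies in both; the two patches agree there).
#'
#' @param map a `cti_bilinear`
#' @param l,m normalized coordinates (vectorized)
#' @return n x 2 matrix of image coordinates (mm)
#' @export
to_image <- function(map, l, m) {
  stopifnot(inherits(map, "cti_bilinear"))
  n <- max(length(l), length(m))
  l <- rep_len(l, n); m <- rep_len(m, n)
  out <- matrix(NA_real_, n, 2)
  use_left <- l <= 0.5
  if (any(use_left)) out[use_left, ] <- eval_half(map$left, l[use_left], m[use_left])
  if (any(!use_left)) out[!use_left, ] <- eval_half(map$right, l[!use_left], m[!use_left])
  out
}

# inverse of one half at one point; returns candidate (l, m) rows
invert_half <- function(hm, x, y) {
  a_ <- hm$alpha; b_ <- hm$beta
  qa <- a_[4] * b_[3] - a_[3] * b_[4]
  qb <- a_[4] * b_[1] - a_[1] * b_[4] + a_[2] * b_[3] - a_[3] * b_[2] +
    x * b_[4] - y * a_[4]
  qc <- a_[2] * b_[1] - a_[1] * b_[2] + x * b_[2] - y * a_[2]
  if (abs(qa) < 1e-12 * max(abs(qb), abs(qc), 1)) {
    if (abs(qb) < 1e-300) return(matrix(numeric(0), ncol = 2))
    ms <- -qc / qb                      # affine patch: linear fallback
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) return(matrix(numeric(0), ncol = 2))
    sq <- sqrt(disc)
    ms <- c((-qb + sq) / (2 * qa), (-qb - sq) / (2 * qa))
  }
  res <- lapply(ms, function(m) {
    den <- a_[2] + a_[4] * m
    if (abs(den) > 1e-10) {
      l <- (x - a_[1] - a_[3] * m) / den
    } else {
      den2 <- b_[2] + b_[4] * m
      if (abs(den2) < 1e-300) return(NULL)
      l <- (y - b_[1] - b_[3] * m) / den2
    }
    c(l, m)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, res)
}

# Euclidean distance of (l, m) to the rectangle l_range x [0, 1]
domain_distance <- function(l, m, l_range) {
  dl <- pmax(l_range[1] - l, 0, l - l_range[2])
  dm <- pmax(0 - m, 0, m - 1)
  sqrt(dl^2 + dm^2)
}

#' Map image coordinates to normalized coordinates
#'
#' Inverts the two-patch bilinear map. For each point the quadratic in m is
#' solved under both halves; among all real candidate solutions, those with
#' m in [-0.25, 1.25] are preferred, and the (root, half) pair whose (l, m)
#' lies nearest to that half's unit domain is selected, ties broken toward
#' the left half. Points inside either patch therefore invert exactly
#' (round-trip to 1e-9 mm); points outside the ROI (e.g. virtual
#' ramifications, curved TC/VB borders) get the nearest-half extrapolation
#' and may have l or m outside [0, 1].
#'
#' @param map a `cti_bilinear`
#' @param x,y image coordinates in mm (vectorized)
#' @return data.frame with columns l, m, half; a row of NAs (with a warning)
#'   where no real solution exists under either half
#' @export
to_normalized <- function(map, x, y) {
  stopifnot(inherits(map, "cti_bilinear"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- data.frame(l = rep(NA_real_, n), m = NA_real_, half = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- invert_half(map$left, x[i], y[i])
    cr <- invert_half(map$right, x[i], y[i])
    cand <- rbind(
      if (nrow(cl) > 0) cbind(cl, 1) else NULL,
      if (nrow(cr) > 0) cbind(cr, 2) else NULL
    )
    if (is.null(cand) || nrow(cand) == 0) {
      warning(sprintf("unmappable point (%.4g, %.4g): no real inverse under either half", x[i], y[i]))
      next
    }
    halves <- c("left", "right")[cand[, 3]]
    dist <- vapply(seq_len(nrow(cand)), function(k) {
      domain_distance(cand[k, 1], cand[k, 2], map[[halves[k]]]$l_range)
    }, numeric(1))
    plaus <- cand[, 2] >= -0.25 & cand[, 2] <= 1.25
    pool <- if (any(plaus)) which(plaus) else seq_len(nrow(cand))
    # smallest domain distance; ties toward the left half
    best <- pool[order(dist[pool], cand[pool, 3])][1]
    out$l[i] <- cand[best, 1]
    out$m[i] <- cand[best, 2]
    out$half[i] <- halves[cand[best, 3]]
  }
  out
}

#' Normalized coordinates of all ramifications of a specimen
#'
#' Maps every ramification (including virtual ones) into the NCTI.
#' Coordinates outside the unit square are retained — ramifications on the
#' curved TC/VB borders or outside the ROI legitimately map outside [0, 1].
#'
#' @param spec a `cti_specimen`
#' @param map a fitted `cti_bilinear`; defaults to `fit_bilinear(spec$corners)`
#' @return data.frame with columns id, level, virtual, l, m, half
#' @export
normalize_specimen <- function(spec, map = NULL) {
  if (is.null(map)) map <- fit_bilinear(spec$corners)
  r <- spec$ramifications
  nc <- to_normalized(map, r$x, r$y)
  data.frame(id = r$id, level = r$level, virtual = r$virtual,
             l = nc$l, m = nc$m, half = nc$half, stringsAsFactors = FALSE)
}
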