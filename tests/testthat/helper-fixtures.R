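# Programmatic fixtures shared across the test files.

# identity layout: corners sit at their own normalized (l, m) positions
identity_corners <- function() {
  list(ilV = c(0, 0), cV = c(0.5, 0), cC = c(0.5, 1),
       ilC = c(0, 1), psV = c(1, 0), psC = c(1, 1))
}

# random non-degenerate two-patch layout: trapezoid with mild corner jitter
# and a random rigid motion
random_layout <- function() {
  W <- runif(1, 8, 16)
  ili <- runif(1, 9, 15)
  ci <- ili * runif(1, 0.6, 0.9)
  psi <- ci * runif(1, 0.3, 0.8)
  jx <- rnorm(3, 0, 0.04 * W)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sh <- runif(2, -20, 20)
  tr <- function(p) as.numeric(R %*% p + sh)
  list(ilV = tr(c(0, 0)), cV = tr(c(W / 2, 0)), psV = tr(c(W, 0)),
       ilC = tr(c(jx[1], ili)), cC = tr(c(W / 2 + jx[2], ci)),
       psC = tr(c(W + jx[3], psi)))
}

# rectangular contour of length L and width D along p1 -> p2
rect_between <- function(p1, p2, D, L = NULL) {
  dvec <- p2 - p1
  dist <- sqrt(sum(dvec^2))
  if (is.null(L)) L <- dist
  u <- dvec / dist
  nv <- c(-u[2], u[1])
  mid <- (p1 + p2) / 2
  rbind(mid - u * L / 2 - nv * D / 2, mid + u * L / 2 - nv * D / 2,
        mid + u * L / 2 + nv * D / 2, mid - u * L / 2 + nv * D / 2)
}

square_boundary <- function() {
  list(
    corners = list(ilV = c(0, 0), cV = c(5, 0), psV = c(10, 0),
                   ilC = c(0, 10), cC = c(5, 10), psC = c(10, 10)),
    tc_contour = rbind(c(0, 10), c(5, 10), c(10, 10), c(10, 9), c(5, 9), c(0, 9)),
    vb_contour = rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 1), c(5, 1), c(0, 1)),
    ili_line = rbind(c(0, 0), c(0, 10)),
    ci_line = rbind(c(5, 0), c(5, 10)),
    psi_line = rbind(c(10, 0), c(10, 10)),
    cti_boundary = rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 10), c(5, 10), c(0, 10))
  )
}

make_square_specimen <- function(ramifications, segments, id = "TEST") {
  b <- square_boundary()
  new_cti_specimen(specimen_id = id, resolution = 10,
                   corners = b$corners, tc_contour = b$tc_contour,
                   vb_contour = b$vb_contour, ili_line = b$ili_line,
                   ci_line = b$ci_line, psi_line = b$psi_line,
                   cti_boundary = b$cti_boundary,
                   ramifications = ramifications, segments = segments)
}

ram_row <- function(id, level, index, x, y, virtual = FALSE) {
  data.frame(id = id, level = level, index = index, x = x, y = y,
             virtual = virtual, stringsAsFactors = FALSE)
}

seg_row <- function(id, start, end, contour, endocardial = TRUE,
                    orthogonal_epicardial = FALSE) {
  d <- data.frame(id = id, start = start, end = end, endocardial = endocardial,
                  orthogonal_epicardial = orthogonal_epicardial,
                  stringsAsFactors = FALSE)
  d$contour <- list(contour)
  d
}

# 10 x 10 square CTI with a single 2 x 1 mm segment centred in it and
# 10 x 1 mm TC/VB strips: hand-computable morphometry
block_specimen <- function() {
  rams <- rbind(ram_row("c1", "c", 1, 5, 8.5), ram_row("v1", "v", 1, 5, 1.5))
  segs <- seg_row("P.c1.v1", "c1", "v1",
                  rbind(c(4, 4.5), c(6, 4.5), c(6, 5.5), c(4, 5.5)))
  make_square_specimen(rams, segs, id = "BLOCK")
}

# small network covering levels c, p, x, a, v (no y), one same-level (ii)
# connection at level a, and a virtual out-of-ROI anchor c0
demo_network_specimen <- function() {
  pos <- list(c0 = c(-0.5, 9.5), c1 = c(1.5, 8.6), c2 = c(4, 8.6),
              p1 = c(2, 7.5), x1 = c(2.5, 5.5),
              a1 = c(2, 3), a2 = c(4, 3), v1 = c(2, 1.4), v2 = c(4, 1.4))
  rams <- rbind(
    ram_row("c0", "c", 0, pos$c0[1], pos$c0[2], virtual = TRUE),
    ram_row("c1", "c", 1, pos$c1[1], pos$c1[2]),
    ram_row("c2", "c", 2, pos$c2[1], pos$c2[2]),
    ram_row("p1", "p", 1, pos$p1[1], pos$p1[2]),
    ram_row("x1", "x", 1, pos$x1[1], pos$x1[2]),
    ram_row("a1", "a", 1, pos$a1[1], pos$a1[2]),
    ram_row("a2", "a", 2, pos$a2[1], pos$a2[2]),
    ram_row("v1", "v", 1, pos$v1[1], pos$v1[2]),
    ram_row("v2", "v", 2, pos$v2[1], pos$v2[2]))
  mk <- function(id, s, e) seg_row(id, s, e, rect_between(pos[[s]], pos[[e]], 0.4))
  segs <- rbind(
    mk("P.c1.p1", "c1", "p1"), mk("P.p1.x1", "p1", "x1"),
    mk("P.x1.a1", "x1", "a1"), mk("P.c2.a2", "c2", "a2"),
    mk("P.c0.a1", "c0", "a1"), mk("P.a1.a2", "a1", "a2"),
    mk("P.a1.v1", "a1", "v1"), mk("P.a2.v2", "a2", "v2"))
  make_square_specimen(rams, segs, id = "DEMO")
}

# apply a rigid motion to every geometric element of a specimen
transform_specimen <- function(spec, theta, tx, ty) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  tr_mat <- function(m) sweep(m %*% t(R), 2, c(tx, ty), "+")
  spec$corners <- lapply(spec$corners, function(p) as.numeric(R %*% p + c(tx, ty)))
  for (key in c("tc_contour", "vb_contour", "ili_line", "ci_line", "psi_line",
                "cti_boundary"))
    spec[[key]] <- tr_mat(spec[[key]])
  xy <- tr_mat(cbind(spec$ramifications$x, spec$ramifications$y))
  spec$ramifications$x <- xy[, 1]; spec$ramifications$y <- xy[, 2]
  spec$segments$contour <- lapply(spec$segments$contour, tr_mat)
  spec
}
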