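# Directed PM network: construction, segment-type taxonomy, complexity
# indices (RI/CXI), sector crossings, per-level counts and the six-class
# consolidation of the paraseptal half.
#
# Edges are directed by ascending ramification level (TC -> VB, c < p < x <
# y < a < v). A segment arriving at a ramification is afferent, one leaving
# is efferent. The graph is a multigraph: parallel PM strands between the
# same node pair are distinct edges.

#' Classify a PM segment by the levels it bridges
#'
#' Distinct levels give the two-letter code in ascending level order
#' ("cp", "cv", ..., "av"; 15 codes in total over the six levels); equal
#' levels give the pooled same-level type "ii".
#'
#' @param start_level,end_level level symbols (vectorized)
#' @return character vector of type codes
#' @export
classify_segment_type <- function(start_level, end_level) {
  o1 <- level_order(start_level)
  o2 <- level_order(end_level)
  ifelse(o1 == o2, "ii",
         paste0(CTI_LEVELS[pmin(o1, o2) + 1L], CTI_LEVELS[pmax(o1, o2) + 1L]))
}

#' All segment type codes
#'
#' The 15 distinct-level codes plus the pooled same-level type "ii".
#' @return character vector of length 16
#' @export
segment_types <- function() {
  pairs <- t(utils::combn(CTI_LEVELS, 2))
  c(paste0(pairs[, 1], pairs[, 2]), "ii")
}

#' Build the directed PM network of a specimen
#'
#' Nodes are all ramifications referenced by the included segments (plus any
#' annotated but so-far unreferenced ones); edges are the PM segments,
#' directed from the lower to the higher ramification level. A segment
#' annotated in descending level order is auto-reversed with a warning.
#' Same-level (type "ii") segments are directed from the lower to the higher
#' ramification index, i.e. inferolateral to paraseptal; this keeps every
#' edge contributing exactly one efferent and one afferent so that the
#' conservation laws sum(CXI) = 0 and sum(RI) = 2 |edges| hold on any graph.
#'
#' @param spec a `cti_specimen`
#' @param included_segments segment data.frame (defaults to
#'   `filter_segments(spec)$included`)
#' @return object of class `cti_graph`: list with `nodes` (id, level, index,
#'   virtual, x, y) and `edges` (id, from, to, from_level, to_level, type)
#' @export
build_graph <- function(spec, included_segments = NULL) {
  if (is.null(included_segments)) included_segments <- filter_segments(spec)$included
  r <- spec$ramifications
  s <- included_segments
  missing <- setdiff(c(s$start, s$end), r$id)
  if (length(missing) > 0)
    stop("segment endpoints reference unknown ramifications: ",
         paste(missing, collapse = ", "))

  lev <- stats::setNames(r$level, r$id)
  idx <- stats::setNames(r$index, r$id)
  edges <- data.frame(id = s$id, from = s$start, to = s$end,
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    o_from <- level_order(lev[edges$from])
    o_to <- level_order(lev[edges$to])
    rev_lvl <- o_from > o_to
    rev_ii <- o_from == o_to & idx[edges$from] > idx[edges$to]
    flip <- rev_lvl | rev_ii
    if (any(rev_lvl))
      warning("segment(s) annotated in descending level order auto-reversed: ",
              paste(edges$id[rev_lvl], collapse = ", "))
    if (any(flip)) {
      tmp <- edges$from[flip]
      edges$from[flip] <- edges$to[flip]
      edges$to[flip] <- tmp
    }
    edges$from_level <- as.character(lev[edges$from])
    edges$to_level <- as.character(lev[edges$to])
    edges$type <- classify_segment_type(edges$from_level, edges$to_level)
  } else {
    edges$from_level <- character(0); edges$to_level <- character(0)
    edges$type <- character(0)
  }
  g <- list(nodes = r[, c("id", "level", "index", "virtual", "x", "y")],
            edges = edges)
  class(g) <- "cti_graph"
  g
}

#' @export
print.cti_graph <- function(x, ...) {
  cat("<cti_graph>", nrow(x$nodes), "ramifications,", nrow(x$edges), "PM segments\n")
  if (nrow(x$nodes) > 0) {
    tab <- table(factor(x$nodes$level[!x$nodes$virtual], levels = CTI_LEVELS))
    cat("  levels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  if (nrow(x$edges) > 0) {
    tt <- sort(table(x$edges$type), decreasing = TRUE)
    cat("  types: ", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  }
  invisible(x)
}

#' Ramification and complexity indices of every node
#'
#' For each ramification, N_afferent is the number of incoming PM segments,
#' N_efferent the number of outgoing ones; the ramification index is
#' RI = N_afferent + N_efferent and the complexity index
#' CXI = N_efferent - N_afferent (positive: branching site, negative:
#' merging site). Isolated nodes (degree 0, an annotation artefact) are
#' excluded with a warning.
#'
#' @param graph a `cti_graph`
#' @return data.frame with columns id, level, virtual, n_afferent,
#'   n_efferent, RI, CXI
#' @export
complexity <- function(graph) {
  nd <- graph$nodes
  n_in <- vapply(nd$id, function(id) sum(graph$edges$to == id), integer(1))
  n_out <- vapply(nd$id, function(id) sum(graph$edges$from == id), integer(1))
  iso <- (n_in + n_out) == 0
  if (any(iso))
    warning("isolated ramification(s) excluded (no attached PM segment): ",
            paste(nd$id[iso], collapse = ", "))
  keep <- !iso
  data.frame(id = nd$id[keep], level = nd$level[keep], virtual = nd$virtual[keep],
             n_afferent = n_in[keep], n_efferent = n_out[keep],
             RI = n_in[keep] + n_out[keep], CXI = n_out[keep] - n_in[keep],
             stringsAsFactors = FALSE)
}

# sectors as open intervals on the level order axis
SECTOR_INTERVALS <- list(posterior = c(0, 1), central = c(1, 4), anterior = c(4, 5))

#' Number of PM segments crossing each CTI sector
#'
#' The CTI is divided into the posterior (between levels c and p), central
#' (between p and a, containing the sublevels x and y) and anterior (between
#' a and v) sectors. A segment crosses a sector iff the open interval of
#' level orders it bridges overlaps the sector's open interval; a segment
#' spanning c to v therefore crosses all three, and same-level ("ii")
#' segments cross none.
#'
#' @param graph a `cti_graph`
#' @return named integer vector (posterior, central, anterior)
#' @export
sector_crossings <- function(graph) {
  e <- graph$edges
  out <- c(posterior = 0L, central = 0L, anterior = 0L)
  if (nrow(e) == 0) return(out)
  o1 <- level_order(e$from_level)
  o2 <- level_order(e$to_level)
  lo <- pmin(o1, o2); hi <- pmax(o1, o2)
  for (sec in names(SECTOR_INTERVALS)) {
    iv <- SECTOR_INTERVALS[[sec]]
    out[sec] <- sum(pmax(lo, iv[1]) < pmin(hi, iv[2]))
  }
  out
}

#' Per-level ramification counts and topology summary
#'
#' Counts ramifications per level (virtual anchor points with index 0 are
#' excluded from the counts, though they remain valid segment endpoints),
#' the c-to-v ratio R.c / R.v comparing PM network entry and exit sites
#' (0 when R.c = 0; NA with `rv_zero = TRUE` when R.v = 0), sector crossings
#' and the segment-type histogram.
#'
#' @param graph a `cti_graph`
#' @return object of class `cti_topology`: list with `counts` (named integer
#'   per level), `total`, `rc_rv_ratio`, `rv_zero`, `crossings`,
#'   `type_histogram`
#' @export
level_counts <- function(graph) {
  nd <- graph$nodes[!graph$nodes$virtual, , drop = FALSE]
  counts <- table(factor(nd$level, levels = CTI_LEVELS))
  counts <- stats::setNames(as.integer(counts), CTI_LEVELS)
  rv_zero <- counts["v"] == 0
  ratio <- if (rv_zero) NA_real_ else unname(counts["c"] / counts["v"])
  th <- table(factor(graph$edges$type, levels = segment_types()))
  out <- list(counts = counts, total = sum(counts),
              rc_rv_ratio = ratio, rv_zero = unname(rv_zero),
              crossings = sector_crossings(graph),
              type_histogram = stats::setNames(as.integer(th), segment_types()))
  class(out) <- "cti_topology"
  out
}

#' @export
print.cti_topology <- function(x, ...) {
  cat("<cti_topology>", x$total, "ramifications within the CTI\n")
  cat("  per level: ", paste(sprintf("R.%s=%d", names(x$counts), x$counts), collapse = " "), "\n")
  cat("  R.c / R.v: ", if (x$rv_zero) "undefined (R.v = 0)" else signif(x$rc_rv_ratio, 4), "\n")
  cat("  sector crossings:",
      paste(sprintf("%s=%d", names(x$crossings), x$crossings), collapse = " "), "\n")
  invisible(x)
}

#' Validate the level ordering of a PM network
#'
#' By definition level c nodes are TC exit sites (no afferents), level v
#' nodes are VB entry sites (no efferents), and directed paths must visit
#' levels in ascending order. Violations are reported as warnings in a
#' diagnostics table, not raised.
#'
#' @param graph a `cti_graph`
#' @return data.frame with columns severity, field, message
#' @export
level_order_validate <- function(graph) {
  d <- diag_row(character(0), character(0), character(0))
  e <- graph$edges
  nd <- graph$nodes
  if (nrow(e) == 0) return(d)
  c_in <- e$to %in% nd$id[nd$level == "c"]
  if (any(c_in))
    d <- rbind(d, diag_row("warning", "segments",
                           paste0("afferent at level c (TC exit site): ",
                                  paste(e$id[c_in], collapse = ","))))
  v_out <- e$from %in% nd$id[nd$level == "v"]
  if (any(v_out))
    d <- rbind(d, diag_row("warning", "segments",
                           paste0("efferent at level v (VB entry site): ",
                                  paste(e$id[v_out], collapse = ","))))
  desc <- level_order(e$from_level) > level_order(e$to_level)
  if (any(desc))
    d <- rbind(d, diag_row("warning", "segments",
                           paste0("descending level on path: ",
                                  paste(e$id[desc], collapse = ","))))
  d
}

PARASEPTAL_CLASSES <- c("Plain", "Simple", "SimpleCrossoverILPS",
                        "SimpleCrossoverPSIL", "ComplexNoCrossover",
                        "ComplexCrossover")

#' Consolidated complexity class of the paraseptal NCTI half
#'
#' Classifies the network restricted to the paraseptal half (normalized
#' l > 0.5) into one of six classes:
#' \itemize{
#'   \item `Plain`: no PM segment touches the paraseptal half.
#'   \item `Simple`: only unbranched or parallel segments (every
#'     paraseptal-half node has RI <= 2 on the restricted subgraph).
#'   \item `SimpleCrossoverILPS` / `SimpleCrossoverPSIL`: Simple, with a
#'     segment entering from (start l <= 0.5, end l > 0.5) or leaving into
#'     (start l > 0.5, end l <= 0.5) the inferolateral half; when both
#'     crossover directions occur without branching, the entering
#'     (IL-to-PS) variant takes precedence.
#'   \item `ComplexNoCrossover` / `ComplexCrossover`: some paraseptal-half
#'     node branches or merges (RI >= 3 on the restricted subgraph),
#'     without / with crossover segments.
#' }
#'
#' @param graph a `cti_graph`
#' @param normalized_points data.frame with columns id, l (e.g. from
#'   [normalize_specimen()]); every node of the graph must appear
#' @return one of "Plain", "Simple", "SimpleCrossoverILPS",
#'   "SimpleCrossoverPSIL", "ComplexNoCrossover", "ComplexCrossover"
#' @export
classify_paraseptal_half <- function(graph, normalized_points) {
  lpos <- stats::setNames(normalized_points$l, normalized_points$id)
  missing <- setdiff(graph$nodes$id, names(lpos))
  if (length(missing) > 0)
    stop("missing normalized coordinates for node(s): ", paste(missing, collapse = ", "))
  e <- graph$edges
  if (nrow(e) == 0) return("Plain")
  l_from <- unname(lpos[e$from]); l_to <- unname(lpos[e$to])
  touches <- l_from > 0.5 | l_to > 0.5
  if (!any(touches)) return("Plain")
  sub <- e[touches, , drop = FALSE]
  cross_ilps <- any(l_from[touches] <= 0.5 & l_to[touches] > 0.5)
  cross_psil <- any(l_from[touches] > 0.5 & l_to[touches] <= 0.5)
  # RI on the restricted subgraph, paraseptal-half nodes only
  right_nodes <- graph$nodes$id[unname(lpos[graph$nodes$id]) > 0.5]
  ri <- vapply(right_nodes, function(id) sum(sub$from == id) + sum(sub$to == id),
               integer(1))
  complex <- length(ri) > 0 && any(ri >= 3)
  if (complex) {
    if (cross_ilps || cross_psil) "ComplexCrossover" else "ComplexNoCrossover"
  } else if (cross_ilps) {
    "SimpleCrossoverILPS"
  } else if (cross_psil) {
    "SimpleCrossoverPSIL"
  } else {
    "Simple"
  }
}
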