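# Synthetic annotation cohorts with ground truth.
#
# The generator emulates the statistical structure the analysis layer
# assumes: body weights coupled to CTI area by a Gaussian copula on ranks,
# trapezoidal corner layouts with decremental isthmus lengths, per-level
# ramification counts, level-by-level PM wiring with calibrated efferent and
# target-level distributions, per-type segment diameters, and a deliberate
# per-class construction of the paraseptal half. PM contours are rectangles,
# so the rectangle-equivalent estimator recovers each segment's (L, D)
# exactly and parameter-recovery tests are sharp.
#
# Node positions are drawn in normalized (l, m) coordinates and pushed
# through the specimen's own bilinear map into image coordinates, so the
# normalization stage can recover them.

#' Generator parameters
#'
#' Loads the versioned default parameter set shipped with the package
#' (calibrated to the bundled reference cohort statistics) and applies any
#' overrides. Overrides are merged recursively, so
#' `generator_params(isthmus_mm = list(ili_mean = 10))` changes one entry
#' and keeps the rest.
#'
#' @param ... named overrides of the defaults
#' @return list of class `cti_generator_params`
#' @export
generator_params <- function(...) {
  path <- system.file("extdata", "default_params.json", package = "ctimorph")
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dots <- list(...)
  if (length(dots) > 0) p <- utils::modifyList(p, dots)
  stopifnot(all(unlist(p$efferent_probs) >= 0))
  class(p) <- c("cti_generator_params", "list")
  p
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# discrete count draw around a median with ~IQR spread
rcount <- function(median, iqr, lo, hi) {
  sd <- max(iqr / 1.349, 0.25)
  as.integer(pmin(pmax(round(stats::rnorm(1, median, sd)), lo), hi))
}

sample_level_counts <- function(p) {
  counts <- vapply(CTI_LEVELS, function(lv) {
    lc <- p$level_counts[[lv]]
    rcount(lc$median, lc$iqr, lc$min, lc$max)
  }, integer(1))
  counts
}

# diameter draw for a segment type: lognormal around the type median with
# spread matched to the raw MAD, floored above the inclusion threshold
sample_diameter <- function(p, type) {
  sd_ <- p$segment_diameter_mm[[type]]
  med <- sd_$median
  mad_ <- if (is.null(sd_$mad) || is.na(sd_$mad)) 0.15 * med else sd_$mad
  sdlog <- mad_ / (0.6745 * med)
  max(p$min_segment_diameter_mm, med * exp(stats::rnorm(1, 0, sdlog)))
}

new_node <- function(level, l, m, virtual = FALSE) {
  data.frame(level = level, l = l, m = m,
             virtual = rep_len(virtual, length(level)),
             stringsAsFactors = FALSE)
}

#' Generate one synthetic specimen with ground truth
#'
#' Builds a fully annotated specimen: (1) body weight and CTI scale from a
#' rank-preserving (Gaussian copula) coupling; (2) a trapezoidal corner
#' layout with isthmus lengths decreasing from inferolateral to paraseptal
#' (occasional inversions arise from the sampled ratio distributions), mild
#' corner jitter and a random rigid motion; (3) per-level ramification
#' counts and placement priors in normalized coordinates (branching sites
#' near 75% of the NCTI height, merging sites near 30%, entries/exits along
#' TC and VB, laterally biased inferolateral); (4) level-by-level wiring
#' with calibrated efferent-count and target-level distributions, every
#' non-c node receiving an afferent and every non-v node an efferent, plus
#' rare same-level (ii) edges and, when the ramification level c is empty,
#' a virtual anchor c0 outside the ROI; (5) rectangular segment contours of
#' sampled length (node distance x tortuosity) and per-type diameter;
#' (6) the paraseptal half populated by a deliberate class motif
#' (Plain/Simple/crossover/complex), drawn from the configured class
#' mixture unless `paraseptal_class` is given.
#'
#' @param params a [generator_params()] object
#' @param seed optional integer seed for this specimen (set via
#'   `set.seed`); `NULL` uses the current RNG state
#' @param specimen_id identifier for the generated specimen
#' @param force_level_counts optional named integer vector (names from
#'   `CTI_LEVELS`) forcing the exact per-level ramification counts; the
#'   paraseptal class motif is skipped and nodes span the full CTI width
#' @param paraseptal_class force one of the six paraseptal classes;
#'   `NULL` samples from `params$paraseptal_class_weights`
#' @return list with `specimen` (a `cti_specimen`) and `truth` (corner
#'   coordinates, isthmus lengths and ratios, per-level counts, per-segment
#'   type/L/D, CTI area, class label)
#' @export
generate_specimen <- function(params = generator_params(), seed = NULL,
                              specimen_id = "SYN001",
                              force_level_counts = NULL,
                              paraseptal_class = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params

  ## (1) weight and CTI area via Gaussian copula on ranks
  rho_s <- p$cti_area_mm2$spearman_with_weight
  r <- 2 * sin(pi * rho_s / 6)
  z1 <- stats::rnorm(1)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(1)
  weight <- exp(p$weight_kg$meanlog + p$weight_kg$sdlog * z1)
  area_target <- exp(p$cti_area_mm2$meanlog + p$cti_area_mm2$sdlog * z2)

  ## (2) trapezoid corner layout
  ili <- rtrunc_norm(1, p$isthmus_mm$ili_mean, p$isthmus_mm$ili_sd,
                     lo = p$isthmus_mm$ili_min)
  repeat {
    ci <- ili * rtrunc_norm(1, p$isthmus_mm$ci_ili_ratio_mean,
                            p$isthmus_mm$ci_ili_ratio_sd, lo = 0.3, hi = 1.25)
    psi <- ci * rtrunc_norm(1, p$isthmus_mm$psi_ci_ratio_mean,
                            p$isthmus_mm$psi_ci_ratio_sd, lo = 0.12, hi = 1.1)
    if (psi < ili && psi > 1) break   # PSI < ILI in every preparation
  }
  W <- 4 * area_target / (ili + 2 * ci + psi)

  corners0 <- NULL
  for (try_i in 1:20) {
    jsd <- if (try_i < 20) p$corner_jitter_frac * W else 0
    jx <- stats::rnorm(3, 0, jsd)
    cand <- list(ilV = c(0, 0), cV = c(W / 2, 0), psV = c(W, 0),
                 ilC = c(jx[1], ili), cC = c(W / 2 + jx[2], ci),
                 psC = c(W + jx[3], psi))
    lq <- rbind(cand$ilV, cand$cV, cand$cC, cand$ilC)
    rq <- rbind(cand$cV, cand$psV, cand$psC, cand$cC)
    if (quad_is_convex(lq) && quad_is_convex(rq)) { corners0 <- cand; break }
  }
  if (is.null(corners0)) stop("generation error: could not build convex corner layout")
  theta <- stats::runif(1, 0, 2 * pi)
  shift <- stats::runif(2, 0, 30)
  corners <- lapply(corners0, function(pt) as.numeric(rigid_transform(rbind(pt), theta, shift[1], shift[2])))
  bmap <- fit_bilinear(corners)

  ## (3) ramification counts and placement
  forced <- !is.null(force_level_counts)
  if (forced) {
    counts <- stats::setNames(rep(0L, 6), CTI_LEVELS)
    counts[names(force_level_counts)] <- as.integer(force_level_counts)
    n_nonv <- sum(counts[c("c", "p", "x", "y", "a")])
    if (counts["v"] == 0 && n_nonv > 0)
      stop("infeasible params: zero level-v ramifications but non-v ramifications present (PM paths cannot terminate)")
    cls <- NULL
  } else {
    counts <- sample_level_counts(p)
    cls <- paraseptal_class
    if (is.null(cls)) {
      w <- unlist(p$paraseptal_class_weights)
      cls <- sample(names(w), 1, prob = w / sum(w))
    }
    cls <- match.arg(cls, PARASEPTAL_CLASSES)
  }

  l_hi <- if (forced) 0.98 else 0.47  # base network confined inferolateral unless counts are forced
  nodes <- do.call(rbind, lapply(CTI_LEVELS, function(lv) {
    n <- counts[[lv]]
    if (n == 0) return(NULL)
    l <- 0.02 + (l_hi - 0.02) * stats::rbeta(n, 1.2, 1.5)
    m <- rtrunc_norm(n, p$level_m[[lv]], p$level_m_sd,
                     lo = p$level_m[[lv]] - 0.08, hi = p$level_m[[lv]] + 0.08)
    new_node(rep(lv, n), l, m)
  }))
  if (is.null(nodes)) nodes <- new_node(character(0), numeric(0), numeric(0))

  ## paraseptal class motif (adds nodes/edges on the right half)
  motif <- build_class_motif(cls, nodes, p)
  nodes <- rbind(nodes, motif$nodes)
  base_ids <- setdiff(seq_len(nrow(nodes)), motif$node_rows)

  ## (4) wiring (row indices into `nodes`)
  wir <- wire_network(nodes, base_ids, p)
  edges <- rbind(wir$edges, motif$edges)
  nodes <- wir$nodes  # may gain a virtual anchor

  ## assign ids: per level, index by ascending l (inferolateral -> paraseptal)
  nodes$index <- 0L
  for (lv in CTI_LEVELS) {
    rows <- which(nodes$level == lv & !nodes$virtual)
    nodes$index[rows[order(nodes$l[rows])]] <- seq_along(rows)
  }
  nodes$id <- paste0(nodes$level, nodes$index)

  ## (5, 6) image coordinates and rectangular contours
  img <- to_image(bmap, nodes$l, nodes$m)
  nodes$x <- img[, 1]; nodes$y <- img[, 2]

  seg_rows <- list(); seg_truth <- list()
  if (nrow(edges) > 0) {
    # parallel strands between the same node pair get a #k suffix
    edge_ids <- make.unique(paste0("P.", nodes$id[edges$from], ".",
                                   nodes$id[edges$to]), sep = "#")
    for (k in seq_len(nrow(edges))) {
      u <- edges$from[k]; w <- edges$to[k]
      type <- classify_segment_type(nodes$level[u], nodes$level[w])
      p1 <- c(nodes$x[u], nodes$y[u]); p2 <- c(nodes$x[w], nodes$y[w])
      dvec <- p2 - p1
      dist <- sqrt(sum(dvec^2))
      L <- max(dist * (1 + abs(stats::rnorm(1, 0, p$tortuosity_sd))), 0.3)
      D <- min(sample_diameter(p, type), 0.8 * L)
      D <- max(D, p$min_segment_diameter_mm)
      uv <- if (dist > 1e-9) dvec / dist else c(1, 0)
      nv <- c(-uv[2], uv[1])
      mid <- (p1 + p2) / 2
      if (edges$offset[k] != 0) mid <- mid + nv * edges$offset[k] * D
      ct <- rbind(mid - uv * L / 2 - nv * D / 2, mid + uv * L / 2 - nv * D / 2,
                  mid + uv * L / 2 + nv * D / 2, mid - uv * L / 2 + nv * D / 2)
      id <- edge_ids[k]
      srow <- data.frame(id = id, start = nodes$id[u], end = nodes$id[w],
                         endocardial = TRUE, orthogonal_epicardial = FALSE,
                         stringsAsFactors = FALSE)
      srow$contour <- list(ct)
      seg_rows[[k]] <- srow
      seg_truth[[k]] <- data.frame(id = id, type = type, L = L, D = D,
                                   A = L * D, stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_rows) > 0) do.call(rbind, seg_rows) else {
    s0 <- data.frame(id = character(0), start = character(0), end = character(0),
                     endocardial = logical(0), orthogonal_epicardial = logical(0))
    s0$contour <- list(); s0
  }

  ## boundary geometry from the (already transformed) corners
  tc_d <- rtrunc_norm(1, p$tc_diameter_mm$mean, p$tc_diameter_mm$sd, lo = p$tc_diameter_mm$min)
  vb_d <- rtrunc_norm(1, p$vb_diameter_mm$mean, p$vb_diameter_mm$sd, lo = p$vb_diameter_mm$min)
  inward <- function(top, bottom, d) top + (bottom - top) * d / sqrt(sum((bottom - top)^2))
  tc_contour <- rbind(corners$ilC, corners$cC, corners$psC,
                      inward(corners$psC, corners$psV, tc_d),
                      inward(corners$cC, corners$cV, tc_d),
                      inward(corners$ilC, corners$ilV, tc_d))
  vb_contour <- rbind(corners$ilV, corners$cV, corners$psV,
                      inward(corners$psV, corners$psC, vb_d),
                      inward(corners$cV, corners$cC, vb_d),
                      inward(corners$ilV, corners$ilC, vb_d))
  cti_boundary <- rbind(corners$ilV, corners$cV, corners$psV,
                        corners$psC, corners$cC, corners$ilC)

  ram_df <- data.frame(id = nodes$id, level = nodes$level, index = nodes$index,
                       x = nodes$x, y = nodes$y, virtual = nodes$virtual,
                       stringsAsFactors = FALSE)
  spec <- new_cti_specimen(
    specimen_id = specimen_id,
    species = sample(names(p$species_probs), 1, prob = unlist(p$species_probs)),
    sex = sample(names(p$sex_probs), 1, prob = unlist(p$sex_probs)),
    body_weight = weight,
    resolution = stats::runif(1, p$resolution_um_per_px[1], p$resolution_um_per_px[2]),
    corners = corners,
    tc_contour = tc_contour, vb_contour = vb_contour,
    ili_line = rbind(corners$ilV, corners$ilC),
    ci_line = rbind(corners$cV, corners$cC),
    psi_line = rbind(corners$psV, corners$psC),
    cti_boundary = cti_boundary,
    ramifications = ram_df, segments = segments)

  truth_counts <- stats::setNames(vapply(CTI_LEVELS, function(lv)
    sum(ram_df$level == lv & !ram_df$virtual), integer(1)), CTI_LEVELS)
  ili_true <- sqrt(sum((corners$ilC - corners$ilV)^2))
  ci_true <- sqrt(sum((corners$cC - corners$cV)^2))
  psi_true <- sqrt(sum((corners$psC - corners$psV)^2))
  npts <- data.frame(id = nodes$id, l = nodes$l, m = nodes$m, stringsAsFactors = FALSE)
  g <- build_graph(spec, segments)
  cls_actual <- classify_paraseptal_half(g, npts)
  truth <- list(
    specimen_id = specimen_id, weight = weight,
    corners = corners,
    cti_area = poly_area(cti_boundary),
    ili = ili_true, ci = ci_true, psi = psi_true,
    ratio_ci_ili = ci_true / ili_true, ratio_psi_ci = psi_true / ci_true,
    ratio_psi_ili = psi_true / ili_true,
    level_counts = truth_counts,
    segments = if (length(seg_truth) > 0) do.call(rbind, seg_truth) else NULL,
    normalized = npts,
    class = cls_actual,
    class_requested = if (forced) NA_character_ else cls
  )
  list(specimen = spec, truth = truth)
}

# ---- internals ------------------------------------------------------------

# Deliberate construction of the paraseptal (l > 0.5) half for one of the
# six consolidation classes. Returns extra nodes (right half), edges
# referencing row indices (negative indices count into the new nodes), and
# is resolved against the full node table by the caller.
build_class_motif <- function(cls, base_nodes, p) {
  empty <- list(nodes = new_node(character(0), numeric(0), numeric(0)),
                edges = data.frame(from = integer(0), to = integer(0), offset = numeric(0)),
                node_rows = integer(0))
  if (is.null(cls) || cls == "Plain") return(empty)
  n0 <- nrow(base_nodes)
  rl <- function() stats::runif(1, 0.55, 0.92)
  mm <- function(lv) rtrunc_norm(1, p$level_m[[lv]], p$level_m_sd,
                                 lo = p$level_m[[lv]] - 0.08, hi = p$level_m[[lv]] + 0.08)
  add <- function(lv) new_node(lv, rl(), mm(lv))
  left_source <- function(max_order) {
    ok <- which(level_order(base_nodes$level) < max_order & !base_nodes$virtual)
    if (length(ok) == 0) NA_integer_ else ok[which.max(base_nodes$l[ok])]
  }
  left_sink_v <- function() {
    ok <- which(base_nodes$level == "v" & !base_nodes$virtual)
    if (length(ok) == 0) NA_integer_ else ok[which.max(base_nodes$l[ok])]
  }
  nodes <- NULL; edges <- NULL
  if (cls == "Simple") {
    nodes <- rbind(add("c"), add("v"))
    edges <- data.frame(from = n0 + 1L, to = n0 + 2L, offset = 0)
    if (stats::runif(1) < 0.3)  # parallel strand between the same pair
      edges <- rbind(edges, data.frame(from = n0 + 1L, to = n0 + 2L, offset = 1.2))
  } else if (cls == "SimpleCrossoverILPS") {
    nodes <- rbind(add("a"), add("v"))
    src <- left_source(level_order("a"))
    if (is.na(src)) { # no inferolateral source: fall back to a right c node
      nodes <- rbind(add("c"), nodes)
      src <- n0 + 1L
      edges <- data.frame(from = c(src, n0 + 2L), to = c(n0 + 2L, n0 + 3L), offset = 0)
    } else {
      edges <- data.frame(from = c(src, n0 + 1L), to = c(n0 + 1L, n0 + 2L), offset = 0)
    }
  } else if (cls == "SimpleCrossoverPSIL") {
    nodes <- rbind(add("c"), add("a"))
    snk <- left_sink_v()
    if (is.na(snk)) stop("infeasible params: paraseptal crossover PS-IL needs a level-v ramification in the inferolateral half")
    edges <- data.frame(from = c(n0 + 1L, n0 + 2L), to = c(n0 + 2L, snk), offset = 0)
  } else if (cls %in% c("ComplexNoCrossover", "ComplexCrossover")) {
    nodes <- rbind(add("c"), add("p"), add("v"), add("v"))
    edges <- data.frame(from = c(n0 + 1L, n0 + 2L, n0 + 2L),
                        to = c(n0 + 2L, n0 + 3L, n0 + 4L), offset = 0)
    if (cls == "ComplexCrossover") {
      src <- left_source(level_order("p"))
      if (!is.na(src))
        edges <- rbind(edges, data.frame(from = src, to = n0 + 2L, offset = 0))
      else  # no left c node: cross over out of the half instead
        edges <- rbind(edges, data.frame(from = n0 + 2L,
                                         to = left_sink_v(), offset = 0))
    }
  }
  list(nodes = nodes, edges = edges, node_rows = n0 + seq_len(nrow(nodes)))
}

# Level-by-level wiring of the base network (node row indices in `base_ids`).
# Ensures every non-c base node has an afferent and every non-v base node an
# efferent; adds rare same-level (ii) edges; creates a virtual anchor c0
# outside the ROI when level c is empty (or occasionally regardless).
wire_network <- function(nodes, base_ids, p) {
  edges <- data.frame(from = integer(0), to = integer(0), offset = numeric(0))
  bn <- nodes[base_ids, , drop = FALSE]
  lv_of <- nodes$level
  present <- function(lv) base_ids[lv_of[base_ids] == lv & !nodes$virtual[base_ids]]

  indeg <- integer(nrow(nodes))
  # lateral proximity, boosted for nodes still lacking an afferent so that
  # coverage spreads instead of piling onto few nodes
  pick_target <- function(u, tgt_rows) {
    wgt <- exp(-abs(nodes$l[tgt_rows] - nodes$l[u]) / 0.15) *
      ifelse(indeg[tgt_rows] == 0, 4, 1)
    tgt_rows[sample.int(length(tgt_rows), 1, prob = wgt)]
  }
  add_edge <- function(u, w) {
    edges <<- rbind(edges, data.frame(from = u, to = w, offset = 0))
    indeg[w] <<- indeg[w] + 1L
  }

  for (lv in c("c", "p", "x", "y", "a")) {
    rows <- present(lv)
    if (length(rows) == 0) next
    probs <- p$efferent_probs[[lv]]
    tl <- p$target_level_probs[[lv]]
    for (u in rows) {
      n_eff <- sample.int(length(probs), 1, prob = probs)
      for (e in seq_len(n_eff)) {
        # target level: calibrated distribution restricted to populated levels
        avail <- names(tl)[vapply(names(tl), function(x) length(present(x)) > 0, logical(1))]
        if (length(present("v")) == 0)
          stop("infeasible params: no level-v ramifications to terminate PM paths")
        if (length(avail) == 0) tgt_lv <- "v"
        else {
          pr <- unlist(tl[avail])
          tgt_lv <- sample(avail, 1, prob = pr / sum(pr))
        }
        tgt_rows <- present(tgt_lv)
        if (length(tgt_rows) == 0) tgt_rows <- present("v")
        add_edge(u, pick_target(u, tgt_rows))
      }
    }
  }

  # afferent repair: every non-c base node needs at least one incoming edge
  virtual_row <- NA_integer_
  get_anchor <- function() {
    if (is.na(virtual_row)) {
      nodes <<- rbind(nodes, new_node("c", -0.05, 0.95, virtual = TRUE))
      virtual_row <<- nrow(nodes)
    }
    virtual_row
  }
  for (lv in c("p", "x", "y", "a", "v")) {
    rows <- present(lv)
    for (w in rows) {
      if (any(edges$to == w)) next
      # repair from the nearest lower populated level (e.g. a -> v)
      lower_lvs <- CTI_LEVELS[seq_len(level_order(lv))]
      src <- NA_integer_
      for (src_lv in rev(lower_lvs)) {
        cand <- present(src_lv)
        if (length(cand) > 0) {
          wgt <- exp(-abs(nodes$l[cand] - nodes$l[w]) / 0.15)
          src <- cand[sample.int(length(cand), 1, prob = wgt)]
          break
        }
      }
      if (is.na(src)) src <- get_anchor()
      edges <- rbind(edges, data.frame(from = src, to = w, offset = 0))
    }
  }
  # occasional virtual anchor even when level c is populated
  if (is.na(virtual_row) && stats::runif(1) < p$virtual_anchor_prob) {
    tgt_rows <- c(present("p"), present("x"), present("a"))
    if (length(tgt_rows) > 0) {
      src <- get_anchor()
      edges <- rbind(edges, data.frame(from = src, to = tgt_rows[sample.int(length(tgt_rows), 1)], offset = 0))
    }
  }
  # rare same-level connections, directed inferolateral -> paraseptal
  n_ii <- stats::rbinom(1, p$ii_edges_max, p$ii_edge_prob)
  for (k in seq_len(n_ii)) {
    lvs <- c("p", "x", "a")
    lvs <- lvs[vapply(lvs, function(x) length(present(x)) >= 2, logical(1))]
    if (length(lvs) == 0) break
    lv <- sample(lvs, 1)
    rows <- present(lv)
    o <- order(nodes$l[rows])
    i0 <- sample.int(length(rows) - 1, 1)
    edges <- rbind(edges, data.frame(from = rows[o[i0]], to = rows[o[i0 + 1]], offset = 0))
  }
  list(edges = edges, nodes = nodes)
}

#' Generate a synthetic cohort
#'
#' Draws `n` specimens with independent per-specimen RNG substreams derived
#' from `seed`, so cohorts are reproducible and order-independent.
#' Optionally writes the annotation files, a manifest CSV and the ground
#' truth (JSON) to a directory.
#'
#' @param params a [generator_params()] object
#' @param n number of specimens (default `params$n_specimens`)
#' @param seed integer base seed
#' @param dir optional output directory; created if needed
#' @param ... passed on to [generate_specimen()] (e.g. `paraseptal_class`)
#' @return list with `specimens` (list of `cti_specimen`), `truths`
#'   (list of truth records), `manifest` (data.frame) and `dir`
#' @export
generate_cohort <- function(params = generator_params(), n = params$n_specimens,
                            seed = 1, dir = NULL, ...) {
  specimens <- list(); truths <- list()
  rows <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("SYN%03d", i)
    sub_seed <- (seed + 7919 * i) %% 2147483629
    g <- generate_specimen(params, seed = sub_seed, specimen_id = sid, ...)
    specimens[[sid]] <- g$specimen
    truths[[sid]] <- g$truth
    rows[[i]] <- data.frame(id = sid, species = g$specimen$species,
                            sex = g$specimen$sex,
                            body_weight_kg = g$specimen$body_weight,
                            class = g$truth$class, stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(id = character(0), species = character(0), sex = character(0),
               body_weight_kg = numeric(0), class = character(0))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(specimens))
      write_specimen(specimens[[sid]], file.path(dir, paste0(sid, ".json")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(truths, digits = NA, auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "truth.json"))
  }
  list(specimens = specimens, truths = truths, manifest = manifest, dir = dir)
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Runs the full analysis pipeline (segment filters, morphometry, bilinear
#' normalization, network topology, paraseptal classification) on each
#' generated specimen and compares the results against the generator's
#' ground truth. Rectangle-equivalent L/D, per-level counts and class labels
#' are expected to agree exactly; areas and lengths are reported with their
#' errors.
#'
#' @param cohort result of [generate_cohort()]
#' @return list with `segments` (per-segment truth vs estimate),
#'   `specimens` (per-specimen isthmus/count/class agreement) and `summary`
#'   (max absolute L/D error, count and class recovery rates, mean CI/ILI
#'   ratio estimate vs truth)
#' @export
recovery_report <- function(cohort) {
  seg_rows <- list(); spec_rows <- list()
  for (sid in names(cohort$specimens)) {
    spec <- cohort$specimens[[sid]]
    truth <- cohort$truths[[sid]]
    filt <- filter_segments(spec)
    sm <- segment_morphometry(spec, filt$included)
    tr <- truth$segments
    if (!is.null(tr)) {
      mrg <- merge(tr, sm[, c("id", "L", "D", "A")], by = "id",
                   suffixes = c("_true", "_est"))
      mrg$specimen_id <- sid
      seg_rows[[sid]] <- mrg
    }
    g <- build_graph(spec, filt$included)
    lc <- level_counts(g)
    np <- suppressWarnings(normalize_specimen(spec))
    cls <- classify_paraseptal_half(g, np)
    morph <- suppressWarnings(specimen_morphometry(spec, filt$included))
    spec_rows[[sid]] <- data.frame(
      specimen_id = sid,
      counts_exact = all(lc$counts == truth$level_counts),
      class_true = truth$class, class_est = cls,
      class_match = identical(cls, truth$class),
      ili_est = morph$ILI_L, ili_true = truth$ili,
      ratio_ci_ili_est = morph$ratio_CI_ILI, ratio_ci_ili_true = truth$ratio_ci_ili,
      cti_area_est = morph$CTI_A, cti_area_true = truth$cti_area,
      stringsAsFactors = FALSE)
  }
  segments <- if (length(seg_rows) > 0) do.call(rbind, seg_rows) else NULL
  specimens <- do.call(rbind, spec_rows)
  summary <- list(
    n = nrow(specimens),
    max_L_abs_err = if (is.null(segments)) NA_real_ else max(abs(segments$L_true - segments$L_est)),
    max_D_abs_err = if (is.null(segments)) NA_real_ else max(abs(segments$D_true - segments$D_est)),
    count_recovery_rate = mean(specimens$counts_exact),
    class_recovery_rate = mean(specimens$class_match),
    mean_ratio_ci_ili_est = mean(specimens$ratio_ci_ili_est),
    mean_ratio_ci_ili_true = mean(specimens$ratio_ci_ili_true),
    max_area_rel_err = max(abs(specimens$cti_area_est / specimens$cti_area_true - 1))
  )
  list(segments = segments, specimens = specimens, summary = summary)
}
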