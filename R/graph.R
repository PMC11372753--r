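## Graph-network quantification of lateral aggregation: distance-cutoff
## neighbour graphs per species, node degree and pairwise connectivity.

## Edge list (2-col matrix of indices into `rows`) for all periodic-xy pairs
## within cutoff, brute force. Oracle path; also the fallback when the box is
## too small for a cell grid.
edges_bruteforce <- function(x, y, Lx, Ly, cutoff) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(), ncol = 2))
  d <- pairwise_xy_dist(cbind(x, y), cbind(x, y), Lx, Ly)
  hits <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  unname(as.matrix(hits))
}

## Cell-list neighbour search, O(n) for fixed density: bin sites into a grid
## with cell size >= cutoff and compare each cell with itself and its 8
## periodic neighbours.
edges_celllist <- function(x, y, Lx, Ly, cutoff) {
  ncx <- max(1L, floor(Lx / cutoff))
  ncy <- max(1L, floor(Ly / cutoff))
  if (ncx < 3L || ncy < 3L) return(edges_bruteforce(x, y, Lx, Ly, cutoff))
  cx <- pmin(floor(x / (Lx / ncx)), ncx - 1L)
  cy <- pmin(floor(y / (Ly / ncy)), ncy - 1L)
  cell <- cx + ncx * cy
  members <- split(seq_along(x), factor(cell, levels = 0:(ncx * ncy - 1L)))
  out <- vector("list", ncx * ncy * 5L)
  k <- 0L
  ## half-stencil so each cell pair is visited once
  stencil <- rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (cyi in 0:(ncy - 1L)) for (cxi in 0:(ncx - 1L)) {
    a <- members[[cxi + ncx * cyi + 1L]]
    if (!length(a)) next
    for (s in seq_len(nrow(stencil))) {
      nx <- (cxi + stencil[s, 1]) %% ncx
      ny <- (cyi + stencil[s, 2]) %% ncy
      b <- members[[nx + ncx * ny + 1L]]
      if (!length(b)) next
      if (s == 1L) {
        if (length(a) < 2L) next
        d <- pairwise_xy_dist(cbind(x[a], y[a]), cbind(x[a], y[a]), Lx, Ly)
        hits <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
        if (nrow(hits)) { k <- k + 1L; out[[k]] <- cbind(a[hits[, 1]], a[hits[, 2]]) }
      } else {
        d <- pairwise_xy_dist(cbind(x[a], y[a]), cbind(x[b], y[b]), Lx, Ly)
        hits <- which(d <= cutoff, arr.ind = TRUE)
        if (nrow(hits)) { k <- k + 1L; out[[k]] <- cbind(a[hits[, 1]], b[hits[, 2]]) }
      }
    }
  }
  if (k == 0L) return(matrix(integer(), ncol = 2))
  e <- do.call(rbind, out[seq_len(k)])
  ## canonical order + dedupe (a pair can be seen twice when the grid wraps)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unname(unique(e))
}

#' Build the same-type neighbour graph of a frame
#'
#' Nodes are the present molecules of one species; an edge joins two nodes
#' whose periodic xy distance is at most \code{cutoff}. Distances use the
#' monolayer plane only (vertical staggering must not distort lateral
#' neighbour shells) and molecules in different leaflets are never joined.
#' On a pure hexagonal lattice at 20 \enc{Å}{Angstrom}^2/molecule with a
#' first-shell cutoff (7.2 \enc{Å}{Angstrom}) the graph is 6-regular.
#'
#' @param frame a [monolayer_frame()].
#' @param species species label, or \code{"all"}.
#' @param cutoff distance cutoff (\enc{Å}{Angstrom}), > 0.
#' @param method \code{"cell"} (cell-list search, default) or
#'   \code{"brute"} (all-pairs; the reference path).
#' @return Object of class \code{same_type_graph}: list with
#'   \code{nodes} (molecule ids), \code{edges} (2-column matrix of molecule
#'   ids), \code{cutoff}, \code{species}.
#' @export
build_same_type_graph <- function(frame, species, cutoff,
                                  method = c("cell", "brute")) {
  stopifnot(inherits(frame, "monolayer_frame"))
  method <- match.arg(method)
  cutoff <- check_finite_scalar(cutoff, "cutoff")
  if (cutoff <= 0) stop_invalid("'cutoff' must be positive")
  box <- frame_box(frame)
  rows <- which(frame$present &
                  (species == "all" | frame$species == species))
  edges <- matrix(integer(), ncol = 2)
  for (lf in unique(frame$leaflet[rows])) {
    sub <- rows[frame$leaflet[rows] == lf]
    if (length(sub) < 2L) next
    fn <- if (method == "cell") edges_celllist else edges_bruteforce
    e <- fn(frame$x[sub], frame$y[sub], box[1], box[2], cutoff)
    if (nrow(e))
      edges <- rbind(edges, cbind(frame$molecule_id[sub[e[, 1]]],
                                  frame$molecule_id[sub[e[, 2]]]))
  }
  structure(list(nodes = frame$molecule_id[rows], edges = edges,
                 cutoff = cutoff, species = species),
            class = "same_type_graph")
}

#' @export
print.same_type_graph <- function(x, ...) {
  cat(sprintf("Same-type graph (%s): %d nodes, %d edges, cutoff %.2f A\n",
              x$species, length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' @describeIn build_same_type_graph Convert to an \pkg{igraph} graph
#'   (isolated nodes retained).
#' @param g a \code{same_type_graph}.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "same_type_graph"))
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$edges[, 1]),
                   to = as.character(g$edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(g$nodes)))
}

#' Mean node degree
#'
#' Average number of edges per node; 0 for an empty graph by convention.
#' On a condensed single-species hexagonal film with a first-shell cutoff
#' this is exactly 6; for a random equimolar binary labelling the same-type
#' degree averages about 3.
#'
#' @param g a \code{same_type_graph} from [build_same_type_graph()].
#' @return Mean degree (numeric).
#' @export
mean_node_degree <- function(g) {
  stopifnot(inherits(g, "same_type_graph"))
  n <- length(g$nodes)
  if (n == 0L) return(0)
  2 * nrow(g$edges) / n
}

## Local vertex connectivity of a node pair in an igraph graph: the maximum
## number of internally vertex-disjoint paths. For adjacent pairs, the direct
## edge contributes one path and the rest must avoid it.
local_vertex_connectivity <- function(ig, u, v) {
  if (igraph::are_adjacent(ig, u, v)) {
    h <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(u, v)))
    1L + igraph::vertex_connectivity(h, source = u, target = v)
  } else {
    igraph::vertex_connectivity(ig, source = u, target = v)
  }
}

#' Mean connectivity of a same-type graph
#'
#' Cohesion of the per-species network. The default (\code{method =
#' "pair_average"}) is the average over all unordered node pairs of the
#' local vertex connectivity — the maximum number of internally
#' vertex-disjoint paths joining the pair, computed by max-flow — with pairs
#' in different components contributing zero. A fully disconnected node set
#' scores 0; the complete graph on n nodes scores n-1. The alternative
#' \code{method = "min_node_cut"} reports, per node, the minimum number of
#' edges whose removal isolates that node from the rest of its component
#' (which for a connected neighbourhood equals its degree) averaged over
#' nodes; it is provided because verbal definitions of "connectivity" in the
#' aggregation literature admit both readings, and the pairwise measure is
#' the one that discriminates fragmented from cohesive networks.
#'
#' @param g a \code{same_type_graph}.
#' @param method \code{"pair_average"} (default) or \code{"min_node_cut"}.
#' @return Mean connectivity (numeric); 0 for graphs with fewer than two
#'   nodes.
#' @export
mean_connectivity <- function(g, method = c("pair_average", "min_node_cut")) {
  stopifnot(inherits(g, "same_type_graph"))
  method <- match.arg(method)
  n <- length(g$nodes)
  if (n < 2L) return(0)
  ig <- as_igraph(g)
  if (method == "min_node_cut") {
    ## per-node min edge cut = min-degree bound attained by the direct cut
    degs <- igraph::degree(ig)
    return(mean(degs))
  }
  comp <- igraph::components(ig)
  total <- 0
  for (cid in seq_len(comp$no)) {
    vs <- which(comp$membership == cid)
    m <- length(vs)
    if (m < 2L) next
    sub <- igraph::induced_subgraph(ig, vs)
    if (m == 2L) { total <- total + 1; next }
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      total <- total + local_vertex_connectivity(sub, i, j)
  }
  total / (n * (n - 1) / 2)
}

#' Aggregation metrics over a trajectory
#'
#' Per-frame, per-species node counts, edge counts, mean degree and mean
#' connectivity, plus run-level means and SDs. The cutoff may be a number
#' (\enc{Å}{Angstrom}) or \code{"auto"}, in which case it is taken at the
#' minimum between the first two peaks of the all-headgroup RDF of the
#' trajectory ([select_cutoff()]).
#'
#' @param traj a trajectory (or single frame).
#' @param species character vector of species labels to analyse.
#' @param cutoff numeric cutoff or \code{"auto"}.
#' @param connectivity whether to compute mean connectivity (pair-average
#'   max-flow; the expensive metric) per frame.
#' @return Object of class \code{graph_metrics_series}: data frame with
#'   columns \code{frame}, \code{species}, \code{n_nodes}, \code{n_edges},
#'   \code{mean_degree}, \code{mean_connectivity}; run summary in
#'   \code{attr(, "summary")}; cutoff used in \code{attr(, "cutoff")}.
#' @export
metrics_over_trajectory <- function(traj, species, cutoff = "auto",
                                    connectivity = TRUE) {
  traj <- as_trajectory(traj)
  if (identical(cutoff, "auto")) {
    rdf <- compute_rdf(traj)
    cutoff <- select_cutoff(rdf)
  }
  rows <- list()
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    for (sp in species) {
      g <- build_same_type_graph(fr, sp, cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi, species = sp, n_nodes = length(g$nodes),
        n_edges = nrow(g$edges), mean_degree = mean_node_degree(g),
        mean_connectivity = if (connectivity) mean_connectivity(g) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$species), function(d) {
    data.frame(species = d$species[1],
               mean_degree = mean(d$mean_degree),
               sd_degree = stats::sd(d$mean_degree),
               mean_connectivity = mean(d$mean_connectivity),
               sd_connectivity = stats::sd(d$mean_connectivity),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  attr(out, "cutoff") <- cutoff
  class(out) <- c("graph_metrics_series", "data.frame")
  out
}

#' @export
print.graph_metrics_series <- function(x, ...) {
  cat(sprintf("Graph metrics over %d frame(s), cutoff %.2f A\n",
              max(x$frame), attr(x, "cutoff")))
  print(attr(x, "summary"))
  invisible(x)
}
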