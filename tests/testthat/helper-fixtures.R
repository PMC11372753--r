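# Fixtures built in code: frames with hand-placed coordinates, Poisson
# configurations, and a brute-force local-vertex-connectivity oracle.

quaternary_proxy <- function()
  mixture_composition(c("LA", "MA", "PA", "SA"), c(1, 2, 4, 3))

ternary_control <- function()
  mixture_composition(c("MA", "PA", "SA"), c(2, 4, 3))

mixture_pkas_for_test <- function(mix)
  mix$table$pKa[match(mix$species, mix$table$name)]

# Frame with explicit xy positions (single species unless given), upper
# leaflet, box (L, L, 160).
point_frame <- function(x, y, L, species = "LA", z = 120, protonated = TRUE) {
  n <- length(x)
  monolayer_frame(data.frame(
    molecule_id = seq_len(n), species = rep_len(species, n),
    protonated = rep_len(protonated, n), x = x, y = y, z = rep_len(z, n),
    leaflet = "upper", present = TRUE, stringsAsFactors = FALSE),
    c(L, L, 160))
}

poisson_frame <- function(n, L, seed) {
  set.seed(seed)
  point_frame(runif(n, 0, L), runif(n, 0, L), L)
}

# Independent oracle for local vertex connectivity on tiny graphs:
# enumerate separating vertex subsets in increasing size (Menger dual).
# adj: symmetric logical matrix.
oracle_local_connectivity <- function(adj, u, v) {
  n <- nrow(adj)
  connected_without <- function(removed) {
    keep <- setdiff(seq_len(n), removed)
    if (!(u %in% keep) || !(v %in% keep)) return(FALSE)
    seen <- rep(FALSE, n); seen[u] <- TRUE
    frontier <- u
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any))
      nb <- intersect(nb, keep)
      nb <- nb[!seen[nb]]
      if (v %in% nb) return(TRUE)
      seen[nb] <- TRUE
      frontier <- nb
    }
    FALSE
  }
  if (adj[u, v]) {
    adj2 <- adj; adj2[u, v] <- adj2[v, u] <- FALSE
    return(1L + oracle_local_connectivity(adj2, u, v))
  }
  if (!connected_without(integer())) return(0L)
  others <- setdiff(seq_len(n), c(u, v))
  for (k in seq_len(length(others))) {
    subsets <- utils::combn(others, k, simplify = FALSE)
    for (s in subsets) if (!connected_without(s)) return(k)
  }
  length(others) + 1L  # unreachable for simple graphs
}

oracle_mean_connectivity <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + oracle_local_connectivity(adj, i, j)
  tot / (n * (n - 1) / 2)
}

graph_adjacency <- function(g) {
  n <- length(g$nodes)
  adj <- matrix(FALSE, n, n)
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1], g$nodes); j <- match(g$edges[, 2], g$nodes)
    adj[cbind(i, j)] <- TRUE; adj[cbind(j, i)] <- TRUE
  }
  adj
}

edge_key <- function(g) {
  if (!nrow(g$edges)) return(character())
  sort(paste(pmin(g$edges[, 1], g$edges[, 2]),
             pmax(g$edges[, 1], g$edges[, 2])))
}
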