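#' Monolayer frame object
#'
#' A frame is a data frame with one row per molecule (headgroup site) and
#' columns \code{molecule_id}, \code{species}, \code{protonated},
#' \code{x}, \code{y}, \code{z} (\enc{Å}{Angstrom}), \code{leaflet}
#' (\code{"upper"}/\code{"lower"}) and \code{present} (FALSE once the
#' molecule has desorbed from the interface). The box
#' \code{c(Lx, Ly, Lz)} is carried as an attribute; x and y are periodic
#' (wrapped into \code{[0, L)}), z is not.
#'
#' @param df data frame with the columns above.
#' @param box numeric length-3 box vector (\enc{Å}{Angstrom}).
#' @param mma optional mean molecular area used at construction
#'   (\enc{Å}{Angstrom}^2/molecule, metadata).
#' @return An object of class \code{monolayer_frame}.
#' @export
monolayer_frame <- function(df, box, mma = NULL) {
  need <- c("molecule_id", "species", "protonated", "x", "y", "z",
            "leaflet", "present")
  if (!all(need %in% names(df)))
    stop_invalid("frame must have columns: ", paste(need, collapse = ", "))
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop_invalid("'box' must be 3 positive finite lengths")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
    stop_invalid("positions must be finite")
  df$x <- df$x %% box[1]
  df$y <- df$y %% box[2]
  attr(df, "box") <- as.numeric(box)
  attr(df, "mma") <- mma
  class(df) <- c("monolayer_frame", "data.frame")
  df
}

#' @describeIn monolayer_frame Box dimensions of a frame.
#' @param frame a \code{monolayer_frame}.
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @export
print.monolayer_frame <- function(x, ...) {
  box <- frame_box(x)
  cat(sprintf("Monolayer frame: %d molecules (%d present), box %.2f x %.2f x %.2f A\n",
              nrow(x), sum(x$present), box[1], box[2], box[3]))
  tab <- table(x$species[x$present])
  cat("Species:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

## Factor n into rows x cols with even rows (periodic hexagonal embedding),
## as close to square as possible. Returns NULL if impossible.
hex_dims <- function(n) {
  best <- NULL
  for (rows in seq(2L, floor(sqrt(n)) + 1L, by = 2L)) {
    if (n %% rows == 0L) {
      cols <- n %/% rows
      if (is.null(best) || abs(rows - cols) < abs(best[1] - best[2]))
        best <- c(rows, cols)
    }
  }
  ## also consider rows > sqrt(n)
  for (cols in seq_len(floor(sqrt(n)))) {
    if (n %% cols == 0L) {
      rows <- n %/% cols
      if (rows %% 2L == 0L &&
          (is.null(best) || abs(rows - cols) < abs(best[1] - best[2])))
        best <- c(rows, cols)
    }
  }
  best
}

#' Build a periodic hexagonal monolayer
#'
#' Places \code{n} headgroup sites on a hexagonal (triangular) lattice at a
#' given mean molecular area (MMA). The lattice constant is
#' \eqn{a = \sqrt{2\,\mathrm{MMA}/\sqrt{3}}} (4.81 \enc{Å}{A} at
#' 20 \enc{Å}{A}^2/molecule), so that each molecule has exactly six nearest
#' neighbours at distance \eqn{a} under the periodic metric — the packing
#' condensed fatty-acid films adopt. The lattice is embedded in a rectangular
#' periodic cell: rows spaced \eqn{\sqrt{3}a/2} apart, alternate rows offset
#' by \eqn{a/2}, which requires an even number of rows.
#'
#' Species are assigned i.i.d. by mole fraction; protonation flags are drawn
#' per species from [fraction_protonated()] at \code{pH} (set
#' \code{pH = NULL} for all-protonated).
#'
#' @param n number of molecules per leaflet; must factor into rows x cols
#'   with even rows (e.g. 100 = 10 x 10, 1024 = 32 x 32).
#' @param mma mean molecular area, \enc{Å}{Angstrom}^2/molecule.
#' @param composition a [mixture_composition()]; default pure LA.
#' @param seed RNG seed for species/protonation assignment.
#' @param pH subphase pH for protonation sampling, or NULL (fully
#'   protonated).
#' @param assignment \code{"multinomial"} (species i.i.d. by mole fraction)
#'   or \code{"exact"} (largest-remainder integer counts per species, then a
#'   random permutation over sites — exact stoichiometry).
#' @param leaflet \code{"upper"}, \code{"lower"} or \code{"both"} (n per
#'   leaflet).
#' @param lz box height (\enc{Å}{Angstrom}); headgroup planes sit at 0.75 and
#'   0.25 lz for the upper and lower leaflet.
#' @return A [monolayer_frame()].
#' @examples
#' fr <- build_hexagonal_monolayer(100, 20)
#' frame_box(fr)
#' @export
build_hexagonal_monolayer <- function(n, mma,
                                      composition = mixture_composition("LA", 1),
                                      seed = 1L, pH = NULL,
                                      assignment = c("multinomial", "exact"),
                                      leaflet = c("upper", "lower", "both"),
                                      lz = 160) {
  leaflet <- match.arg(leaflet)
  assignment <- match.arg(assignment)
  mma <- check_finite_scalar(mma, "mma")
  if (mma <= 0) stop_invalid("'mma' must be positive")
  n <- as.integer(n)
  if (n < 1L) stop_invalid("'n' must be >= 1")
  a <- sqrt(2 * mma / sqrt(3))
  if (n == 1L) {
    dims <- c(1L, 1L)
    lx <- a; ly <- a
  } else {
    dims <- hex_dims(n)
    if (is.null(dims)) {
      near <- Filter(function(m) !is.null(hex_dims(m)), (n - 5L):(n + 5L))
      stop_invalid("n = ", n, " does not tile a periodic hexagonal lattice; ",
                   "nearby valid n: ", paste(near, collapse = ", "))
    }
    lx <- dims[2] * a
    ly <- dims[1] * a * sqrt(3) / 2
  }
  rows <- dims[1]; cols <- dims[2]
  row_i <- rep(seq_len(rows) - 1L, each = cols)
  col_i <- rep(seq_len(cols) - 1L, times = rows)
  x <- (col_i + ifelse(row_i %% 2L == 1L, 0.5, 0)) * a
  y <- row_i * a * sqrt(3) / 2

  build_leaflet <- function(which, id0) {
    z0 <- if (which == "upper") 0.75 * lz else 0.25 * lz
    sp <- with_seed(seed + ifelse(which == "lower", 1L, 0L), {
      f <- mole_fractions(composition)
      s <- if (assignment == "multinomial") {
        sample(names(f), n, replace = TRUE, prob = f)
      } else {
        ## largest-remainder apportionment, then shuffle over sites
        base <- floor(n * f)
        rem <- n - sum(base)
        if (rem > 0) {
          extra <- order(n * f - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1L
        }
        sample(rep(names(f), times = base))
      }
      prot <- rep(TRUE, n)
      if (!is.null(pH)) {
        fp <- fraction_protonated(mixture_pkas(composition), pH)
        names(fp) <- composition$species
        prot <- stats::runif(n) < fp[s]
      }
      list(s = s, prot = prot)
    })
    data.frame(molecule_id = id0 + seq_len(n), species = sp$s,
               protonated = sp$prot, x = x, y = y, z = z0,
               leaflet = which, present = TRUE, stringsAsFactors = FALSE)
  }
  df <- switch(leaflet,
    upper = build_leaflet("upper", 0L),
    lower = build_leaflet("lower", 0L),
    both = rbind(build_leaflet("upper", 0L), build_leaflet("lower", n)))
  monolayer_frame(df, c(lx, ly, lz), mma = mma)
}

## Neighbor list (list of integer vectors) of all present molecules of a
## leaflet within cutoff, periodic xy metric. Used by demixing and tests.
lattice_neighbors <- function(frame, cutoff) {
  box <- frame_box(frame)
  idx <- which(frame$present)
  nb <- vector("list", nrow(frame))
  for (lf in unique(frame$leaflet[idx])) {
    sub <- idx[frame$leaflet[idx] == lf]
    if (length(sub) < 2L) next
    xy <- cbind(frame$x[sub], frame$y[sub])
    d <- pairwise_xy_dist(xy, xy, box[1], box[2])
    diag(d) <- Inf
    hits <- which(d <= cutoff, arr.ind = TRUE)
    for (i in seq_along(sub)) nb[[sub[i]]] <- sub[hits[hits[, 1] == i, 2]]
  }
  nb
}

#' Demix species labels by Metropolis label swaps
#'
#' Drives a frame toward lateral phase separation by label-swap Metropolis
#' Monte Carlo: the energy is \eqn{-J} per same-species nearest-neighbour
#' pair, and a move exchanges the (species, protonation) labels of two
#' randomly chosen molecules. Species counts are conserved exactly. With
#' \code{J = 0} every labelling is equally likely (ideal mixing); large
#' \code{J} (around 1.5 and above, in kT units) produces connected
#' same-species domains like the aggregates long-chain acids form under
#' compression.
#'
#' @param frame a [monolayer_frame()].
#' @param J same-type nearest-neighbour affinity, kT units, >= 0.
#' @param n_sweeps number of Monte Carlo sweeps (one sweep = one attempted
#'   swap per molecule).
#' @param seed RNG seed.
#' @param cutoff neighbour cutoff (\enc{Å}{Angstrom}); default the first
#'   coordination shell of the construction lattice (1.2 x lattice
#'   constant).
#' @return The frame with relabelled species/protonation columns.
#' @export
demix_labels <- function(frame, J, n_sweeps, seed = 1L, cutoff = NULL) {
  stopifnot(inherits(frame, "monolayer_frame"))
  J <- check_finite_scalar(J, "J")
  if (J < 0) stop_invalid("'J' must be >= 0")
  if (n_sweeps < 0) stop_invalid("'n_sweeps' must be >= 0")
  if (n_sweeps == 0) return(frame)
  if (is.null(cutoff)) {
    mma <- attr(frame, "mma")
    if (is.null(mma)) stop_invalid("no 'mma' metadata; supply 'cutoff'")
    cutoff <- 1.2 * sqrt(2 * mma / sqrt(3))
  }
  nb <- lattice_neighbors(frame, cutoff)
  idx <- which(frame$present)
  if (length(idx) < 2L) return(frame)
  ## pack neighbors into 0-based flat arrays for the C++ kernel
  deg <- lengths(nb[idx])
  pos <- match(seq_len(nrow(frame)), idx)   # frame row -> packed index (NA if absent)
  flat <- unlist(lapply(nb[idx], function(v) pos[v] - 1L), use.names = FALSE)
  offs <- c(0L, cumsum(deg))
  lab <- as.integer(factor(frame$species[idx]))
  n_attempts <- as.numeric(n_sweeps) * length(idx)
  new_lab <- with_seed(seed,
    demix_mc(lab - 1L, flat, offs, J, n_attempts))
  ## carry protonation flags with the species labels: permute within species
  ## is unnecessary — swaps exchange full (species, protonated) label pairs,
  ## so reassign protonation by matching multiset per species
  old_lab <- lab - 1L
  prot <- frame$protonated[idx]
  new_prot <- prot
  for (s in unique(new_lab)) {
    new_prot[new_lab == s] <- prot[old_lab == s]
  }
  frame$species[idx] <- levels(factor(frame$species[idx]))[new_lab + 1L]
  frame$protonated[idx] <- new_prot
  frame
}

#' Apply vertical headgroup staggering
#'
#' Offsets each molecule's z by a (species, protonation)-dependent amount
#' plus Gaussian jitter, emulating the chain-length- and charge-dependent
#' vertical staggering of carboxyl C1 carbons: deprotonated headgroups sink
#' toward the water, shorter chains ride higher. Offsets are measured from
#' the leaflet reference plane; positive offsets point away from the water
#' on either leaflet (so a negative offset means "more hydrated" on both).
#'
#' @param frame a [monolayer_frame()].
#' @param z_offsets data frame with columns \code{species},
#'   \code{protonated} (logical) and \code{offset}
#'   (\enc{Å}{Angstrom}); every (species, protonation) pair present in the
#'   frame must appear.
#' @param jitter_sd Gaussian jitter SD (\enc{Å}{Angstrom}).
#' @param seed RNG seed.
#' @return The frame with updated z (x, y untouched).
#' @export
apply_staggering <- function(frame, z_offsets, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(frame, "monolayer_frame"))
  need <- c("species", "protonated", "offset")
  if (!all(need %in% names(z_offsets)))
    stop_invalid("'z_offsets' needs columns: ", paste(need, collapse = ", "))
  key <- paste(frame$species, frame$protonated)
  tabkey <- paste(z_offsets$species, z_offsets$protonated)
  hit <- match(key, tabkey)
  if (anyNA(hit[frame$present]))
    stop("no offset for group(s): ",
         paste(unique(key[frame$present][is.na(hit[frame$present])]),
               collapse = ", "), call. = FALSE)
  off <- z_offsets$offset[hit]
  off[is.na(off)] <- 0
  sgn <- ifelse(frame$leaflet == "upper", 1, -1)   # +offset = away from water
  lz <- frame_box(frame)[3]
  ref <- ifelse(frame$leaflet == "upper", 0.75 * lz, 0.25 * lz)
  noise <- if (jitter_sd > 0)
    with_seed(seed, stats::rnorm(nrow(frame), 0, jitter_sd)) else 0
  frame$z <- ref + sgn * off + noise
  frame
}

#' Desorb molecules from the interface
#'
#' Marks a random fraction of molecules (optionally of one species) as no
#' longer present, emulating expulsion of soluble acids from a compressed
#' film. Desorbed molecules keep their row (identity is preserved across
#' frames); all analyses skip them.
#'
#' @param frame a [monolayer_frame()].
#' @param fraction fraction in \[0, 1\] of the targeted molecules to remove.
#' @param species species label, or \code{"all"}.
#' @param seed RNG seed.
#' @return The frame with updated \code{present} flags.
#' @export
desorb <- function(frame, fraction, species = "all", seed = 1L) {
  stopifnot(inherits(frame, "monolayer_frame"))
  fraction <- check_finite_scalar(fraction, "fraction")
  if (fraction < 0 || fraction > 1) stop_invalid("'fraction' must be in [0, 1]")
  pool <- which(frame$present)
  if (!identical(species, "all")) {
    if (!species %in% frame$species)
      stop_invalid("unknown species '", species, "'")
    pool <- pool[frame$species[pool] == species]
  }
  k <- floor(fraction * length(pool))
  if (k > 0) {
    gone <- with_seed(seed, sample(pool, k))
    frame$present[gone] <- FALSE
  }
  frame
}

#' Build a synthetic trajectory
#'
#' Replicates a frame \code{n_frames} times with independent Gaussian xy
#' jitter per frame (periodic wrap), keeping identity, labels and box
#' constant. Frame 1 is the input frame unchanged.
#'
#' @param frame a [monolayer_frame()].
#' @param n_frames number of frames (>= 1).
#' @param xy_jitter_sd per-frame positional jitter SD (\enc{Å}{Angstrom});
#'   0 gives a static trajectory.
#' @param z_jitter_sd per-frame vertical jitter SD.
#' @param seed RNG seed.
#' @param dt_ps frame interval metadata (picoseconds).
#' @return An object of class \code{monolayer_trajectory}: list with
#'   \code{frames} (list of frames) and \code{dt_ps}.
#' @export
make_trajectory <- function(frame, n_frames, xy_jitter_sd = 0,
                            z_jitter_sd = 0, seed = 1L, dt_ps = 1000) {
  stopifnot(inherits(frame, "monolayer_frame"))
  n_frames <- as.integer(n_frames)
  if (n_frames <= 0L) stop_invalid("'n_frames' must be positive")
  box <- frame_box(frame)
  frames <- vector("list", n_frames)
  frames[[1]] <- frame
  if (n_frames > 1L) {
    n <- nrow(frame)
    jit <- with_seed(seed,
      list(x = matrix(stats::rnorm((n_frames - 1L) * n, 0, xy_jitter_sd), ncol = n),
           y = matrix(stats::rnorm((n_frames - 1L) * n, 0, xy_jitter_sd), ncol = n),
           z = matrix(stats::rnorm((n_frames - 1L) * n, 0, z_jitter_sd), ncol = n)))
    for (i in 2:n_frames) {
      f <- frame
      if (xy_jitter_sd > 0) {
        f$x <- (f$x + jit$x[i - 1L, ]) %% box[1]
        f$y <- (f$y + jit$y[i - 1L, ]) %% box[2]
      }
      if (z_jitter_sd > 0) f$z <- f$z + jit$z[i - 1L, ]
      frames[[i]] <- f
    }
  }
  structure(list(frames = frames, dt_ps = dt_ps),
            class = "monolayer_trajectory")
}

#' @export
print.monolayer_trajectory <- function(x, ...) {
  cat(sprintf("Monolayer trajectory: %d frames, %d molecules, dt = %g ps\n",
              length(x$frames), nrow(x$frames[[1]]), x$dt_ps))
  invisible(x)
}

#' @describeIn make_trajectory Coerce a single frame to a one-frame
#'   trajectory (frames pass through unchanged).
#' @param x a frame or trajectory.
#' @export
as_trajectory <- function(x) {
  if (inherits(x, "monolayer_trajectory")) return(x)
  if (inherits(x, "monolayer_frame"))
    return(structure(list(frames = list(x), dt_ps = NA_real_),
                     class = "monolayer_trajectory"))
  stop_invalid("cannot coerce to trajectory")
}
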