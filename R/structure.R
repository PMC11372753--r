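## Interface structure: vertical headgroup staggering, z-density profiles,
## geometric hydrogen-bond counting.

## Signed vertical deviation of each present molecule from its leaflet's
## mean headgroup height in one frame. Negative = toward the aqueous side:
## for the upper leaflet water lies below (smaller z), for the lower leaflet
## above, so the sign is flipped there.
frame_deviations <- function(fr) {
  dev <- rep(NA_real_, nrow(fr))
  for (lf in unique(fr$leaflet)) {
    sel <- fr$present & fr$leaflet == lf
    if (!any(sel)) next
    mu <- mean(fr$z[sel])
    d <- fr$z[sel] - mu
    if (lf == "lower") d <- -d
    dev[sel] <- d
  }
  dev
}

#' Vertical headgroup deviations by species and protonation
#'
#' Pools, over all frames, the deviation of each headgroup's z from the
#' per-leaflet, per-frame mean headgroup height, grouped by species and
#' protonation state. Negative deviations point toward the aqueous phase
#' (more hydrated); in staggered mixed films deprotonated headgroups and
#' longer chains sit on the hydrated side. The per-frame reference removes
#' any global drift.
#'
#' @param traj a trajectory or single frame.
#' @param bin_width histogram bin width (\enc{Å}{Angstrom}).
#' @return Object of class \code{deviation_profiles}: list with
#'   \code{stats} (data frame: species, protonated, n, mean, sd, se) and
#'   \code{histograms} (named list of data frames with \code{z} bin centers
#'   and probability \code{density}).
#' @export
vertical_deviations <- function(traj, bin_width = 0.25) {
  traj <- as_trajectory(traj)
  devs <- list(); keys <- list()
  for (fr in traj$frames) {
    d <- frame_deviations(fr)
    ok <- !is.na(d)
    devs[[length(devs) + 1L]] <- d[ok]
    keys[[length(keys) + 1L]] <-
      paste(fr$species[ok], ifelse(fr$protonated[ok], "prot", "deprot"))
  }
  dev <- unlist(devs); key <- unlist(keys)
  groups <- split(dev, key)
  stats_df <- do.call(rbind, lapply(names(groups), function(k) {
    v <- groups[[k]]
    parts <- strsplit(k, " ")[[1]]
    data.frame(species = parts[1], protonated = parts[2] == "prot",
               n = length(v), mean = mean(v), sd = stats::sd(v),
               se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  hists <- lapply(groups, function(v) {
    rng <- range(v)
    if (diff(rng) < bin_width) rng <- rng + c(-1, 1) * bin_width
    breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                  ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(z = h$mids, density = h$density)
  })
  structure(list(stats = stats_df, histograms = hists),
            class = "deviation_profiles")
}

#' @export
print.deviation_profiles <- function(x, ...) {
  cat("Vertical headgroup deviations (Å, negative = more hydrated):\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Vertical density profile
#'
#' Frame-averaged histogram of headgroup z positions, per leaflet. The
#' profile integrates (sums counts x bin width / bin width) to the mean
#' number of selected molecules, so species can be compared by where their
#' headgroups sit in the interfacial region.
#'
#' @param traj a trajectory or single frame.
#' @param species species label or \code{"all"}.
#' @param bin_width bin width (\enc{Å}{Angstrom}).
#' @return Data frame of class \code{density_profile} with columns
#'   \code{leaflet}, \code{z} (bin centers), \code{count} (mean molecules
#'   per bin per frame).
#' @export
density_profile <- function(traj, species = "all", bin_width = 0.5) {
  traj <- as_trajectory(traj)
  if (bin_width <= 0) stop_invalid("'bin_width' must be positive")
  lz <- frame_box(traj$frames[[1]])[3]
  breaks <- seq(0, max(lz, bin_width * ceiling(lz / bin_width)),
                by = bin_width)
  nfr <- length(traj$frames)
  out <- list()
  for (lf in c("upper", "lower")) {
    counts <- numeric(length(breaks) - 1L)
    for (fr in traj$frames) {
      sel <- fr$present & fr$leaflet == lf &
        (species == "all" | fr$species == species)
      if (!any(sel)) next
      z <- pmin(pmax(fr$z[sel], 0), max(breaks) - 1e-9)
      counts <- counts + tabulate(findInterval(z, breaks,
                                               rightmost.closed = TRUE),
                                  length(counts))
    }
    if (sum(counts) > 0)
      out[[lf]] <- data.frame(leaflet = lf,
                              z = (breaks[-1] + breaks[-length(breaks)]) / 2,
                              count = counts / nfr, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(leaflet = character(), z = numeric(), count = numeric())
  rownames(res) <- NULL
  class(res) <- c("density_profile", "data.frame")
  res
}

#' Hydrogen-bond criterion
#'
#' Geometric criterion: a donor-H...acceptor triple is a hydrogen bond when
#' the donor-acceptor distance is at most \code{max_da_dist} and the
#' donor-H-acceptor angle is at least \code{min_dha_angle}. The 3.5
#' \enc{Å}{Angstrom} / 150 degree default is a common choice for carboxylic
#' headgroups and water; both parameters are free.
#'
#' @param max_da_dist maximum donor-acceptor distance, (0, 5]
#'   \enc{Å}{Angstrom}.
#' @param min_dha_angle minimum donor-H-acceptor angle, \[90, 180\] degrees.
#' @return A list of class \code{hbond_criterion}.
#' @export
hbond_criterion <- function(max_da_dist = 3.5, min_dha_angle = 150) {
  if (max_da_dist <= 0 || max_da_dist > 5)
    stop_invalid("'max_da_dist' must be in (0, 5] Å")
  if (min_dha_angle < 90 || min_dha_angle > 180)
    stop_invalid("'min_dha_angle' must be in [90, 180] degrees")
  structure(list(max_da_dist = max_da_dist, min_dha_angle = min_dha_angle),
            class = "hbond_criterion")
}

#' Count hydrogen bonds from explicit donor/H/acceptor triples
#'
#' Applies a geometric criterion to a table of candidate triples and tallies
#' accepted bonds per interaction class (same-species head-head,
#' cross-species head-head, head-water, ...). The angle is measured at the
#' hydrogen, between the H->donor and H->acceptor directions (180 degrees =
#' linear bond).
#'
#' @param triples data frame with coordinate columns \code{dx,dy,dz}
#'   (donor), \code{hx,hy,hz} (hydrogen), \code{ax,ay,az} (acceptor) in
#'   \enc{Å}{Angstrom}, and a \code{class} column labelling the pair type.
#' @param criterion an [hbond_criterion()].
#' @return Data frame of class \code{hbond_counts} with columns
#'   \code{class}, \code{n_candidates}, \code{n_bonds}; per-triple verdicts
#'   in \code{attr(, "bonded")}.
#' @export
count_hbonds <- function(triples, criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  need <- c("dx", "dy", "dz", "hx", "hy", "hz", "ax", "ay", "az", "class")
  if (!all(need %in% names(triples)))
    stop("'triples' must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  co <- as.matrix(triples[, setdiff(need, "class")])
  if (any(!is.finite(co))) stop("non-finite coordinates in triples", call. = FALSE)
  da <- sqrt((triples$dx - triples$ax)^2 + (triples$dy - triples$ay)^2 +
               (triples$dz - triples$az)^2)
  hd <- cbind(triples$dx - triples$hx, triples$dy - triples$hy,
              triples$dz - triples$hz)
  ha <- cbind(triples$ax - triples$hx, triples$ay - triples$hy,
              triples$az - triples$hz)
  nhd <- sqrt(rowSums(hd^2)); nha <- sqrt(rowSums(ha^2))
  if (any(nhd == 0) || any(nha == 0))
    stop("degenerate triple: hydrogen coincides with donor or acceptor",
         call. = FALSE)
  cosang <- pmin(1, pmax(-1, rowSums(hd * ha) / (nhd * nha)))
  ang <- acos(cosang) * 180 / pi
  bonded <- da <= criterion$max_da_dist & ang >= criterion$min_dha_angle
  out <- do.call(rbind, lapply(split(seq_len(nrow(triples)), triples$class),
                               function(i) data.frame(
    class = triples$class[i[1]], n_candidates = length(i),
    n_bonds = sum(bonded[i]), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "bonded") <- bonded
  class(out) <- c("hbond_counts", "data.frame")
  out
}
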