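## Umbrella sampling -> PMF reconstruction via the weighted histogram
## analysis method, plus an overdamped Langevin sampler used to generate
## synthetic windows. Internal energy unit is kT at 298.15 K; disk formats
## use GROMACS conventions (kJ/mol, nm).

#' Thermal energy at 298.15 K in kJ/mol
#' @return 2.47896 (kJ/mol).
#' @export
kT_kJ_mol <- function() 8.314462618e-3 * 298.15

#' Umbrella window
#'
#' Samples of a 1D reaction coordinate collected under a harmonic bias
#' \eqn{U(x) = k (x - x_0)^2 / 2}.
#'
#' @param center bias center \eqn{x_0} (\enc{Å}{Angstrom}).
#' @param k force constant; units per \code{k_units}. Stored internally in
#'   kT/\enc{Å}{Angstrom}^2 at 298.15 K.
#' @param samples numeric vector of coordinate samples
#'   (\enc{Å}{Angstrom}), finite, length >= 1.
#' @param k_units \code{"kT_A2"} (internal) or \code{"kJ_mol_nm2"}
#'   (GROMACS disk convention; 1 kJ/mol/nm^2 = (1/kT)/100 kT/\enc{Å}{A}^2).
#' @return Object of class \code{umbrella_window}.
#' @export
umbrella_window <- function(center, k, samples,
                            k_units = c("kT_A2", "kJ_mol_nm2")) {
  k_units <- match.arg(k_units)
  center <- check_finite_scalar(center, "center")
  k <- check_finite_scalar(k, "k")
  if (k < 0) stop_invalid("'k' must be >= 0")
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop_invalid("'samples' must be non-empty and finite")
  if (k_units == "kJ_mol_nm2") k <- k / kT_kJ_mol() / 100
  structure(list(center = center, k = k, samples = as.numeric(samples),
                 n = length(samples)),
            class = "umbrella_window")
}

#' Analytic test potentials for the Langevin sampler
#'
#' \code{"flat"}: V = 0. \code{"harmonic"}: \eqn{V = \kappa x^2/2}.
#' \code{"double_well"}: \eqn{V = a (x^2 - b^2)^2}, minima at \eqn{\pm b}
#' and a barrier of height \eqn{a b^4} (kT) at x = 0.
#'
#' @param name one of \code{"flat"}, \code{"harmonic"},
#'   \code{"double_well"}.
#' @param kappa harmonic stiffness (kT/\enc{Å}{Angstrom}^2).
#' @param a,b double-well parameters.
#' @return List with elements \code{V}, \code{dV} (functions of x, kT
#'   units) and \code{name}.
#' @export
make_potential <- function(name = c("flat", "harmonic", "double_well"),
                           kappa = 1, a = 1, b = 1.5) {
  name <- match.arg(name)
  switch(name,
    flat = list(V = function(x) 0 * x, dV = function(x) 0 * x, name = name),
    harmonic = list(V = function(x) 0.5 * kappa * x^2,
                    dV = function(x) kappa * x, name = name),
    double_well = list(V = function(x) a * (x^2 - b^2)^2,
                       dV = function(x) 4 * a * x * (x^2 - b^2),
                       name = name))
}

#' Generate umbrella windows with overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of \eqn{\gamma \dot x = -V'(x) - k(x - x_0) +
#' \sqrt{2\gamma k_BT}\,\xi(t)} (kT = 1 internally), one independent
#' trajectory per bias center. The first \code{burn_in} fraction of steps is
#' discarded. A stand-in for biased MD when validating the PMF
#' reconstruction: the stationary distribution of each window is known
#' exactly, so WHAM output can be checked against closed forms.
#'
#' @param potential a list from [make_potential()], or a function V(x)
#'   (gradient taken by central difference).
#' @param centers numeric vector of bias centers (\enc{Å}{Angstrom}).
#' @param k force constant(s), kT/\enc{Å}{Angstrom}^2 (recycled).
#' @param n_steps integration steps per window.
#' @param dt time step; must satisfy \code{dt * max(k + stiffness) /
#'   friction < 0.1} for stability.
#' @param friction friction coefficient \eqn{\gamma}.
#' @param seed RNG seed.
#' @param burn_in fraction of initial steps discarded.
#' @param x0 optional start positions (default: the centers).
#' @return List of [umbrella_window()] objects.
#' @export
langevin_windows <- function(potential, centers, k, n_steps = 20000,
                             dt = 0.01, friction = 1, seed = 1L,
                             burn_in = 0.1, x0 = NULL) {
  if (is.function(potential)) {
    V <- potential
    dV <- function(x) (V(x + 1e-5) - V(x - 1e-5)) / 2e-5
  } else {
    V <- potential$V; dV <- potential$dV
  }
  nw <- length(centers)
  if (nw < 1L) stop_invalid("need at least one window center")
  k <- rep_len(k, nw)
  if (any(k < 0)) stop_invalid("force constants must be >= 0")
  if (dt * max(k) / friction >= 0.1)
    stop_invalid("unstable integration: require dt * k / friction < 0.1 ",
                 "for the stiffest bias")
  n_steps <- as.integer(n_steps)
  if (n_steps < 10L) stop_invalid("'n_steps' must be >= 10")
  x <- if (is.null(x0)) as.numeric(centers) else rep_len(x0, nw)
  keep_from <- max(1L, ceiling(burn_in * n_steps)) + 1L
  out <- matrix(NA_real_, nrow = n_steps, ncol = nw)
  sqcoef <- sqrt(2 * dt / friction)
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      force_tot <- -dV(x) - k * (x - centers)
      x <- x + dt * force_tot / friction + sqcoef * stats::rnorm(nw)
      if (any(!is.finite(x)) || any(abs(x) > 1e6))
        stop("Langevin integration diverged; reduce dt or increase friction",
             call. = FALSE)
      out[s, ] <- x
    }
  })
  lapply(seq_len(nw), function(i)
    umbrella_window(centers[i], k[i], out[keep_from:n_steps, i]))
}

#' Weighted histogram analysis method
#'
#' Self-consistent unbiasing of overlapping umbrella windows into a single
#' free-energy profile. Window samples are histogrammed on a common grid and
#' the standard WHAM fixed-point equations are iterated in the log domain
#' (log-sum-exp accumulation, so force constants up to the hundreds of
#' kJ/mol/nm^2 used in practice cannot underflow):
#' \deqn{P(x_b) \propto \frac{\sum_i h_i(x_b)}{\sum_i n_i
#'   e^{-\beta(U_i(x_b) - f_i)}}, \qquad
#'   e^{-\beta f_i} = \sum_b P(x_b) e^{-\beta U_i(x_b)}.}
#' Iteration starts from \eqn{f_i = 0} with plain (Jacobi) updates and stops
#' when \eqn{\max_i |\Delta f_i|} falls below \code{tol}. The free energy is
#' \eqn{G = -k_BT \ln P}, shifted so its minimum over defined bins is zero;
#' bins with no counts anywhere are left NA (never interpolated).
#'
#' @param windows list of [umbrella_window()] objects.
#' @param grid \code{c(xmin, xmax, n_bins)}.
#' @param kT thermal energy unit for the output scale (1 = report G in kT).
#' @param tol convergence tolerance on the window free-energy shifts (kT).
#' @param max_iter iteration cap.
#' @return Object of class \code{pmf_profile}: data frame with columns
#'   \code{x} (bin centers) and \code{G} (kT), with attributes \code{f}
#'   (window shifts), \code{iterations}, \code{residual}, \code{converged},
#'   \code{P} (normalized probability), \code{kT}.
#' @export
wham <- function(windows, grid, kT = 1, tol = 1e-6, max_iter = 1e5) {
  if (!length(windows)) stop_invalid("no windows supplied")
  stopifnot(all(vapply(windows, inherits, TRUE, "umbrella_window")))
  if (length(grid) != 3L || grid[2] <= grid[1] || grid[3] < 2)
    stop_invalid("'grid' must be c(xmin, xmax, n_bins) with xmax > xmin")
  if (tol <= 0) stop_invalid("'tol' must be positive")
  xmin <- grid[1]; xmax <- grid[2]; nbins <- as.integer(grid[3])
  breaks <- seq(xmin, xmax, length.out = nbins + 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nw <- length(windows)
  H <- matrix(0, nrow = nw, ncol = nbins)       # counts per window per bin
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    s <- s[s >= xmin & s <= xmax]
    if (length(s))
      H[i, ] <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE),
                         nbins)
  }
  n_i <- vapply(windows, function(w) w$n, 0)
  total <- colSums(H)
  defined <- total > 0
  if (!any(defined)) stop_invalid("no samples fall inside the grid")
  ## bias energies in kT: U[i, b]
  U <- t(vapply(windows, function(w) 0.5 * w$k * (centers - w$center)^2,
                numeric(nbins)))
  if (nw > 1L) {
    occ <- H > 0
    no_overlap <- vapply(seq_len(nw), function(i)
      sum(occ[i, ] & colSums(occ[-i, , drop = FALSE]) > 0) == 0L, TRUE)
    if (any(no_overlap))
      warning("window(s) with no histogram overlap with any other window: ",
              paste(which(no_overlap), collapse = ", "),
              "; their relative free energies are poorly determined",
              call. = FALSE)
  }
  log_n <- log(n_i)
  log_tot <- ifelse(defined, log(total), -Inf)
  f <- numeric(nw)                              # beta * f_i
  iter <- 0L; resid <- Inf
  resid_hist <- numeric()
  repeat {
    iter <- iter + 1L
    ## log P_b (unnormalized)
    denom <- logsumexp_cols(log_n + f - U)      # over windows, per bin
    logP <- log_tot - denom
    logP[!defined] <- -Inf
    logP <- logP - logsumexp(logP)
    f_new <- -vapply(seq_len(nw), function(i) logsumexp(logP - U[i, ]), 0)
    resid <- max(abs(f_new - f))
    resid_hist[iter] <- resid
    f <- f_new
    if (resid < tol || iter >= max_iter) break
  }
  converged <- resid < tol
  if (!converged) {
    ## overlap diagnostics: windows whose histograms share no bins with any
    ## neighbour cannot be tied together
    occ <- H > 0
    overlap <- vapply(seq_len(nw), function(i)
      sum(occ[i, ] & colSums(occ[-i, , drop = FALSE]) > 0), 0L)
    warning("WHAM did not converge (residual ", signif(resid, 3), " kT after ",
            iter, " iterations); windows with no histogram overlap: ",
            paste(which(overlap == 0L), collapse = ", "), call. = FALSE)
  }
  denom <- logsumexp_cols(log_n + f - U)
  logP <- log_tot - denom
  logP[!defined] <- -Inf
  logP <- logP - logsumexp(logP)
  G <- ifelse(defined, -kT * logP, NA_real_)
  G <- G - min(G, na.rm = TRUE)
  out <- data.frame(x = centers, G = G)
  attr(out, "f") <- f * kT
  attr(out, "iterations") <- iter
  attr(out, "residual") <- resid
  attr(out, "residual_history") <- resid_hist
  attr(out, "converged") <- converged
  attr(out, "P") <- exp(logP)
  attr(out, "kT") <- kT
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Free-energy difference between two regions of a PMF
#'
#' \eqn{\Delta G = S_b - S_a} where \eqn{S} is a summary (mean or minimum)
#' of G over the bins falling in each coordinate region. Positive values
#' mean region b lies uphill of region a.
#'
#' @param pmf a \code{pmf_profile} from [wham()].
#' @param region_a,region_b numeric length-2 ranges (\enc{Å}{Angstrom}).
#' @param statistic \code{"mean"} (default) or \code{"min"} over each
#'   region's defined bins.
#' @return Named vector with the difference in kT and kJ/mol.
#' @export
delta_g <- function(pmf, region_a, region_b,
                    statistic = c("mean", "min")) {
  stopifnot(inherits(pmf, "pmf_profile"))
  statistic <- match.arg(statistic)
  pick <- function(region) {
    v <- pmf$G[pmf$x >= region[1] & pmf$x <= region[2]]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("region [", region[1], ", ", region[2],
           "] contains no defined PMF bins", call. = FALSE)
    if (statistic == "mean") mean(v) else min(v)
  }
  d_kt <- pick(region_b) - pick(region_a)
  c(kT = d_kt, kJ_mol = d_kt * kT_kJ_mol() / attr(pmf, "kT"))
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$x, x$G, type = "l", xlab = "x (Å)", ylab = "G (kT)",
                 main = "Potential of mean force", ...)
  invisible(x)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins on [%.2f, %.2f] Å, %d defined; %s after %d iterations (residual %.2e)\n",
              nrow(x), min(x$x), max(x$x), sum(!is.na(x$G)),
              if (attr(x, "converged")) "converged" else "NOT converged",
              attr(x, "iterations"), attr(x, "residual")))
  invisible(x)
}

#' Read and write umbrella-window files
#'
#' One plain-text file per window: header lines \code{#center <Å>} and
#' \code{#k <kJ/mol/nm^2>} followed by one sample (\enc{Å}{Angstrom}) per
#' line. A manifest TSV with a \code{file} column lists the windows of a
#' run; relative paths resolve against the manifest's directory.
#'
#' @param window an [umbrella_window()] (for writing).
#' @param path file path.
#' @return \code{read_umbrella_window}: an \code{umbrella_window};
#'   \code{write_umbrella_window}: the path, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#center %.10g", window$center),
               sprintf("#k %.10g", window$k * kT_kJ_mol() * 100),
               sprintf("%.10g", window$samples)), con)
  invisible(path)
}

#' @rdname write_umbrella_window
#' @export
read_umbrella_window <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) stop("window file missing '#", key, "' header: ", path,
                         call. = FALSE)
    as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][2])
  }
  samples <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  umbrella_window(getv("center"), getv("k"), samples, k_units = "kJ_mol_nm2")
}

#' @rdname write_umbrella_window
#' @param windows list of windows (for \code{write_window_manifest}).
#' @param dir output directory for the per-window files.
#' @export
write_window_manifest <- function(windows, dir, path = file.path(dir, "manifest.tsv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("window_%03d.dat", seq_along(windows))
  for (i in seq_along(windows))
    write_umbrella_window(windows[[i]], file.path(dir, files[i]))
  utils::write.table(data.frame(file = files), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_umbrella_window
#' @export
read_window_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"file" %in% names(tab))
    stop("manifest must have a 'file' column", call. = FALSE)
  base <- dirname(path)
  lapply(tab$file, function(f) {
    p <- if (file.exists(f)) f else file.path(base, f)
    read_umbrella_window(p)
  })
}
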