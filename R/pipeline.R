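## End-to-end demo pipeline: protonation tables -> synthetic monolayer ->
## RDF/cutoff -> graph metrics -> structure -> synthetic umbrella windows ->
## WHAM, with TSV/JSON outputs. Driven by a versioned YAML config.

pipeline_schema <- list(
  top = c("version", "seed", "output_dir", "protonation", "synth",
          "network", "structure", "wham"),
  protonation = c("ph_values", "composition", "totals", "policy"),
  synth = c("n_molecules", "mma", "composition", "ph", "demix_J", "demix_sweeps",
            "stagger_offsets", "desorb_fraction", "desorb_species",
            "n_frames", "xy_jitter_sd", "z_jitter_sd"),
  network = c("species", "cutoff", "rdf_r_max", "rdf_bin_width",
              "connectivity"),
  structure = c("deviation_bin_width", "density_bin_width"),
  wham = c("potential", "kappa", "a", "b", "centers", "k", "n_steps",
           "dt", "friction", "grid", "tol"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

#' Read and validate a pipeline configuration
#'
#' YAML with a versioned schema; unknown keys are rejected so typos fail
#' fast. See the packaged demo at
#' \code{system.file("extdata", "demo_config.yaml", package = "monomix")}.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  check_keys(cfg, pipeline_schema$top, "top level")
  if (is.null(cfg$version) || cfg$version != 1)
    stop("config 'version' must be 1", call. = FALSE)
  if (is.null(cfg$seed)) stop("config must set 'seed'", call. = FALSE)
  for (blk in c("protonation", "synth", "network", "structure", "wham"))
    if (!is.null(cfg[[blk]]))
      check_keys(cfg[[blk]], pipeline_schema[[blk]], blk)
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — protonation tables, synthetic
#' monolayer generation (with optional demixing, staggering, desorption),
#' RDF and cutoff selection, per-species graph metrics, vertical-deviation
#' and density profiles, synthetic umbrella windows and WHAM — writing TSV
#' outputs, a machine-readable JSON summary, and a run log (seeds and
#' parameters included) under \code{output_dir}.
#'
#' @param config path to a YAML config or a config list
#'   (see [read_run_config()]).
#' @param output_dir overrides the config's output directory if given.
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% "monomix_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  logmsg("monomix ", as.character(utils::packageVersion("monomix")),
         " pipeline; seed = ", cfg$seed)
  seed <- as.integer(cfg$seed)
  results <- list(config = cfg)
  summary <- list(seed = seed,
                  package_version = as.character(utils::packageVersion("monomix")))

  ## --- protonation tables ---
  if (!is.null(cfg$protonation)) {
    pc <- cfg$protonation
    mix <- parse_composition(pc$composition)
    totals <- if (!is.null(pc$totals)) unlist(pc$totals)
    prot <- list()
    for (ph in pc$ph_values) {
      rep_ <- protonation_report(mix, ph, totals = totals,
                                 policy = pc$policy %||% "nearest")
      write_tsv(rep_$table, file.path(out_dir, sprintf("protonation_pH%s.tsv", ph)))
      prot[[as.character(ph)]] <- list(
        percent_protonated = rep_$percent_protonated,
        table = rep_$table)
      logmsg(sprintf("protonation pH %s: %.1f%% protonated", ph,
                     rep_$percent_protonated))
    }
    results$protonation <- prot
    summary$protonation <- lapply(prot, function(p)
      list(percent_protonated = p$percent_protonated))
  }

  ## --- synthetic monolayer ---
  sc <- cfg$synth %||% stop("config must include a 'synth' block", call. = FALSE)
  mix_s <- parse_composition(sc$composition)
  frame <- build_hexagonal_monolayer(sc$n_molecules, sc$mma, mix_s, seed = seed,
                                     pH = sc$ph)
  if (!is.null(sc$demix_J) && sc$demix_J > 0)
    frame <- demix_labels(frame, sc$demix_J, sc$demix_sweeps %||% 100,
                          seed = seed + 1L)
  if (!is.null(sc$stagger_offsets)) {
    off <- do.call(rbind, lapply(sc$stagger_offsets, as.data.frame))
    frame <- apply_staggering(frame, off, jitter_sd = 0.2, seed = seed + 2L)
  }
  if (!is.null(sc$desorb_fraction) && sc$desorb_fraction > 0)
    frame <- desorb(frame, sc$desorb_fraction,
                    sc$desorb_species %||% "all", seed = seed + 3L)
  traj <- make_trajectory(frame, sc$n_frames %||% 1L,
                          xy_jitter_sd = sc$xy_jitter_sd %||% 0,
                          z_jitter_sd = sc$z_jitter_sd %||% 0,
                          seed = seed + 4L)
  write_frames(traj, file.path(out_dir, "trajectory.gro"))
  logmsg("generated ", length(traj$frames), " frame(s), ", nrow(frame),
         " molecules")
  results$trajectory <- traj

  ## --- RDF + cutoff + graph metrics ---
  nc <- cfg$network %||% list()
  rdf <- compute_rdf(traj, r_max = nc$rdf_r_max,
                     bin_width = nc$rdf_bin_width %||% 0.1)
  write_tsv(rdf, file.path(out_dir, "rdf.tsv"))
  cutoff <- nc$cutoff %||% "auto"
  metrics <- metrics_over_trajectory(traj,
                                     species = nc$species %||% unique(frame$species),
                                     cutoff = cutoff,
                                     connectivity = nc$connectivity %||% TRUE)
  write_tsv(metrics, file.path(out_dir, "graph_metrics.tsv"))
  write_tsv(attr(metrics, "summary"), file.path(out_dir, "graph_summary.tsv"))
  logmsg(sprintf("graph metrics at cutoff %.2f A", attr(metrics, "cutoff")))
  results$rdf <- rdf; results$metrics <- metrics
  summary$cutoff_A <- attr(metrics, "cutoff")
  summ <- attr(metrics, "summary")
  summary$graph <- lapply(split(summ, summ$species), function(d)
    list(mean_degree = d$mean_degree, mean_connectivity = d$mean_connectivity))

  ## --- interface structure ---
  stc <- cfg$structure %||% list()
  devs <- vertical_deviations(traj, bin_width = stc$deviation_bin_width %||% 0.25)
  write_tsv(devs$stats, file.path(out_dir, "vertical_deviations.tsv"))
  dens <- density_profile(traj, bin_width = stc$density_bin_width %||% 0.5)
  write_tsv(dens, file.path(out_dir, "density_profile.tsv"))
  results$deviations <- devs; results$density <- dens

  ## --- synthetic umbrella windows + WHAM ---
  if (!is.null(cfg$wham)) {
    wc <- cfg$wham
    pot <- make_potential(wc$potential %||% "harmonic",
                          kappa = wc$kappa %||% 1,
                          a = wc$a %||% 1, b = wc$b %||% 1.5)
    centers <- seq(wc$centers[[1]], wc$centers[[2]], by = wc$centers[[3]])
    wins <- langevin_windows(pot, centers, k = wc$k %||% 10,
                             n_steps = wc$n_steps %||% 5000,
                             dt = wc$dt %||% 0.005,
                             friction = wc$friction %||% 1,
                             seed = seed + 5L)
    pmf <- wham(wins, grid = c(wc$grid[[1]], wc$grid[[2]], wc$grid[[3]]),
                tol = wc$tol %||% 1e-6)
    write_tsv(as.data.frame(pmf), file.path(out_dir, "pmf.tsv"))
    logmsg(sprintf("WHAM: %d windows, %d iterations, residual %.2e",
                   length(wins), attr(pmf, "iterations"), attr(pmf, "residual")))
    results$pmf <- pmf
    summary$wham <- list(iterations = attr(pmf, "iterations"),
                         converged = attr(pmf, "converged"),
                         max_G_kT = max(pmf$G, na.rm = TRUE))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("pipeline complete; outputs in ", normalizePath(out_dir))
  results$summary <- summary
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
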