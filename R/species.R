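#' Fatty-acid species table
#'
#' A species is a saturated fatty acid identified by a short label (for
#' example \code{"LA"} for lauric acid), its chain length in carbons, and its
#' surface acid dissociation constant (pKa). Surface pKa values at the
#' air-water interface are substantially larger than bulk values; the packaged
#' defaults are LA 7.44, MA 7.88, PA 8.34 and SA 9.89 (lauric, myristic,
#' palmitic, stearic).
#'
#' @param name character vector of unique short labels.
#' @param n_carbons integer vector of chain lengths (>= 2).
#' @param pKa numeric vector of surface pKa values (log10 scale).
#' @return A \code{data.frame} of class \code{fa_species_table} with columns
#'   \code{name}, \code{n_carbons}, \code{pKa}.
#' @examples
#' fa_species_table(c("LA", "PA"), c(12, 16), c(7.44, 8.34))
#' default_species_table()
#' @export
fa_species_table <- function(name, n_carbons, pKa) {
  if (length(name) == 0L) stop_invalid("species table must have at least one row")
  if (anyDuplicated(name)) stop_invalid("species names must be unique")
  n_carbons <- as.integer(n_carbons)
  if (any(is.na(n_carbons)) || any(n_carbons < 2L))
    stop_invalid("'n_carbons' must be integers >= 2")
  if (!all(is.finite(pKa))) stop_invalid("'pKa' must be finite")
  stopifnot(length(name) == length(n_carbons), length(name) == length(pKa))
  out <- data.frame(name = as.character(name), n_carbons = n_carbons,
                    pKa = as.numeric(pKa), stringsAsFactors = FALSE)
  class(out) <- c("fa_species_table", "data.frame")
  out
}

#' @describeIn fa_species_table The packaged default table (LA, MA, PA, SA
#'   surface pKa values) read from \code{inst/extdata/species.tsv}.
#' @export
default_species_table <- function() {
  path <- system.file("extdata", "species.tsv", package = "monomix",
                      mustWork = TRUE)
  read_species_table(path)
}

#' Read a species table from TSV
#'
#' Expects tab-separated columns \code{name}, \code{n_carbons}, \code{pKa}.
#'
#' @param path file path.
#' @return A \code{fa_species_table}.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "n_carbons", "pKa")
  if (!all(need %in% names(tab)))
    stop_invalid("species TSV must have columns: ", paste(need, collapse = ", "))
  fa_species_table(tab$name, tab$n_carbons, tab$pKa)
}

#' Mixture composition
#'
#' An ordered set of species with nonnegative mole ratios, e.g. the
#' quaternary marine proxy 1:2:4:3 LA:MA:PA:SA or a binary 1:1 LA:PA film.
#' Ratios are stored as given; normalized mole fractions are available via
#' \code{mole_fractions()}.
#'
#' @param species character vector of species names (must exist in
#'   \code{table}).
#' @param ratio numeric vector of nonnegative mole ratios, not all zero.
#' @param table a \code{fa_species_table}; defaults to the packaged table.
#' @return An object of class \code{mixture_composition}.
#' @examples
#' proxy <- mixture_composition(c("LA", "MA", "PA", "SA"), c(1, 2, 4, 3))
#' mole_fractions(proxy)
#' @export
mixture_composition <- function(species, ratio,
                                table = default_species_table()) {
  if (length(species) == 0L) stop_invalid("composition must have at least one entry")
  if (length(species) != length(ratio))
    stop_invalid("'species' and 'ratio' lengths differ")
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop_invalid("mole ratios must be finite and nonnegative")
  if (sum(ratio) <= 0) stop_invalid("mole ratios must not all be zero")
  if (anyDuplicated(species)) stop_invalid("duplicate species in composition")
  missing <- setdiff(species, table$name)
  if (length(missing))
    stop_invalid("species not in table: ", paste(missing, collapse = ", "))
  structure(list(species = as.character(species), ratio = as.numeric(ratio),
                 table = table),
            class = "mixture_composition")
}

#' @describeIn mixture_composition Normalized mole fractions (sum to 1).
#' @param mix a \code{mixture_composition}.
#' @export
mole_fractions <- function(mix) {
  stopifnot(inherits(mix, "mixture_composition"))
  f <- mix$ratio / sum(mix$ratio)
  names(f) <- mix$species
  f
}

## pKa lookup for the species of a mixture, in composition order.
mixture_pkas <- function(mix) {
  mix$table$pKa[match(mix$species, mix$table$name)]
}

#' Parse a composition string
#'
#' Parses compact \code{"LA:1,MA:2,PA:4,SA:3"} notation into a
#' \code{mixture_composition}.
#'
#' @param text composition string, comma-separated \code{name:ratio} pairs.
#' @param table species table used for pKa lookup.
#' @return A \code{mixture_composition}.
#' @export
parse_composition <- function(text, table = default_species_table()) {
  parts <- strsplit(trimws(strsplit(text, ",")[[1]]), ":")
  if (any(lengths(parts) != 2L))
    stop_invalid("composition must look like 'LA:1,PA:1'")
  mixture_composition(vapply(parts, `[`, "", 1L),
                      as.numeric(vapply(parts, `[`, "", 2L)), table)
}

#' @export
print.mixture_composition <- function(x, ...) {
  f <- mole_fractions(x)
  cat("Mixture composition:",
      paste(sprintf("%s:%g", x$species, x$ratio), collapse = " "), "\n")
  cat("Mole fractions:",
      paste(sprintf("%s=%.4f", names(f), f), collapse = " "), "\n")
  invisible(x)
}
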