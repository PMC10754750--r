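# Closed vocabularies and table schemas for the survey data model.
# All categorical fields are closed enums: unidentifiable particles must use
# the explicit "unknown"/"other" values, never free text.

#' @keywords internal
mp_sites <- c("S1", "S2")

#' @keywords internal
mp_seasons <- c("winter", "spring", "summer", "autumn")

#' @keywords internal
mp_matrices <- c("sediment", "larva", "tube")

#' @keywords internal
mp_shapes <- c("fiber", "fragment")

#' @keywords internal
mp_colors <- c("blue", "red", "black", "green", "violet", "orange",
               "yellow", "other")

#' @keywords internal
mp_polymers <- c("PES", "PE", "PP", "unknown")

#' @keywords internal
mp_basis_units <- c("kg_dry_sediment", "individual", "tube", "g_wet_tube")

#' @keywords internal
mp_instars <- c("L2", "L4")

# basis unit(s) admissible for each sample matrix
basis_for_matrix <- list(
  sediment = "kg_dry_sediment",
  larva    = "individual",
  tube     = c("tube", "g_wet_tube")
)

particle_cols <- c("site", "season", "matrix", "replicate_id", "shape",
                   "length_um", "width_um", "color", "polymer")

abundance_cols <- c("site", "season", "matrix", "replicate_id", "count",
                    "basis_amount", "basis_unit", "abundance")

#' Closed vocabularies of the survey schema
#'
#' Returns the categorical vocabularies used throughout the package: sites,
#' seasons, sample matrices, particle shapes, colours, polymer labels, count
#' basis units and larval instars.
#'
#' @return Named list of character vectors.
#' @export
#' @examples
#' mp_vocabulary()$polymer
mp_vocabulary <- function() {
  list(site = mp_sites, season = mp_seasons, matrix = mp_matrices,
       shape = mp_shapes, color = mp_colors, polymer = mp_polymers,
       basis_unit = mp_basis_units, instar = mp_instars)
}

# -- validation helpers -------------------------------------------------------

fail_rows <- function(bad, what) {
  if (any(bad)) {
    rows <- which(bad)
    stop(sprintf("invalid %s in row(s) %s", what,
                 paste(utils::head(rows, 10L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_enum <- function(x, allowed, what) {
  fail_rows(!(x %in% allowed), sprintf(
    "%s (allowed: %s)", what, paste(allowed, collapse = ", ")))
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[needed]
}

#' Validate a particle table
#'
#' Checks one-row-per-particle data against the schema: closed enums for
#' site/season/matrix/shape/color/polymer, strictly positive length and width
#' (micrometres), and width < length for fibers. Validation is total: any
#' malformed row aborts with the offending row numbers, never a partially
#' accepted table.
#'
#' @param particles data.frame with columns
#'   `site, season, matrix, replicate_id, shape, length_um, width_um, color, polymer`.
#' @return The validated data.frame, columns in canonical order, invisibly
#'   usable downstream.
#' @export
validate_particles <- function(particles) {
  particles <- check_columns(as.data.frame(particles), particle_cols,
                             "particle table")
  particles$replicate_id <- as.character(particles$replicate_id)
  check_enum(particles$site, mp_sites, "site")
  check_enum(particles$season, mp_seasons, "season")
  check_enum(particles$matrix, mp_matrices, "matrix")
  check_enum(particles$shape, mp_shapes, "shape")
  check_enum(particles$color, mp_colors, "color")
  check_enum(particles$polymer, mp_polymers, "polymer")
  fail_rows(!is.finite(particles$length_um) | particles$length_um <= 0,
            "length_um (must be a positive number)")
  fail_rows(!is.finite(particles$width_um) | particles$width_um <= 0,
            "width_um (must be a positive number)")
  fib <- particles$shape == "fiber"
  fail_rows(fib & particles$width_um >= particles$length_um,
            "fiber geometry (width_um must be < length_um)")
  particles
}

#' Validate a replicate abundance table
#'
#' Checks one-row-per-replicate normalized counts: non-negative integer
#' `count`, positive `basis_amount`, `abundance == count / basis_amount`
#' exactly, and a `basis_unit` consistent with the matrix (sediment is
#' counted per kg dry sediment, larvae per individual, tubes per tube or per
#' g wet tube).
#'
#' @param abundances data.frame with columns
#'   `site, season, matrix, replicate_id, count, basis_amount, basis_unit, abundance`.
#' @return The validated data.frame in canonical column order.
#' @export
validate_abundances <- function(abundances) {
  abundances <- check_columns(as.data.frame(abundances), abundance_cols,
                              "abundance table")
  abundances$replicate_id <- as.character(abundances$replicate_id)
  check_enum(abundances$site, mp_sites, "site")
  check_enum(abundances$season, mp_seasons, "season")
  check_enum(abundances$matrix, mp_matrices, "matrix")
  check_enum(abundances$basis_unit, mp_basis_units, "basis_unit")
  fail_rows(!is.finite(abundances$count) | abundances$count < 0 |
              abundances$count != round(abundances$count),
            "count (must be a non-negative integer)")
  fail_rows(!is.finite(abundances$basis_amount) | abundances$basis_amount <= 0,
            "basis_amount (must be positive)")
  fail_rows(abs(abundances$abundance -
                  abundances$count / abundances$basis_amount) > 1e-9,
            "abundance (must equal count / basis_amount)")
  ok_unit <- mapply(function(m, u) u %in% basis_for_matrix[[m]],
                    abundances$matrix, abundances$basis_unit)
  fail_rows(!ok_unit, "basis_unit (inconsistent with matrix)")
  abundances
}
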