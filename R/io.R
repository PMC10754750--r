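# Delimited-text I/O for the canonical tables. Comma-separated, UTF-8,
# "." decimal, units fixed in column names (length_um, basis_amount in the
# unit named by basis_unit). Column order in files is free; readers
# canonicalise it.

#' Read a particle table
#'
#' Reads a comma-separated particle table (one row per detected microplastic
#' particle) and validates every row against the schema. The header must
#' contain the canonical column names; column order is free.
#'
#' @param path Path to a CSV file.
#' @return Validated particle data.frame (see [validate_particles()]).
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(replicate_id = "character"))
  validate_particles(df)
}

#' Write a particle table
#'
#' Writes validated particle records as UTF-8 CSV. `read_particle_table()`
#' round-trips the result.
#'
#' @param particles Particle data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  particles <- if (nrow(as.data.frame(particles)) == 0L)
    empty_particles() else validate_particles(particles)
  utils::write.csv(particles, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a replicate abundance table
#'
#' @param path Path to a CSV file with the replicate abundance schema.
#' @return Validated abundance data.frame (see [validate_abundances()]).
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(replicate_id = "character"))
  validate_abundances(df)
}

#' Write a replicate abundance table
#'
#' @param abundances Abundance data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abundances, path) {
  abundances <- if (nrow(as.data.frame(abundances)) == 0L)
    empty_abundances() else validate_abundances(abundances)
  utils::write.csv(abundances, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

empty_particles <- function() {
  data.frame(site = character(), season = character(), matrix = character(),
             replicate_id = character(), shape = character(),
             length_um = numeric(), width_um = numeric(),
             color = character(), polymer = character(),
             stringsAsFactors = FALSE)
}

empty_abundances <- function() {
  data.frame(site = character(), season = character(), matrix = character(),
             replicate_id = character(), count = integer(),
             basis_amount = numeric(), basis_unit = character(),
             abundance = numeric(), stringsAsFactors = FALSE)
}

#' Default polymer hazard scores
#'
#' Dimensionless per-polymer hazard scores (Lithner scores) used by the
#' polymer hazard index: PP = 4, PES = 4, PE = 11. Lookups of polymers absent
#' from the table are errors, never silent zeros; extend the table to admit
#' additional polymers.
#'
#' @param ... Named numeric overrides or additions, e.g. `PVC = 10001`.
#' @return Named numeric vector of hazard scores.
#' @export
#' @examples
#' hazard_scores()
#' hazard_scores(PS = 30)
hazard_scores <- function(...) {
  scores <- c(PP = 4, PES = 4, PE = 11)
  extra <- c(...)
  if (length(extra) > 0L) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("hazard score overrides must be named", call. = FALSE)
    if (any(extra < 0)) stop("hazard scores must be >= 0", call. = FALSE)
    scores[names(extra)] <- extra
  }
  scores
}
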