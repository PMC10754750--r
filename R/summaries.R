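# Descriptive statistics: abundance mean/sd per group, composition
# proportions, size-class binning and detection rates. Full precision is
# retained internally; report rounding happens only in the rendering layer.

#' Summarise replicate abundances by group
#'
#' Mean, sd and replicate count of `abundance` per grouping cell. Groups are
#' taken from the data; requesting a grouping column that does not exist, or
#' a table whose groups are empty, is an error.
#'
#' @param abundances Replicate abundance table.
#' @param by Character vector of grouping columns (default site x season x
#'   matrix).
#' @return data.frame with the grouping columns plus `n_replicates`, `mean`,
#'   `sd` (sd is 0 for a single replicate) and `unit`.
#' @export
#' @examples
#' sed <- gen_sediment(default_calibration(), seed = 1, particles = FALSE)
#' summarize_abundance(sed$abundances)
summarize_abundance <- function(abundances,
                                by = c("site", "season", "matrix")) {
  abundances <- validate_abundances(abundances)
  if (nrow(abundances) == 0L)
    stop("empty abundance table", call. = FALSE)
  bad <- setdiff(by, names(abundances))
  if (length(bad) > 0L)
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- interaction(abundances[by], drop = TRUE, sep = "|")
  groups <- split(abundances, key)
  out <- lapply(groups, function(g) {
    if (nrow(g) == 0L)
      stop("empty group in abundance summary", call. = FALSE)
    unit <- unique(g$basis_unit)
    if (length(unit) > 1L)
      stop("mixed basis units within group ",
           paste(g[1L, by], collapse = "/"), call. = FALSE)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n_replicates = nrow(g), mean = mean(g$abundance),
                     sd = if (nrow(g) > 1L) stats::sd(g$abundance) else 0,
                     unit = unit, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Pool site means into cross-site seasonal means
#'
#' The cross-site seasonal mean is the unweighted mean of the per-site
#' means, with its sd the sd of the site means — the pooling convention used
#' when two sites' seasonal abundances are reported together (e.g. site
#' means 345.8 and 380 pool to 362.9, reported 363 +/- 24).
#'
#' @param summary Output of [summarize_abundance()] grouped by site and
#'   season.
#' @return data.frame with `season`, `mean`, `sd`, `n_sites`.
#' @export
pool_site_means <- function(summary) {
  if (!all(c("site", "season", "mean") %in% names(summary)))
    stop("need a summary with site, season and mean columns", call. = FALSE)
  groups <- split(summary, summary$season)
  out <- lapply(groups, function(g) {
    data.frame(season = g$season[1L], mean = mean(g$mean),
               sd = if (nrow(g) > 1L) stats::sd(g$mean) else 0,
               n_sites = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$season, mp_seasons)), , drop = FALSE]
}

#' Size-class labels for the survey's length bins
#'
#' @param edges_um Upper class edges in micrometres.
#' @param overflow Include a final open class above the top edge?
#' @return Character vector of class labels.
#' @export
size_class_labels <- function(edges_um = c(500, 1000, 1500, 2000, 2500),
                              overflow = TRUE) {
  lab <- c(sprintf("<%d", edges_um[1L]),
           sprintf("%d-%d", utils::head(edges_um, -1L) + 1L,
                   utils::tail(edges_um, -1L)))
  if (overflow) lab <- c(lab, sprintf(">%d", edges_um[length(edges_um)]))
  lab
}

#' Bin particle lengths into size classes
#'
#' Partitions lengths into the survey's five classes using half-open
#' intervals (0, 500\], (500, 1000\], ..., (2000, 2500\] — the half-open
#' convention closes the gap between the nominal "<500" and "501-1000"
#' labels, so a length of exactly 500 falls in the first class and 500.5 in
#' the second. Lengths above the top edge go to an explicit overflow class.
#'
#' @param particles Particle table (or any data.frame with `length_um`).
#' @param edges_um Upper class edges in micrometres.
#' @return data.frame with `size_class`, `count`, `proportion`; counts
#'   partition the particles (they sum to `nrow(particles)`).
#' @export
#' @examples
#' p <- data.frame(length_um = c(400, 700, 1200, 1800, 2300))
#' bin_lengths(p)
bin_lengths <- function(particles, edges_um = c(500, 1000, 1500, 2000, 2500)) {
  len <- particles$length_um
  if (is.null(len)) stop("no length_um column", call. = FALSE)
  labels <- size_class_labels(edges_um, overflow = TRUE)
  cls <- cut(len, breaks = c(0, edges_um, Inf), labels = labels,
             right = TRUE, include.lowest = TRUE)
  cnt <- as.integer(table(cls))
  data.frame(size_class = labels, count = cnt,
             proportion = if (length(len) > 0L) cnt / length(len)
                          else rep(NA_real_, length(cnt)),
             stringsAsFactors = FALSE)
}

#' Composition proportions for a particle attribute
#'
#' Proportion of particles in each category of `attribute` (shape, color,
#' polymer or size_class), optionally per grouping cell. Categories with
#' zero count are reported as 0, never dropped, so compositions are always
#' exhaustive and sum to 1.
#'
#' @param particles Particle table.
#' @param attribute One of `"shape"`, `"color"`, `"polymer"`,
#'   `"size_class"`.
#' @param by Optional character vector of grouping columns.
#' @param edges_um Size-class edges (used when `attribute = "size_class"`).
#' @return data.frame with grouping columns, `category`, `count`,
#'   `proportion`.
#' @export
composition <- function(particles, attribute = c("shape", "color", "polymer",
                                                 "size_class"),
                        by = NULL, edges_um = c(500, 1000, 1500, 2000, 2500)) {
  attribute <- match.arg(attribute)
  particles <- as.data.frame(particles)
  if (nrow(particles) == 0L) stop("empty particle table", call. = FALSE)
  if (attribute == "size_class") {
    labels <- size_class_labels(edges_um, overflow = TRUE)
    particles$size_class <- as.character(
      cut(particles$length_um, breaks = c(0, edges_um, Inf), labels = labels,
          right = TRUE, include.lowest = TRUE))
    cats <- labels
  } else {
    cats <- mp_vocabulary()[[attribute]]
  }
  one_group <- function(g, meta) {
    cnt <- table(factor(g[[attribute]], levels = cats))
    res <- data.frame(category = cats, count = as.integer(cnt),
                      proportion = as.integer(cnt) / nrow(g),
                      stringsAsFactors = FALSE)
    if (!is.null(meta)) res <- cbind(meta, res, row.names = NULL)
    res
  }
  if (is.null(by)) return(one_group(particles, NULL))
  bad <- setdiff(by, names(particles))
  if (length(bad) > 0L)
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- interaction(particles[by], drop = TRUE, sep = "|")
  out <- lapply(split(particles, key), function(g) {
    if (nrow(g) == 0L) stop("empty group in composition", call. = FALSE)
    one_group(g, g[1L, by, drop = FALSE])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detection rate of contaminated units
#'
#' Fraction of sampled units (larvae, tubes, samples) carrying at least one
#' particle.
#'
#' @param burdens Non-negative integer vector, one entry per unit.
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' detection_rate(c(0, 1, 2, 0, 3))  # 0.6
detection_rate <- function(burdens) {
  if (length(burdens) < 1L) stop("need at least one unit", call. = FALSE)
  if (any(!is.finite(burdens) | burdens < 0))
    stop("burdens must be non-negative counts", call. = FALSE)
  mean(burdens >= 1)
}
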