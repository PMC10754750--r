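# Survey calibration: the generator's parameter set. Defaults encode the
# field study's reported conditions (site x season sediment abundances,
# shape/colour/polymer compositions, truncated-normal size distributions,
# sediment->biota burden couplings, instar morphometrics). Overrides come
# from a hierarchical YAML config; unknown keys are rejected with a
# nearest-key hint so typos never silently fall back to defaults.

#' Default survey calibration
#'
#' The full parameter set of the synthetic survey generator. Abundances are
#' items per kg dry sediment (mean, sd per site x season, 15 replicates);
#' compositions are proportion vectors per matrix (and per site where the
#' study reports site-level values); particle sizes are truncated normals in
#' micrometres parameterised by the reported mean/sd and truncated at the
#' reported min/max; sediment-to-biota couplings are linear models of the
#' cell mean burden on the cell sediment abundance, least-squares calibrated
#' to the reported cell means; the ingestion selectivity curve is a
#' monotone non-increasing weight over particle length.
#'
#' @return Nested list; see the methods vignette for the meaning, unit and
#'   provenance of every leaf.
#' @export
#' @examples
#' cal <- default_calibration()
#' cal$sediment_abundance$S1$winter
default_calibration <- function() {
  list(
    co = 1.79,                   # background concentration, items/kg DW
    n_sediment_replicates = 15,  # sediment samples per site x season
    sediment_basis_kg = 1,       # dry mass counted per replicate, kg
    sediment_abundance = list(   # items/kg DW
      S1 = list(winter = c(mean = 345.8, sd = 63),
                spring = c(mean = 251.4, sd = 27.2),
                summer = c(mean = 385.2, sd = 38.2),
                autumn = c(mean = 310,   sd = 84)),
      S2 = list(winter = c(mean = 380,   sd = 54),
                spring = c(mean = 312,   sd = 64.7),
                summer = c(mean = 470,   sd = 70),
                autumn = c(mean = 354.2, sd = 62))),
    shape_proportions = list(
      sediment = list(S1 = c(fiber = 0.96, fragment = 0.04),
                      S2 = c(fiber = 0.88, fragment = 0.12)),
      larva    = list(S1 = c(fiber = 0.93, fragment = 0.07),
                      S2 = c(fiber = 0.86, fragment = 0.14)),
      tube     = list(S1 = c(fiber = 0.90, fragment = 0.10),
                      S2 = c(fiber = 0.90, fragment = 0.10))),
    color_proportions = list(
      sediment = c(blue = 0.35, red = 0.23, black = 0.22, green = 0.13,
                   violet = 0.03, orange = 0.02, yellow = 0.02, other = 0),
      larva    = c(blue = 0.405, red = 0.28, black = 0.16, green = 0.065,
                   violet = 0.03, orange = 0.03, yellow = 0.03, other = 0),
      tube     = c(blue = 0.42, red = 0.225, black = 0.145, green = 0.08,
                   violet = 0.05, orange = 0.04, yellow = 0.04, other = 0)),
    polymer_proportions = list(
      sediment = list(S1 = c(PES = 0.96, PE = 0.01, PP = 0.03, unknown = 0),
                      S2 = c(PES = 0.87, PE = 0.09, PP = 0.04, unknown = 0)),
      larva    = list(S1 = c(PES = 0.895, PE = 0.105, PP = 0, unknown = 0),
                      S2 = c(PES = 0.895, PE = 0.105, PP = 0, unknown = 0)),
      tube     = list(S1 = c(PES = 0.93, PE = 0.07, PP = 0, unknown = 0),
                      S2 = c(PES = 0.93, PE = 0.07, PP = 0, unknown = 0))),
    length_dists = list(  # sediment particle lengths, um
      fiber    = c(mean = 1429, sd = 495, lower = 684, upper = 2390),
      fragment = c(mean = 554,  sd = 269, lower = 157, upper = 1032)),
    width_dists = list(   # sediment particle widths, um
      fiber    = c(mean = 14.6, sd = 4,   lower = 13,  upper = 18),
      fragment = c(mean = 278,  sd = 181, lower = 64,  upper = 632)),
    # ingestion selectivity: weight 1 up to plateau_um, linear decay to
    # `floor` at cutoff_um, constant floor beyond
    selectivity = c(plateau_um = 1000, cutoff_um = 1500, floor = 0.05),
    larva_coupling = c(intercept = -0.0287776, slope = 0.00243422),
    larva_design   = c(n_subsamples = 5, n_per_subsample = 10),
    tube_coupling  = c(intercept = -0.2022368, slope = 0.00215631),
    tube_design    = c(n_samples = 5, n_tubes_per_sample = 10),
    tube_sample_weight_g = c(mean = 0.8535, sd = 0.10),  # per 10-tube sample
    instar = list(
      L2 = list(weight_mg = c(mean = 4.8, sd = 1.2),
                body_length_mm = c(mean = 3.2, sd = 0.5),
                head_capsule_width_mm = c(mean = 0.21, sd = 0.01),
                head_capsule_length_mm = c(mean = 0.213, sd = 0.022),
                mentum_width_mm = c(mean = 0.059, sd = 0.004),
                burden_mean = 0.52,
                fragment_share = 0,
                fiber_length = c(mean = 422, sd = 84, lower = 200, upper = 600),
                fragment_length = c(mean = 90, sd = 13, lower = 40, upper = 140)),
      L4 = list(weight_mg = c(mean = 8.6, sd = 2.4),
                body_length_mm = c(mean = 14.8, sd = 6.3),
                head_capsule_width_mm = c(mean = 0.69, sd = 0.15),
                head_capsule_length_mm = c(mean = 0.37, sd = 0.041),
                mentum_width_mm = c(mean = 0.162, sd = 0.013),
                burden_mean = 0.91,
                fragment_share = 0.17,
                fiber_length = c(mean = 937, sd = 120, lower = 894, upper = 1132),
                fragment_length = c(mean = 73, sd = 20, lower = 20, upper = 130))),
    instar_design = c(n_replicates = 10, n_per_replicate = 10)
  )
}

prop_sum_ok <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)

check_dist <- function(d, what) {
  if (!all(c("mean", "sd", "lower", "upper") %in% names(d)))
    stop(what, ": distribution needs mean, sd, lower, upper", call. = FALSE)
  if (d[["sd"]] < 0) stop(what, ": sd must be >= 0", call. = FALSE)
  if (d[["lower"]] <= 0 || d[["lower"]] >= d[["upper"]])
    stop(what, ": need 0 < lower < upper", call. = FALSE)
  invisible(TRUE)
}

#' Validate a survey calibration
#'
#' Checks structural and numeric invariants: every proportion vector sums to
#' 1 within 1e-9 with non-negative entries, all sds are non-negative, size
#' distributions have 0 < lower < upper, and the selectivity curve is a
#' valid non-increasing weight (floor in \[0, 1\]).
#'
#' @param cal Calibration list as produced by [default_calibration()] or
#'   [load_calibration()].
#' @return `cal`, invisibly, if valid; otherwise an error.
#' @export
validate_calibration <- function(cal) {
  for (site in mp_sites) for (season in mp_seasons) {
    a <- cal$sediment_abundance[[site]][[season]]
    if (is.null(a) || !all(c("mean", "sd") %in% names(a)))
      stop("sediment_abundance$", site, "$", season,
           " needs mean and sd", call. = FALSE)
    if (a[["mean"]] < 0 || a[["sd"]] < 0)
      stop("sediment_abundance$", site, "$", season,
           ": mean and sd must be >= 0", call. = FALSE)
  }
  for (m in mp_matrices) {
    for (site in mp_sites) {
      sp <- cal$shape_proportions[[m]][[site]]
      if (!prop_sum_ok(sp) || !setequal(names(sp), mp_shapes))
        stop("shape_proportions$", m, "$", site,
             " must cover {fiber, fragment} and sum to 1", call. = FALSE)
      pp <- cal$polymer_proportions[[m]][[site]]
      if (!prop_sum_ok(pp) || !all(names(pp) %in% mp_polymers))
        stop("polymer_proportions$", m, "$", site,
             " must use known polymers and sum to 1", call. = FALSE)
    }
    cp <- cal$color_proportions[[m]]
    if (!prop_sum_ok(cp) || !all(names(cp) %in% mp_colors))
      stop("color_proportions$", m,
           " must use known colors and sum to 1", call. = FALSE)
  }
  for (sh in mp_shapes) {
    check_dist(cal$length_dists[[sh]], paste0("length_dists$", sh))
    check_dist(cal$width_dists[[sh]], paste0("width_dists$", sh))
  }
  sel <- cal$selectivity
  if (sel[["floor"]] < 0 || sel[["floor"]] > 1 ||
      sel[["plateau_um"]] <= 0 || sel[["cutoff_um"]] < sel[["plateau_um"]])
    stop("selectivity: need 0 < plateau_um <= cutoff_um and floor in [0, 1]",
         call. = FALSE)
  if (cal$co <= 0) stop("co must be > 0", call. = FALSE)
  if (cal$n_sediment_replicates < 1 || cal$sediment_basis_kg <= 0)
    stop("need n_sediment_replicates >= 1 and sediment_basis_kg > 0",
         call. = FALSE)
  for (ins in mp_instars) {
    ip <- cal$instar[[ins]]
    if (ip$burden_mean < 0 || ip$fragment_share < 0 || ip$fragment_share > 1)
      stop("instar$", ins, ": burden_mean >= 0, fragment_share in [0, 1]",
           call. = FALSE)
    check_dist(ip$fiber_length, paste0("instar$", ins, "$fiber_length"))
    check_dist(ip$fragment_length, paste0("instar$", ins, "$fragment_length"))
  }
  invisible(cal)
}

# Recursively merge `override` into `base`, refusing keys absent from the
# default structure and suggesting the nearest valid key.
merge_calibration <- function(base, override, path = "") {
  if (!is.list(override))
    override <- as.list(override)
  for (key in names(override)) {
    if (!key %in% names(base)) {
      valid <- names(base)
      d <- utils::adist(key, valid, ignore.case = TRUE)
      hint <- valid[which.min(d)]
      stop(sprintf("unknown calibration key '%s%s'; nearest valid key: '%s%s'",
                   path, key, path, hint), call. = FALSE)
    }
    new <- override[[key]]
    old <- base[[key]]
    sub <- paste0(path, key, "$")
    if (is.list(old) && !is.null(names(old))) {
      base[[key]] <- merge_calibration(old, new, sub)
    } else if (is.numeric(old) && length(old) > 1L && !is.null(names(old))) {
      new <- unlist(new)
      if (is.null(names(new)) || any(names(new) == "")) {
        if (length(new) != length(old))
          stop("calibration key '", path, key, "' needs named values",
               call. = FALSE)
        names(new) <- names(old)
      }
      base[[key]] <- unlist(merge_calibration(as.list(old), as.list(new), sub))
    } else {
      base[[key]] <- as.numeric(unlist(new))
    }
  }
  base
}

#' Load a survey calibration from a YAML config
#'
#' Reads a hierarchical YAML file whose structure mirrors
#' [default_calibration()], fills every omitted leaf with its default, and
#' rejects unknown keys (naming the nearest valid key, so a misspelt key can
#' never silently leave a default in place). An empty or missing config
#' yields the full default calibration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional nested list of overrides applied after the file
#'   (flags-over-config precedence).
#' @return Validated calibration list.
#' @export
#' @examples
#' cal <- load_calibration(NULL,
#'   overrides = list(sediment_abundance = list(S1 = list(summer =
#'     c(mean = 500)))))
#' cal$sediment_abundance$S1$summer
load_calibration <- function(path = NULL, overrides = NULL) {
  cal <- default_calibration()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    conf <- yaml::read_yaml(path)
    if (length(conf) > 0L) cal <- merge_calibration(cal, conf)
  }
  if (!is.null(overrides) && length(overrides) > 0L)
    cal <- merge_calibration(cal, overrides)
  validate_calibration(cal)
  cal
}
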