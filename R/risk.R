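# The five-equation sediment risk-index stack and its hazard categories:
#
#   CF  = Ci / Co            contamination factor
#   PLI = sqrt(CF)           pollution load index
#   H   = sum_n Pn * Sn      polymer hazard index, Pn on the PERCENT scale
#   Tj  = H / Ci             toxicity coefficient
#   RI  = Tj * CF            potential ecological risk index
#
# Note the algebraic identity RI = H / Co: RI does not depend on Ci. All
# internal arithmetic is full precision; report rounding is applied only by
# the rendering helpers (report_* / render_table1).

#' Contamination factor
#'
#' `CF = Ci / Co`: site concentration over a literature background
#' concentration (default 1.79 items/kg dry weight, a worldwide sediment
#' benchmark — overridable, it is not a constant of nature).
#'
#' @param ci Site MP concentration, items/kg dry sediment (>= 0).
#' @param co Background concentration, items/kg dry sediment (> 0).
#' @return CF, full precision.
#' @export
#' @examples
#' contamination_factor(345.8)  # 193.2
contamination_factor <- function(ci, co = 1.79) {
  if (any(co <= 0)) stop("background concentration co must be > 0",
                         call. = FALSE)
  if (any(ci < 0)) stop("ci must be >= 0", call. = FALSE)
  ci / co
}

#' Pollution load index
#'
#' `PLI = sqrt(CF)`.
#'
#' @param cf Contamination factor (>= 0).
#' @return PLI, full precision.
#' @export
pollution_load_index <- function(cf) {
  if (any(cf < 0)) stop("cf must be >= 0", call. = FALSE)
  sqrt(cf)
}

#' Polymer hazard index
#'
#' `H = sum_n Pn * Sn`, where `Pn` is each polymer's share of the site's
#' particles ON THE PERCENT SCALE (0-100) and `Sn` its hazard score. The
#' percent scale is deliberate: with the default scores (PES = PP = 4,
#' PE = 11) it is what yields index values in the hundreds, e.g.
#' `{PES: 93, PP: 7} -> 93*4 + 7*4 = 400`; a fraction-scale Pn would give
#' values 100x smaller. Percentages must sum to 100 within 0.5 (reported
#' compositions drift by rounding). A polymer missing from the score table
#' is an error, never a silent zero.
#'
#' @param percent Named numeric vector of polymer percentages (0-100).
#' @param scores Named hazard-score vector, see [hazard_scores()].
#' @return H, full precision.
#' @export
#' @examples
#' polymer_hazard_index(c(PES = 93, PP = 7))  # 400
polymer_hazard_index <- function(percent, scores = hazard_scores()) {
  if (length(percent) == 0L) stop("empty polymer composition", call. = FALSE)
  if (is.null(names(percent)) || any(names(percent) == ""))
    stop("polymer percentages must be named", call. = FALSE)
  if (any(percent < 0)) stop("polymer percentages must be >= 0",
                             call. = FALSE)
  if (abs(sum(percent) - 100) > 0.5)
    stop(sprintf("polymer percentages sum to %.2f, not 100 (+/- 0.5)",
                 sum(percent)), call. = FALSE)
  missing <- setdiff(names(percent), names(scores))
  if (length(missing) > 0L)
    stop("no hazard score for polymer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sum(percent * scores[names(percent)])
}

#' Toxicity coefficient
#'
#' `Tj = H / Ci`: the polymer hazard index scaled by the site concentration.
#'
#' @param h Polymer hazard index (>= 0).
#' @param ci Site MP concentration, items/kg (> 0).
#' @return Tj, full precision.
#' @export
#' @examples
#' toxicity_coefficient(400, 380)  # 1.0526
toxicity_coefficient <- function(h, ci) {
  if (any(ci <= 0)) stop("ci must be > 0 (Tj is undefined at 0)",
                         call. = FALSE)
  if (any(h < 0)) stop("h must be >= 0", call. = FALSE)
  h / ci
}

#' Potential ecological risk index
#'
#' `RI = Tj * CF`. Algebraically `RI = H / Co`, so RI is independent of the
#' site concentration — the implementation computes `Tj * CF` at full
#' precision and preserves that identity to floating error.
#'
#' @param tj Toxicity coefficient (>= 0).
#' @param cf Contamination factor (>= 0).
#' @return RI, full precision.
#' @export
ecological_risk_index <- function(tj, cf) {
  if (any(tj < 0) || any(cf < 0)) stop("tj and cf must be >= 0",
                                       call. = FALSE)
  tj * cf
}

# -- hazard categories --------------------------------------------------------

roman <- c("I", "II", "III", "IV", "V")

step_level <- function(x, breaks, n_levels) {
  if (any(x < 0)) stop("index values must be >= 0", call. = FALSE)
  lvl <- findInterval(x, breaks, left.open = FALSE) + 1L
  factor(roman[pmin(lvl, n_levels)], levels = roman[seq_len(n_levels)])
}

#' Pollution load categories
#'
#' Four pollution degrees for PLI. The category table is not printed with
#' the index definition in the field literature we calibrate to; the default
#' thresholds (I: <10, II: 10-20, III: 20-30, IV: >=30) are chosen so that
#' PLI values of 12-16.5 fall in category II ("medium"), matching how such
#' surveys label them, and are overridable.
#'
#' @param pli PLI values (>= 0).
#' @param breaks Ascending category thresholds.
#' @return Factor with levels I-IV; labels via [pli_label()].
#' @export
#' @examples
#' classify_pli(13.5)  # II
classify_pli <- function(pli, breaks = c(10, 20, 30)) {
  step_level(pli, breaks, 4L)
}

#' English label of a PLI category
#' @param category Factor/character I-IV from [classify_pli()].
#' @return Character: "low", "medium", "high", "very high".
#' @export
pli_label <- function(category) {
  unname(c(I = "low", II = "medium", III = "high",
           IV = "very high")[as.character(category)])
}

#' Polymer hazard levels
#'
#' Four levels for H: I < 10, II 10-100, III 100-1000, IV > 1000, read as
#' half-open intervals \[10, 100), \[100, 1000) with 1000 itself assigned to
#' level IV.
#'
#' @param h H values (>= 0).
#' @return Factor with levels I-IV.
#' @export
#' @examples
#' classify_h(416)  # III
classify_h <- function(h) {
  step_level(h, c(10, 100, 1000), 4L)
}

#' Ecological risk levels
#'
#' Five levels for RI: I < 150, II 150-300, III 300-600, IV 600-1200,
#' V >= 1200 (half-open intervals).
#'
#' @param ri RI values (>= 0).
#' @return Factor with levels I-V.
#' @export
#' @examples
#' classify_ri(232)  # II
classify_ri <- function(ri) {
  step_level(ri, c(150, 300, 600, 1200), 5L)
}

# -- profile assembly ---------------------------------------------------------

#' Assemble a full risk profile for one site and period
#'
#' Computes the whole stack (CF, PLI, H, Tj, RI) plus hazard categories from
#' a period concentration and a polymer composition. `ci` may be a vector of
#' seasonal mean concentrations, in which case the period concentration is
#' their unweighted mean (the convention for annual rows: the 1-year Ci is
#' the mean of the four seasonal means). `h` may be supplied directly when
#' the hazard index is an input (e.g. reproducing a published table whose
#' underlying unrounded compositions are not available); otherwise it is
#' computed from `polymer_percent`.
#'
#' @param ci Period concentration (items/kg), or vector of seasonal means.
#' @param polymer_percent Named polymer percentages (0-100); required unless
#'   `h` is given.
#' @param h Optional pre-computed polymer hazard index.
#' @param co Background concentration.
#' @param scores Hazard score table.
#' @param site,period Labels carried into the profile (period is a season or
#'   `"year"`).
#' @return One-row data.frame: site, period, Ci, Co, CF, PLI, H, Tj, RI,
#'   pli_category, h_level, ri_level. All numeric columns full precision.
#' @export
#' @examples
#' risk_profile(ci = c(380, 312, 470, 354.2), h = 460,
#'              site = "S2", period = "year")
risk_profile <- function(ci, polymer_percent = NULL, h = NULL, co = 1.79,
                         scores = hazard_scores(), site = NA_character_,
                         period = NA_character_) {
  ci <- mean(ci)
  if (ci <= 0)
    stop("period concentration must be > 0 (Tj is undefined)", call. = FALSE)
  if (is.null(h)) {
    if (is.null(polymer_percent))
      stop("supply either polymer_percent or h", call. = FALSE)
    h <- polymer_hazard_index(polymer_percent, scores)
  }
  cf <- contamination_factor(ci, co)
  pli <- pollution_load_index(cf)
  tj <- toxicity_coefficient(h, ci)
  ri <- ecological_risk_index(tj, cf)
  data.frame(site = site, period = period, Ci = ci, Co = co, CF = cf,
             PLI = pli, H = h, Tj = tj, RI = ri,
             pli_category = as.character(classify_pli(pli)),
             h_level = as.character(classify_h(h)),
             ri_level = as.character(classify_ri(ri)),
             stringsAsFactors = FALSE)
}

#' Seasonal and annual risk profiles for both sites
#'
#' Builds the full 2-site x 5-period (four seasons + year) risk table from
#' seasonal mean concentrations and per-cell hazard indices (or polymer
#' compositions). The annual Ci is the unweighted mean of the four seasonal
#' means; the annual H, when given via `h`, is taken from `h$year`.
#'
#' @param seasonal_ci Named list `list(S1 = c(winter = ..., ...), S2 = ...)`
#'   of seasonal mean concentrations (items/kg).
#' @param h Optional named list per site of per-period H values (seasons +
#'   `year`).
#' @param polymer_percent Optional named list per site of polymer
#'   percentages used for every period when `h` is absent.
#' @param co Background concentration.
#' @param scores Hazard score table.
#' @return data.frame of 10 risk profiles.
#' @export
risk_table <- function(seasonal_ci, h = NULL, polymer_percent = NULL,
                       co = 1.79, scores = hazard_scores()) {
  rows <- list()
  for (site in names(seasonal_ci)) {
    ci <- seasonal_ci[[site]]
    if (!setequal(names(ci), mp_seasons))
      stop("seasonal_ci$", site, " must name all four seasons",
           call. = FALSE)
    for (period in c(mp_seasons, "year")) {
      ci_p <- if (period == "year") mean(ci[mp_seasons]) else ci[[period]]
      h_p <- if (!is.null(h)) h[[site]][[period]] else NULL
      pp <- if (is.null(h_p)) polymer_percent[[site]] else NULL
      rows[[length(rows) + 1L]] <-
        risk_profile(ci_p, polymer_percent = pp, h = h_p, co = co,
                     scores = scores, site = site, period = period)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# -- report rounding ledger ---------------------------------------------------
# CF -> nearest integer; displayed PLI is recomputed from the displayed CF
# (the published workflow evidently did the same: sqrt(181) = 13.45 -> 13.5)
# and shown to 1 decimal when the displayed CF < 200, else as an integer;
# Tj -> 2 decimals; RI -> nearest integer from full-precision intermediates.

#' @rdname render_table1
#' @export
report_cf <- function(cf) round(cf)

#' @rdname render_table1
#' @export
report_pli <- function(cf) {
  cfr <- report_cf(cf)
  ifelse(cfr < 200, round(sqrt(cfr), 1L), round(sqrt(cfr)))
}

#' @rdname render_table1
#' @export
report_tj <- function(tj) round(tj, 2L)

#' @rdname render_table1
#' @export
report_ri <- function(ri) round(ri)

#' Render a risk-profile table in the survey report layout
#'
#' Applies the report rounding ledger (CF to the nearest integer; PLI
#' recomputed from the reported CF, 1 decimal below CF 200 and integer
#' above; Tj to 2 decimals; RI to the nearest integer) and renders each
#' profile as `CF, PLI (label), H (level), Tj, RI (level)`. Internal values
#' stay full precision; only this layer rounds.
#'
#' @param profiles data.frame of risk profiles from [risk_profile()] /
#'   [risk_table()].
#' @return Character vector: a header line followed by one line per profile.
#'   The rounded values themselves are available via the `report_*` helpers.
#' @export
#' @examples
#' p <- risk_profile(ci = c(380, 312, 470, 354.2), h = 460,
#'                   site = "S2", period = "year")
#' render_table1(p)
render_table1 <- function(profiles) {
  header <- "site | period | CFj | PLIj | H | Tj | RI"
  if (is.null(profiles) || nrow(profiles) == 0L) return(header)
  lines <- sprintf(
    "%s | %s | %s, %s (%s), %s (level %s), %s, %s (level %s)",
    profiles$site, profiles$period,
    format(report_cf(profiles$CF), trim = TRUE),
    format(report_pli(profiles$CF), trim = TRUE),
    pli_label(profiles$pli_category),
    format(round(profiles$H, 1L), trim = TRUE), profiles$h_level,
    format(report_tj(profiles$Tj), trim = TRUE),
    format(report_ri(profiles$RI), trim = TRUE), profiles$ri_level)
  c(header, lines)
}
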