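# Reported field-survey values used as inputs: the seasonal sediment means
# the risk stack is evaluated on, the per-cell polymer hazard indices (the
# survey's own H values, whose unrounded source compositions were never
# published and which are therefore inputs when reproducing Tj/RI), and the
# annual site-level polymer percentages. These are measurements — data, not
# computation — and double as the generator's calibration targets.

#' Reported survey reference values
#'
#' The field measurements the package's examples, analysis scripts and
#' generator calibration are anchored to: seasonal sediment abundance means
#' and sds per site (items/kg dry weight), per-cell polymer hazard index
#' values (seasons + year; the annual S2 value 460 is the mean of the four
#' seasonal values), annual site-level polymer percentages, seasonal mean
#' burdens per larva and per tube for the cells with reported values, the
#' grand mean tube load per gram wet weight, larval detection rates, and
#' the background sediment concentration.
#'
#' @return Nested list of reference values.
#' @export
#' @examples
#' survey_reference()$seasonal_ci$S1
survey_reference <- function() {
  list(
    co = 1.79,
    seasonal_ci = list(
      S1 = c(winter = 345.8, spring = 251.4, summer = 385.2, autumn = 310),
      S2 = c(winter = 380, spring = 312, summer = 470, autumn = 354.2)),
    seasonal_sd = list(
      S1 = c(winter = 63, spring = 27.2, summer = 38.2, autumn = 84),
      S2 = c(winter = 54, spring = 64.7, summer = 70, autumn = 62)),
    h = list(
      S1 = list(winter = 403, spring = 463, summer = 420, autumn = 410,
                year = 416),
      S2 = list(winter = 400, spring = 519, summer = 449, autumn = 470.7,
                year = 460)),
    annual_polymer_percent = list(
      S1 = c(PES = 96, PP = 3, PE = 1),
      S2 = c(PES = 87, PE = 9, PP = 4)),
    sediment_fiber_percent = c(S1 = 96, S2 = 88),
    sediment_color_percent = c(blue = 35, red = 23, black = 22, green = 13),
    larva_burden = list(
      S1 = c(winter = 0.78, spring = 0.59, summer = 0.91),
      S2 = c(winter = 0.98, summer = 1.10, autumn = 0.79)),
    tube_burden = list(
      S1 = c(spring = 0.38, summer = 0.47),
      S2 = c(spring = 0.50, summer = 0.90)),
    tube_particles_per_g = 6.5,
    larva_detection_rate = c(S1 = 0.95, S2 = 1.00),
    sediment_larva_r = 0.96,
    sediment_tube_r = 0.87,
    headwidth_burden_r = 0.85,
    instar_burden = c(L2 = 0.52, L4 = 0.91)
  )
}
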