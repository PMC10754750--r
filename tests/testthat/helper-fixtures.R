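# In-code fixtures: every table used by the tests is generated here, none is
# stored on disk.

make_particles <- function(n, seed = 1) {
  set.seed(seed)
  voc <- mp_vocabulary()
  shape <- sample(voc$shape, n, replace = TRUE)
  length_um <- stats::runif(n, 100, 2400)
  width_um <- pmin(stats::runif(n, 10, 600), length_um * 0.4)
  data.frame(
    site = sample(voc$site, n, replace = TRUE),
    season = sample(voc$season, n, replace = TRUE),
    matrix = "sediment",
    replicate_id = paste0("rep", seq_len(n)),
    shape = shape, length_um = length_um, width_um = width_um,
    color = sample(voc$color, n, replace = TRUE),
    polymer = sample(voc$polymer, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

make_abundances <- function(counts, site = "S1", season = "winter",
                            matrix = "sediment", basis = 1,
                            basis_unit = "kg_dry_sediment") {
  data.frame(site = site, season = season, matrix = matrix,
             replicate_id = paste0("r", seq_along(counts)),
             count = counts, basis_amount = basis, basis_unit = basis_unit,
             abundance = counts / basis, stringsAsFactors = FALSE)
}

# calibration with every sediment sd forced to 0 and integer means
degenerate_calibration <- function(mean_value = 300) {
  cal <- default_calibration()
  for (site in c("S1", "S2")) for (season in names(cal$sediment_abundance[[site]]))
    cal$sediment_abundance[[site]][[season]] <- c(mean = mean_value, sd = 0)
  cal
}
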