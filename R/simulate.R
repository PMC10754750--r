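# Seeded synthetic-survey generator. Output is a pure function of
# (calibration, seed): every site x season cell draws from its own seed
# substream derived from the master seed by a fixed counter scheme
# (stream offset + cell index), so adding or reordering downstream draws in
# one cell never perturbs another.

# inverse-CDF sampler for a normal truncated to [lower, upper];
# sd = 0 degenerates to the (clipped) mean
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Ingestion selectivity weight
#'
#' Monotone non-increasing weight in \[0, 1\] over particle length: 1 up to
#' `plateau_um`, linear decay to `floor` at `cutoff_um`, constant beyond.
#' Used to reweight the sediment length distribution when larvae ingest (or
#' build tubes from) particles.
#'
#' @param length_um Numeric vector of particle lengths (micrometres).
#' @param selectivity Named vector `c(plateau_um, cutoff_um, floor)`;
#'   defaults to the curve in [default_calibration()].
#' @return Numeric vector of weights in \[0, 1\].
#' @export
selectivity_weight <- function(length_um,
                               selectivity = default_calibration()$selectivity) {
  p <- selectivity[["plateau_um"]]
  k <- selectivity[["cutoff_um"]]
  fl <- selectivity[["floor"]]
  w <- rep(fl, length(length_um))
  w[length_um <= p] <- 1
  mid <- length_um > p & length_um < k
  if (k > p) w[mid] <- 1 - (1 - fl) * (length_um[mid] - p) / (k - p)
  w
}

# stream offsets keep the generators' substreams disjoint
stream_offset <- c(sediment = 0L, larva = 100L, tube = 200L, instar = 300L,
                   weights = 400L)

cell_seed <- function(seed, stream, cell = 1L) {
  base <- abs(as.integer(seed)) %% 1000000L
  set.seed(base * 1000L + stream_offset[[stream]] + as.integer(cell))
}

survey_cells <- function() {
  data.frame(site = rep(mp_sites, each = 4L),
             season = rep(mp_seasons, 2L),
             cell = seq_len(8L), stringsAsFactors = FALSE)
}

# draw attribute columns for `n` particles of one cell
draw_particles <- function(n, matrix, site, season, replicate_id, cal,
                           selective = FALSE) {
  if (n == 0L) return(empty_particles())
  shp <- cal$shape_proportions[[matrix]][[site]]
  shape <- sample(names(shp), n, replace = TRUE, prob = shp)
  length_um <- numeric(n)
  width_um <- numeric(n)
  for (sh in unique(shape)) {
    idx <- which(shape == sh)
    ld <- cal$length_dists[[sh]]
    if (!selective) {
      length_um[idx] <- rtruncnorm(length(idx), ld[["mean"]], ld[["sd"]],
                                   ld[["lower"]], ld[["upper"]])
    } else {
      length_um[idx] <- draw_selective_lengths(length(idx), ld,
                                               cal$selectivity)
    }
    wd <- cal$width_dists[[sh]]
    w <- rtruncnorm(length(idx), wd[["mean"]], wd[["sd"]],
                    wd[["lower"]], wd[["upper"]])
    if (sh == "fiber") w <- pmin(w, length_um[idx] * 0.5)  # keep width < length
    width_um[idx] <- w
  }
  cp <- cal$color_proportions[[matrix]]
  pp <- cal$polymer_proportions[[matrix]][[site]]
  data.frame(site = site, season = season, matrix = matrix,
             replicate_id = replicate_id, shape = shape,
             length_um = length_um, width_um = width_um,
             color = sample(names(cp), n, replace = TRUE, prob = cp),
             polymer = sample(names(pp), n, replace = TRUE, prob = pp),
             stringsAsFactors = FALSE)
}

# rejection sampler: sediment length distribution reweighted by the
# selectivity curve
draw_selective_lengths <- function(n, ld, selectivity) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    prop <- rtruncnorm(m, ld[["mean"]], ld[["sd"]], ld[["lower"]],
                       ld[["upper"]])
    keep <- stats::runif(m) < selectivity_weight(prop, selectivity)
    out <- c(out, prop[keep])
  }
  out[seq_len(n)]
}

#' Generate synthetic sediment replicates and particles
#'
#' For every site x season cell, draws `n_replicates` replicate abundances
#' from a normal truncated at 0 with the calibrated cell mean and sd, turns
#' them into integer counts over `sediment_basis_kg` kg dry sediment
#' (abundance is re-derived as count / basis, so the count invariant holds
#' exactly), and, optionally, draws one particle record per counted item
#' from the sediment composition and size distributions.
#'
#' @param cal Calibration list.
#' @param seed Integer master seed.
#' @param particles Emit the particle table? Setting `FALSE` skips attribute
#'   draws when only abundances are needed.
#' @param n_replicates Override of the calibrated replicate count (e.g.
#'   inflated replication for calibration-recovery checks).
#' @return List with `abundances` (validated replicate table) and
#'   `particles` (validated particle table, or `NULL`).
#' @export
#' @examples
#' sed <- gen_sediment(default_calibration(), seed = 1)
#' head(sed$abundances)
gen_sediment <- function(cal, seed, particles = TRUE, n_replicates = NULL) {
  validate_calibration(cal)
  cells <- survey_cells()
  n <- if (is.null(n_replicates)) cal$n_sediment_replicates else n_replicates
  basis <- cal$sediment_basis_kg
  ab <- vector("list", nrow(cells))
  pt <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    site <- cells$site[i]; season <- cells$season[i]
    cell_seed(seed, "sediment", cells$cell[i])
    par <- cal$sediment_abundance[[site]][[season]]
    draw <- rtruncnorm(n, par[["mean"]], par[["sd"]], lower = 0)
    count <- round(draw * basis)
    rid <- sprintf("%s_%s_r%02d", site, season, seq_len(n))
    ab[[i]] <- data.frame(site = site, season = season, matrix = "sediment",
                          replicate_id = rid, count = count,
                          basis_amount = basis,
                          basis_unit = "kg_dry_sediment",
                          abundance = count / basis,
                          stringsAsFactors = FALSE)
    if (particles) {
      pt[[i]] <- draw_particles(sum(count), "sediment", site, season,
                                rep(rid, count), cal)
    }
  }
  list(abundances = validate_abundances(do.call(rbind, ab)),
       particles = if (particles)
         validate_particles(do.call(rbind, pt)) else NULL)
}

cell_lambda <- function(coupling, sed_mean, label) {
  lam <- coupling[["intercept"]] + coupling[["slope"]] * sed_mean
  if (lam < 0) {
    warning("negative coupling mean clipped to 0 for ", label, call. = FALSE)
    lam <- 0
  }
  lam
}

cell_sediment_means <- function(sediment_abundances) {
  sediment_abundances <- validate_abundances(sediment_abundances)
  stats::aggregate(abundance ~ site + season, sediment_abundances, mean)
}

#' Generate synthetic larvae with ingested particles
#'
#' Per site x season cell, draws `n_subsamples` x `n_per_subsample`
#' individual larvae whose particle burden is Poisson with mean
#' `intercept + slope * cell sediment abundance` (the calibrated
#' sediment-to-larva coupling; negative means are clipped to 0 with a
#' warning). Ingested particle lengths are drawn from the sediment length
#' distribution reweighted by the selectivity curve; second-instar larvae
#' ingest fibers only, with lengths from the calibrated L2 distribution.
#'
#' @param cal Calibration list.
#' @param sediment_abundances Sediment replicate table (as from
#'   [gen_sediment()]) supplying each cell's realised mean abundance.
#' @param seed Integer master seed.
#' @param particles Emit the ingested-particle table?
#' @param n_subsamples,n_per_subsample Optional overrides of the field design
#'   (5 subsamples of 10 individuals).
#' @param instar Instar of the field larvae (the field collections are
#'   fourth-instar).
#' @return List with `larvae` (one row per individual: site, season,
#'   subsample, instar, burden), `abundances` (per-subsample counts per
#'   individual) and `particles`.
#' @export
gen_larvae <- function(cal, sediment_abundances, seed, particles = TRUE,
                       n_subsamples = NULL, n_per_subsample = NULL,
                       instar = "L4") {
  validate_calibration(cal)
  instar <- match.arg(instar, mp_instars)
  sed <- cell_sediment_means(sediment_abundances)
  cells <- survey_cells()
  ns <- if (is.null(n_subsamples))
    cal$larva_design[["n_subsamples"]] else n_subsamples
  np <- if (is.null(n_per_subsample))
    cal$larva_design[["n_per_subsample"]] else n_per_subsample
  lv <- vector("list", nrow(cells))
  ab <- vector("list", nrow(cells))
  pt <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    site <- cells$site[i]; season <- cells$season[i]
    m <- sed$abundance[sed$site == site & sed$season == season]
    if (length(m) != 1L)
      stop("no sediment abundance for cell ", site, " ", season,
           call. = FALSE)
    cell_seed(seed, "larva", cells$cell[i])
    lam <- cell_lambda(cal$larva_coupling, m, paste(site, season))
    n <- ns * np
    burden <- stats::rpois(n, lam)
    sub <- rep(seq_len(ns), each = np)
    rid <- sprintf("%s_%s_sub%d", site, season, sub)
    lv[[i]] <- data.frame(site = site, season = season, matrix = "larva",
                          replicate_id = rid, instar = instar,
                          burden = burden, stringsAsFactors = FALSE)
    cnt <- tapply(burden, factor(sub, levels = seq_len(ns)), sum)
    ab[[i]] <- data.frame(site = site, season = season, matrix = "larva",
                          replicate_id = sprintf("%s_%s_sub%d", site, season,
                                                 seq_len(ns)),
                          count = as.integer(cnt), basis_amount = np,
                          basis_unit = "individual",
                          abundance = as.integer(cnt) / np,
                          stringsAsFactors = FALSE)
    if (particles) {
      pt[[i]] <- draw_biota_particles(burden, "larva", site, season, rid,
                                      cal, instar)
    }
  }
  list(larvae = do.call(rbind, lv),
       abundances = validate_abundances(do.call(rbind, ab)),
       particles = if (particles)
         validate_particles(do.call(rbind, pt)) else NULL)
}

# particles carried by larvae or tubes: composition from the matrix's
# vectors, lengths selectivity-reweighted from sediment (L2: fibers only,
# calibrated short-length distribution)
draw_biota_particles <- function(burden, matrix, site, season, rid, cal,
                                 instar = "L4") {
  n <- sum(burden)
  if (n == 0L) return(empty_particles())
  rep_id <- rep(rid, burden)
  if (matrix == "larva" && instar == "L2") {
    ld <- cal$instar$L2$fiber_length
    length_um <- rtruncnorm(n, ld[["mean"]], ld[["sd"]], ld[["lower"]],
                            ld[["upper"]])
    wd <- cal$width_dists$fiber
    width_um <- pmin(rtruncnorm(n, wd[["mean"]], wd[["sd"]], wd[["lower"]],
                                wd[["upper"]]), length_um * 0.5)
    cp <- cal$color_proportions[[matrix]]
    pp <- cal$polymer_proportions[[matrix]][[site]]
    return(data.frame(site = site, season = season, matrix = matrix,
                      replicate_id = rep_id, shape = "fiber",
                      length_um = length_um, width_um = width_um,
                      color = sample(names(cp), n, TRUE, cp),
                      polymer = sample(names(pp), n, TRUE, pp),
                      stringsAsFactors = FALSE))
  }
  draw_particles(n, matrix, site, season, rep_id, cal, selective = TRUE)
}

#' Generate synthetic chironomid tubes with incorporated particles
#'
#' Per site x season cell, draws `n_samples` samples of
#' `n_tubes_per_sample` tubes; per-tube burdens are Poisson with mean from
#' the calibrated sediment-to-tube coupling, and each sample's wet weight is
#' drawn so per-gram loads can be reported. Particle attributes use the
#' tube composition vectors with selectivity-reweighted lengths.
#'
#' @inheritParams gen_larvae
#' @param n_samples,n_tubes_per_sample Optional design overrides (field
#'   design: 5 samples of 10 tubes).
#' @return List with `tubes` (one row per tube), `abundances` (per-tube rows
#'   with `basis_unit = "tube"` plus per-sample rows with
#'   `basis_unit = "g_wet_tube"`) and `particles`.
#' @export
gen_tubes <- function(cal, sediment_abundances, seed, particles = TRUE,
                      n_samples = NULL, n_tubes_per_sample = NULL) {
  validate_calibration(cal)
  sed <- cell_sediment_means(sediment_abundances)
  cells <- survey_cells()
  ns <- if (is.null(n_samples)) cal$tube_design[["n_samples"]] else n_samples
  nt <- if (is.null(n_tubes_per_sample))
    cal$tube_design[["n_tubes_per_sample"]] else n_tubes_per_sample
  tb <- vector("list", nrow(cells))
  ab <- vector("list", nrow(cells))
  pt <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    site <- cells$site[i]; season <- cells$season[i]
    m <- sed$abundance[sed$site == site & sed$season == season]
    if (length(m) != 1L)
      stop("no sediment abundance for cell ", site, " ", season,
           call. = FALSE)
    cell_seed(seed, "tube", cells$cell[i])
    lam <- cell_lambda(cal$tube_coupling, m, paste(site, season))
    n <- ns * nt
    burden <- stats::rpois(n, lam)
    samp <- rep(seq_len(ns), each = nt)
    wpar <- cal$tube_sample_weight_g
    wt <- rtruncnorm(ns, wpar[["mean"]], wpar[["sd"]], lower = 0.2)
    rid_tube <- sprintf("%s_%s_s%d_t%d", site, season, samp,
                        rep(seq_len(nt), ns))
    rid_samp <- sprintf("%s_%s_s%d", site, season, samp)
    tb[[i]] <- data.frame(site = site, season = season, matrix = "tube",
                          replicate_id = rid_samp, tube_id = rid_tube,
                          burden = burden, stringsAsFactors = FALSE)
    per_tube <- data.frame(site = site, season = season, matrix = "tube",
                           replicate_id = rid_tube, count = burden,
                           basis_amount = 1, basis_unit = "tube",
                           abundance = burden, stringsAsFactors = FALSE)
    cnt <- as.integer(tapply(burden, factor(samp, levels = seq_len(ns)), sum))
    per_g <- data.frame(site = site, season = season, matrix = "tube",
                        replicate_id = sprintf("%s_%s_s%d", site, season,
                                               seq_len(ns)),
                        count = cnt, basis_amount = wt,
                        basis_unit = "g_wet_tube", abundance = cnt / wt,
                        stringsAsFactors = FALSE)
    ab[[i]] <- rbind(per_tube, per_g)
    if (particles) {
      pt[[i]] <- draw_biota_particles(burden, "tube", site, season,
                                      rid_tube, cal)
    }
  }
  list(tubes = do.call(rbind, tb),
       abundances = validate_abundances(do.call(rbind, ab)),
       particles = if (particles)
         validate_particles(do.call(rbind, pt)) else NULL)
}

#' Generate the instar-comparison experiment
#'
#' Emulates the summer collection of second- (L2) and fourth-instar (L4)
#' larvae: `n_replicates` replicates of `n_per_replicate` individuals per
#' instar, morphometrics drawn from the calibrated per-instar normal
#' distributions (truncated at 0), and per-individual burdens Poisson with
#' mean proportional to the individual's head capsule width (scaled so the
#' instar mean equals the calibrated burden mean). L2 individuals carry
#' fibers only, below the calibrated L2 length cap; L4 individuals carry the
#' calibrated fiber/fragment mixture.
#'
#' @param cal Calibration list.
#' @param seed Integer master seed.
#' @param n_replicates,n_per_replicate Optional design overrides (field
#'   design: 10 replicates of 10 individuals per instar).
#' @return List with `larvae` (one row per individual with all five
#'   morphometrics and the burden) and `particles`.
#' @export
gen_instar_experiment <- function(cal, seed, n_replicates = NULL,
                                  n_per_replicate = NULL) {
  validate_calibration(cal)
  nr <- if (is.null(n_replicates))
    cal$instar_design[["n_replicates"]] else n_replicates
  np <- if (is.null(n_per_replicate))
    cal$instar_design[["n_per_replicate"]] else n_per_replicate
  out <- vector("list", 2L)
  pts <- vector("list", 2L)
  morpho <- c("weight_mg", "body_length_mm", "head_capsule_width_mm",
              "head_capsule_length_mm", "mentum_width_mm")
  for (k in seq_along(mp_instars)) {
    ins <- mp_instars[k]
    ip <- cal$instar[[ins]]
    cell_seed(seed, "instar", k)
    n <- nr * np
    df <- data.frame(site = "S2", season = "summer", matrix = "larva",
                     replicate_id = sprintf("instar_%s_rep%02d", ins,
                                            rep(seq_len(nr), each = np)),
                     instar = ins, stringsAsFactors = FALSE)
    for (mcol in morpho) {
      p <- ip[[mcol]]
      df[[mcol]] <- rtruncnorm(n, p[["mean"]], p[["sd"]], lower = 1e-6)
    }
    hw <- df$head_capsule_width_mm
    lam <- pmax(0, ip$burden_mean * hw /
                  ip$head_capsule_width_mm[["mean"]])
    df$burden <- stats::rpois(n, lam)
    out[[k]] <- df
    pts[[k]] <- draw_instar_particles(df$burden, ins, df$replicate_id, cal)
  }
  list(larvae = do.call(rbind, out),
       particles = validate_particles(do.call(rbind, pts)))
}

draw_instar_particles <- function(burden, instar, rid, cal) {
  n <- sum(burden)
  if (n == 0L) return(empty_particles())
  ip <- cal$instar[[instar]]
  rep_id <- rep(rid, burden)
  shape <- ifelse(stats::runif(n) < ip$fragment_share, "fragment", "fiber")
  length_um <- numeric(n)
  for (sh in unique(shape)) {
    idx <- which(shape == sh)
    ld <- if (sh == "fiber") ip$fiber_length else ip$fragment_length
    length_um[idx] <- rtruncnorm(length(idx), ld[["mean"]], ld[["sd"]],
                                 ld[["lower"]], ld[["upper"]])
  }
  wd <- cal$width_dists
  width_um <- numeric(n)
  for (sh in unique(shape)) {
    idx <- which(shape == sh)
    w <- rtruncnorm(length(idx), wd[[sh]][["mean"]], wd[[sh]][["sd"]],
                    wd[[sh]][["lower"]], wd[[sh]][["upper"]])
    if (sh == "fiber") w <- pmin(w, length_um[idx] * 0.5)
    width_um[idx] <- w
  }
  cp <- cal$color_proportions$larva
  pp <- cal$polymer_proportions$larva$S2
  data.frame(site = "S2", season = "summer", matrix = "larva",
             replicate_id = rep_id, shape = shape, length_um = length_um,
             width_um = width_um,
             color = sample(names(cp), n, TRUE, cp),
             polymer = sample(names(pp), n, TRUE, pp),
             stringsAsFactors = FALSE)
}
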