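#!/usr/bin/env Rscript
# Stage 4: the survey's inferential comparisons on the simulated data —
# season effect on sediment abundance per site (one-way ANOVA), 501-1000 um
# size-class enrichment in larvae vs host sediment (chi-square), sediment ->
# larva and sediment -> tube coupling (Pearson correlation + regression),
# and the L2 vs L4 instar contrast.

suppressPackageStartupMessages(library(mpsurvey))

out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

abundances <- read_abundance_table("results/survey/abundances.csv")
particles <- read_particle_table("results/survey/particles.csv")
larvae <- utils::read.csv("results/survey/larvae.csv")
tubes <- utils::read.csv("results/survey/tubes.csv")
instar <- utils::read.csv("results/survey/instar_larvae.csv")

rows <- list()
keep <- function(label, tr, extra = NA_real_) {
  rows[[length(rows) + 1L]] <<- data.frame(
    test = label, statistic = tr$statistic,
    df = paste(tr$df, collapse = ","), p_value = tr$p_value,
    estimate = extra, stringsAsFactors = FALSE)
}

sed_ab <- abundances[abundances$matrix == "sediment", ]
for (site in c("S1", "S2")) {
  g <- sed_ab[sed_ab$site == site, ]
  tr <- oneway_anova(split(g$abundance, g$season))
  keep(paste0("season_anova_", site), tr)
  message(sprintf("season ANOVA %s: F = %.1f, p = %.2g", site,
                  tr$statistic, tr$p_value))
}

inout <- function(p) {
  b <- bin_lengths(p)
  k <- b$size_class == "501-1000"
  c(inside = sum(b$count[k]), outside = sum(b$count[!k]))
}
sed_pt <- particles[particles$matrix == "sediment", ]
lar_pt <- particles[particles$matrix == "larva", ]
for (site in c("S1", "S2")) {
  tr <- sizeclass_chisq(inout(sed_pt[sed_pt$site == site, ]),
                        inout(lar_pt[lar_pt$site == site, ]))
  keep(paste0("sizeclass_enrichment_", site), tr)
  message(sprintf("501-1000 um enrichment %s: chi2 = %.1f, p = %.2g", site,
                  tr$statistic, tr$p_value))
}

cells <- stats::aggregate(abundance ~ site + season, sed_ab, mean)
for (what in c("larva", "tube")) {
  b <- if (what == "larva") larvae else tubes
  bm <- stats::aggregate(burden ~ site + season, b, mean)
  m <- merge(cells, bm, by = c("site", "season"))
  tr <- pearson_r(m$abundance, m$burden)
  keep(paste0("sediment_", what, "_cor"), tr, tr$estimate[["r"]])
  fit <- univariate_regression(m$abundance, m$burden)
  keep(paste0("sediment_", what, "_fit"), fit, fit$estimate[["slope"]])
  message(sprintf("sediment -> %s: r = %.2f (p = %.2g), slope = %.2g", what,
                  tr$estimate[["r"]], tr$p_value, fit$estimate[["slope"]]))
}

cmp <- compare_instars(instar[instar$instar == "L2", ],
                       instar[instar$instar == "L4", ])
keep("instar_burden_anova", cmp$burden_test)
keep("headwidth_burden_cor", cmp$headwidth_cor,
     cmp$headwidth_cor$estimate[["r"]])
utils::write.csv(cmp$summary, file.path(out, "instar_summary.csv"),
                 row.names = FALSE)
bs <- cmp$summary[cmp$summary$variable == "burden", ]
message(sprintf(
  "instar burdens: L2 %.2f +/- %.2f vs L4 %.2f +/- %.2f (p = %.2g)",
  bs$mean[1], bs$sd[1], bs$mean[2], bs$sd[2], cmp$burden_test$p_value))

utils::write.csv(do.call(rbind, rows), file.path(out, "test_results.csv"),
                 row.names = FALSE)
message("test results written under ", out)
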