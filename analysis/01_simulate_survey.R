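#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-site, four-season survey at the
# default calibration and write the raw tables every later stage consumes.
# The calibration's defaults are the surveyed field conditions (seasonal
# sediment abundances, compositions, size distributions, biota couplings);
# see the methods vignette.

suppressPackageStartupMessages(library(mpsurvey))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1L) as.integer(args[[1L]]) else 1L
out <- "results/survey"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cal <- default_calibration()
message("simulating survey at seed ", seed)

sed <- gen_sediment(cal, seed = seed)
larv <- gen_larvae(cal, sed$abundances, seed = seed)
tube <- gen_tubes(cal, sed$abundances, seed = seed)
instar <- gen_instar_experiment(cal, seed = seed)

write_particle_table(rbind(sed$particles, larv$particles, tube$particles),
                     file.path(out, "particles.csv"))
write_abundance_table(rbind(sed$abundances, larv$abundances,
                            tube$abundances),
                      file.path(out, "abundances.csv"))
utils::write.csv(larv$larvae, file.path(out, "larvae.csv"),
                 row.names = FALSE)
utils::write.csv(tube$tubes, file.path(out, "tubes.csv"), row.names = FALSE)
utils::write.csv(instar$larvae, file.path(out, "instar_larvae.csv"),
                 row.names = FALSE)
write_particle_table(instar$particles,
                     file.path(out, "instar_particles.csv"))
writeLines(as.character(seed), file.path(out, "seed.txt"))

message("sediment replicates: ", nrow(sed$abundances),
        "; particles: ", nrow(sed$particles))
message("larvae: ", nrow(larv$larvae), " carrying ",
        sum(larv$larvae$burden), " particles")
message("tubes: ", nrow(tube$tubes), " carrying ",
        sum(tube$tubes$burden), " particles")
message("tables written under ", out)
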