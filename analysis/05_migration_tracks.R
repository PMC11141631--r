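#!/usr/bin/env Rscript
# Migration statistics on the simulated growth movie: cell density and
# aligned time (peak at t_a = 36 h), per-step speeds and directions,
# normalized migration within the director-flanking bins, and the
# speed-versus-density profile on a 10 cells/mm^2 lattice.

suppressPackageStartupMessages(library(cellnematics))
dir.create("results", showWarnings = FALSE)

ts <- read_tracks_csv("results/simulated/tracks_truth.csv")
dens <- cell_density(ts)
al <- align_time_series(dens, target_peak = 36)
write.csv(al, "results/density_aligned.csv", row.names = FALSE)
message(sprintf("density: peak %.0f cells/mm^2 at t_a = %.0f h (offset %+.0f h)",
                max(al$density_smooth), al$t_a[which.max(al$density_smooth)],
                attr(al, "offset_h")))

ms <- migration_stats(ts)
write.csv(ms$steps, "results/migration_steps.csv", row.names = FALSE)
ratio <- normalized_migration_series(ms$steps, director = 0, bin_width = 20)
ratio$t_a <- ratio$t_h + attr(al, "offset_h")
write.csv(ratio, "results/normalized_migration.csv", row.names = FALSE)
message(sprintf("normalized migration along the director: mean %.2f (1 = isotropic)",
                mean(ratio$ratio, na.rm = TRUE)))

# speed vs density, averaged over interpolated replicates (split the field
# into two replicate halves by track id parity)
halves <- lapply(0:1, function(p) {
  ids <- unique(ts$track_id)[unique(ts$track_id) %% 2 == p]
  sub <- ms$steps[ms$steps$track_id %in% ids, ]
  spd <- tapply(sub$speed_umh, sub$frame, mean)
  data.frame(density = dens$density[as.integer(names(spd))],
             value = as.numeric(spd))
})
prof <- density_profile_average(halves, increment = 10, min_n = 2)
write.csv(prof, "results/speed_vs_density.csv", row.names = FALSE)
message(sprintf("speed falls from %.1f to %.1f um/h as density rises %0.f -> %0.f cells/mm^2",
                prof$mean_value[1], tail(prof$mean_value, 1),
                prof$density[1], tail(prof$density, 1)))
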