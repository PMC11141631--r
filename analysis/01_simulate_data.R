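#!/usr/bin/env Rscript
# Generate the synthetic data set the rest of the analysis runs on: a
# filament-textured image whose local orientation follows a director field
# with two +/-1/2 defects, a speckle image pair displaced by a known flow,
# and a nuclei movie from a biased persistent random walk with logistic
# growth. Everything is seeded; later scripts regenerate nothing.

suppressPackageStartupMessages(library(cellnematics))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

# director field with a +1/2 / -1/2 pair, sampled every 5 px over 600 px
truth <- data.frame(x = c(40.5, 80.5), y = c(60.5, 60.5),
                    charge = c(0.5, -0.5))
fld <- gen_defect_field(c(120, 120), truth, grid_size = 5)
write_field_csv(fld, "results/simulated/defect_field.csv")
write.csv(truth, "results/simulated/defect_truth.csv", row.names = FALSE)

img <- gen_filament_image(fld, filament_length = 12,
                          filament_density = 0.035, seed = 7)
write_pgm(img, "results/simulated/actin_texture.pgm")
message(sprintf("actin-like texture: %d x %d px, 2 planted defects",
                nrow(img), ncol(img)))

# speckle pair displaced by a known constant flow (for PIV)
spk <- gen_speckle_image(256, seed = 21)
pair <- gen_displaced_pair(spk, c(2.5, -1.25))
write_pgm(pair$a, "results/simulated/piv_frame_a.pgm")
write_pgm(pair$b, "results/simulated/piv_frame_b.pgm")
message("speckle pair displaced by (2.50, -1.25) px")

# growth-and-migration movie: 42 frames every 3 h, carrying capacity
# 4000 cells/mm^2, no directional bias
g <- gen_growth_tracks(n_frames = 42, frame_interval = 3,
                       field_size_px = 250, capacity = 4000, rate = 0.05,
                       bias = 0, seed = 3, render = FALSE)
write_tracks_csv(g$tracks, "results/simulated/tracks_truth.csv")
write.csv(g$density, "results/simulated/density_truth.csv", row.names = FALSE)
message(sprintf("growth movie: %d tracks, %d frames, final density %.0f cells/mm^2",
                length(unique(g$tracks$track_id)), max(g$tracks$frame),
                tail(g$density$density, 1)))
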