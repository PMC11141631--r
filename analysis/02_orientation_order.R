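#!/usr/bin/env Rscript
# Extract the orientation field of the simulated actin texture with the
# structure tensor (sigma 10 px, grid 5 px, 25% coherency gate), and compute
# the order statistics: global S, the local 4x4-window order map, spatial
# disorder, and the 20-degree orientation frequency distribution.

suppressPackageStartupMessages(library(cellnematics))
dir.create("results", showWarnings = FALSE)

img <- read_pgm("results/simulated/actin_texture.pgm")
pm <- structure_tensor(img, sigma_window = 10)
fld <- sample_grid(pm, 5, min_coherency = 0.25, pixel_size = 1)
write_field_csv(fld, "results/orientation_field.csv")

om <- local_order_map(fld, window = 4)
dis <- spatial_disorder(om, threshold = 0.5)
write_pgm(order_map_gray(om) / 255, "results/local_order_heatmap.pgm")

h <- orientation_histogram(pm, bin_width = 20, min_coherency = 0.25)
write.csv(as.data.frame(h), "results/orientation_histogram.csv",
          row.names = FALSE)

summary <- data.frame(S_global = om$S_global, spatial_disorder_pct = dis,
                      n_vectors = sum(fld$mask))
write.csv(summary, "results/order_summary.csv", row.names = FALSE)
message(sprintf(
  "S = %.3f over %d vectors; %.1f%% of local windows below S = 0.5 (the coherency gate masks the singular defect cores)",
  om$S_global, sum(fld$mask), dis))
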