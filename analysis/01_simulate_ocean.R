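#!/usr/bin/env Rscript
# Stage 1: build the synthetic study domain.
#
# Generates the default synthetic ocean — a 40 x 80 pixel, 10-year record of
# 8-day composites with planted nutricline structure, hemispheric seasonal
# cycles, one ENSO-like interannual mode, per-pixel trends, and 5%
# multiplicative noise — plus cruise-track biomarker samples, a gene-coverage
# table, and monthly climate-index series.  Writes the point artifacts and a
# coarse copy of the scene under results/.

suppressPackageStartupMessages(library(thetaprime))
dir.create("results", showWarnings = FALSE)
seed <- 1L

scene <- generate_scene(scene_spec(seed = seed))
cat(sprintf("scene: %d x %d pixels, %d composites (%.1f years)\n",
            length(scene$lat), length(scene$lon), length(scene$time_days),
            max(scene$time_days) / 365.25))
cat(sprintf("planted variance budget: %.1f%% seasonal, %.1f%% interannual\n",
            100 * scene$meta$planted_seasonal_share,
            100 * scene$meta$planted_interannual_share))

samples <- sample_biomarkers(scene, n = 300, seed = seed + 1)
genes <- generate_gene_table(samples, n_genes = 30, seed = seed + 2)
climate <- generate_climate_index(scene, n_distractors = 1, seed = seed + 3)

write.csv(samples, "results/biomarker_samples.csv", row.names = FALSE)
write.csv(data.frame(gene = rownames(genes$coverage),
                     effect = genes$effects, genes$coverage),
          "results/gene_coverage.csv", row.names = FALSE)
write.csv(climate, "results/climate_indices.csv", row.names = FALSE)
# keep a desk-sized copy of the grid for inspection
write_scene(regrid_downscale(scene, factor_space = 4, factor_time = 6),
            "results/scene_coarse.scene.json")

cat(sprintf("wrote %d biomarker samples along cruise tracks\n",
            nrow(samples)))
cat(sprintf("wrote %d-gene coverage table (%d+, %d-, %d null effects)\n",
            nrow(genes$coverage), sum(genes$effects > 0),
            sum(genes$effects < 0), sum(genes$effects == 0)))
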