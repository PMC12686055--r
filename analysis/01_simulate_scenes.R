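#!/usr/bin/env Rscript
# Generates the synthetic scenes used throughout the analysis: puncta images
# on flat and gradient backgrounds, a planted-correlation channel pair, a
# membrane-enriched dendrite cross-section, and a protrusion table. Writes
# images (TIFF/PNG) and ground truth under results/scenes/.

library(brightclust)
library(jsonlite)

out_dir <- "results/scenes"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

flat <- make_puncta_image(scene_params(n_puncta = 12L, punctum_peak = 0.8), seed)
grad <- make_puncta_image(scene_params(n_puncta = 12L, punctum_peak = 0.8,
                                       background = "linear-gradient"), seed)
write_image(file.path(out_dir, "puncta_flat.tif"), flat$image)
write_image(file.path(out_dir, "puncta_gradient.tif"), grad$image)

sk <- matrix(FALSE, 256, 256); sk[128, ] <- TRUE
write_image(file.path(out_dir, "skeleton.png"), sk)
roi <- grow_skeleton(skeleton_curve(sk, calibration(5 / 95)), radius_px = 95)
write_image(file.path(out_dir, "observation_path.png"), roi$mask)

memb <- make_membrane_scene(enrichment = 1.5, noise_sd = 0.01, seed = seed)
write_image(file.path(out_dir, "membrane_plane.tif"), memb$plane)

prot <- make_protrusion_table(10, seed = seed, n_reject = 5)
write.csv(prot, file.path(out_dir, "protrusions.csv"), row.names = FALSE)

truth <- list(
  seed = seed,
  puncta_flat = list(n = nrow(flat$truth$puncta_centers),
                     centers = unname(apply(flat$truth$puncta_centers, 1, as.list))),
  puncta_gradient = list(n = nrow(grad$truth$puncta_centers)),
  membrane_enrichment = memb$truth$enrichment,
  dendrite_length_um = roi$length_um
)
write_json(truth, file.path(out_dir, "truth.json"), auto_unbox = TRUE)

cat(sprintf("wrote %d puncta scenes, skeleton + %d-px-wide observation path,\n",
            2, 2 * roi$grow_radius_px + 1))
cat(sprintf("membrane scene (enrichment %.2f) and %d protrusions to %s\n",
            memb$truth$enrichment, nrow(prot), out_dir))
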