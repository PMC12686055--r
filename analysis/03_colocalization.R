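#!/usr/bin/env Rscript
# Colocalization and intensity-ratio analyses on synthetic scenes: PCC
# recovery across planted correlations, membrane/diffuse line ratios, and
# the expressing/non-expressing intensity ratio. Writes
# results/coloc_recovery.csv and results/ratio_summary.json.

library(brightclust)
library(jsonlite)

dir.create("results", showWarnings = FALSE)

rows <- list()
for (rho in c(-0.8, -0.3, 0, 0.3, 0.5, 0.8, 0.9)) {
  r <- vapply(1:100, function(s) {
    p <- make_coloc_pair(2000, rho, seed = 500 + s)
    pcc(p$chanA, p$chanB)$pcc
  }, numeric(1))
  rows[[length(rows) + 1L]] <- data.frame(
    rho = rho, mean_pcc = mean(r), sem = sd(r) / 10, n_seeds = 100
  )
}
coloc <- do.call(rbind, rows)
write.csv(coloc, "results/coloc_recovery.csv", row.names = FALSE)
cat("planted vs recovered correlation (100 seeds each):\n")
print(coloc, row.names = FALSE, digits = 4)

ratios <- vapply(c(1, 1.5, 2), function(e) {
  sc <- make_membrane_scene(e, noise_sd = 0.01, seed = 600)
  membrane_diffuse_ratio(sc$plane, sc$truth$membrane_lines,
                         sc$truth$center_line)$ratio
}, numeric(1))
cat("\nmembrane/diffuse ratios for planted enrichments 1, 1.5, 2:\n")
print(round(ratios, 4))

# phalloidin-style expressing vs non-expressing comparison: planted 30%
# dimmer signal in the expressing ROI
img <- withr::with_seed(700, matrix(runif(256 * 256, 0.4, 0.6), 256, 256))
roi_e <- matrix(FALSE, 256, 256); roi_e[, 1:100] <- TRUE
roi_n <- matrix(FALSE, 256, 256); roi_n[, 157:256] <- TRUE
img[roi_e] <- img[roi_e] * 0.7
er <- expression_ratio(img, roi_e, roi_n)
cat(sprintf("\nexpression ratio with a planted 30%% dimmer ROI: %.4f\n", er))

write_json(list(membrane_ratios = data.frame(enrichment = c(1, 1.5, 2),
                                             ratio = ratios),
                expression_ratio = er),
           "results/ratio_summary.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/coloc_recovery.csv and results/ratio_summary.json\n")
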