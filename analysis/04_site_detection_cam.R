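#!/usr/bin/env Rscript
# How much site identity leaks from the pixels: train a multiclass CNN to
# predict the hospital site directly, repeat within site_a for the
# acquiring department (inverted-color portable ED scanner vs inpatient),
# and audit the evidence with subregion activation maps: how many grid
# cells individually call the site decisively, and where the influence
# heatmap localizes.

library(radshift)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

det <- run_site_detection(
  generator_config(n_patients_per_site = 200, image_size = 32,
                   lateral_fraction = 0, seed = seed),
  default_site_profiles(), seed = seed,
  target_site = "site_b", cam_sample = 100, channels = c(8L, 16L))

cat("Held-out site identification (confounds on):\n")
print(det$site_accuracy, digits = 4)
if (!is.null(det$department_accuracy)) {
  cat("\nDepartment identification within site_a:\n")
  print(det$department_accuracy, digits = 4)
}
cat("\nActivation-map audit of the site_b test images:\n")
print(det$decisive)
cat(sprintf("influence heatmap argmax falls on the corner-token cells in %.0f%% of images\n",
            100 * det$localization))
cat("(with the full acquisition signature the strongest per-cell evidence can be a\n",
    "global cue such as the detector-noise texture rather than the token itself;\n",
    "on a token-only two-site design the heatmap localizes on the token, which is\n",
    "what the test suite checks)\n", sep = "")

# null control: identical acquisition and prevalence across sites
det0 <- run_site_detection(
  generator_config(n_patients_per_site = 150, image_size = 32,
                   lateral_fraction = 0, seed = seed),
  default_site_profiles(confounds = FALSE, equal_prevalence = TRUE),
  seed = seed, cam_sample = 20, channels = c(8L, 16L),
  department_site = NULL)
cat(sprintf("\nWith all acquisition artifacts removed, overall accuracy drops to %.3f (majority rate %.3f)\n",
            det0$overall_accuracy,
            max(det0$site_accuracy$n) / sum(det0$site_accuracy$n)))

write.csv(det$site_accuracy, "results/site_detection_accuracy.csv",
          row.names = FALSE)
write_heatmap(det$heatmap, path_png = "results/site_b_influence_heatmap.png",
              path_csv = "results/site_b_influence_heatmap.csv")
write.csv(data.frame(image = seq_along(det$decisive$counts),
                     decisive_cells = det$decisive$counts),
          "results/decisive_subregions.csv", row.names = FALSE)
cat("\nwrote results/site_detection_accuracy.csv, heatmap PNG/CSV, decisive counts\n")
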