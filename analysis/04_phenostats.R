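#!/usr/bin/env Rscript

# Step 4: downstream quantification statistics.
#
# The computable end-points of the angiogenesis phenotyping: the exact test
# on the ectopic-vessel phenotype table, dose-equivalence conversions, the
# caliper tumor-volume formula, the scratch-wound closure ratio, and
# thresholded vessel-staining area on a synthetic intensity grid. Results go
# to results/phenostats.json.

suppressMessages(library(chemoconsensus))

dir.create("results", showWarnings = FALSE)
out <- list()

# 6 of 8 control animals developed ectopic vessels vs 0 of 9 treated animals
p <- fisher_exact_2x2(6, 2, 0, 9)
cat(sprintf("ectopic-vessel phenotype, exact test: p = %.5f (%.2g)\n",
            p, p))
out$fisher <- list(table = c(6, 2, 0, 9), p_two_sided = p)

# dose equivalences for thiabendazole (201.25 g/mol)
mouse <- dose_convert(1, 20)       # 1 mg daily, 20 g mouse
human <- dose_convert(3000, 60000) # 3 g daily, 60 kg patient
cat(sprintf("mouse dose: %.0f mg/kg = %.0f uM-equivalent\n",
            mouse$mg_per_kg, mouse$uM_equivalent))
cat(sprintf("human maximum dose: %.0f mg/kg\n", human$mg_per_kg))
out$dose <- list(mouse = mouse, human = human)

# caliper tumor volumes for an example treated/control pair (mm)
vol_ctrl <- tumor_volume(width = 9.5, length = 12.0)
vol_tbz <- tumor_volume(width = 6.0, length = 8.5)
cat(sprintf("tumor volumes: control %.0f mm^3 vs treated %.0f mm^3\n",
            vol_ctrl, vol_tbz))
out$tumor_volume_mm3 <- list(control = vol_ctrl, treated = vol_tbz)

# wound closure after 15 h for an example area pair
closure <- wound_closure_ratio(area_0 = 100, area_t = 40)
cat(sprintf("wound closure ratio: %.2f\n", closure))
out$wound_closure <- closure

# vessel staining area above threshold on a synthetic intensity grid
set.seed(1)
img <- matrix(rexp(400, rate = 1 / 20), 20, 20)
va <- vessel_area_fraction(img, threshold = 40)
cat(sprintf("vessel area above threshold: %.1f%% (%d/%d pixels)\n",
            100 * va$fraction, va$n_above, va$n_pixels))
out$vessel_area <- va

jsonlite::write_json(out, "results/phenostats.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
cat("wrote results/phenostats.json\n")
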