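#!/usr/bin/env Rscript
# Step 1 — simulate one continuous recording session.
#
# Generates a 210-s, 32-channel session on the 4x8 grid at 500 Hz: a
# pseudo-periodic 3-D reach trajectory (~5 s cycles) and ECoG in which ten
# electrodes carry band-envelope coupling to the kinematics (gamma3 > gamma4
# > delta), on top of broadband and common-mode noise. The later steps
# (02-04) read this session from disk, so the whole analysis can also be
# rerun against any dataset written in the same container format.

library(ecogpls)

out_dir <- "scratch/session01"
seed <- 1L

ds <- make_dataset(list(duration_s = 210, seed = seed))
print(ds)
write_dataset(ds, out_dir)

cat("informative channels:", ds$truth$informative_channels, "\n")
cat("band weights:", paste(names(ds$truth$band_weights),
                           ds$truth$band_weights, sep = "=", collapse = " "), "\n")
cat("wrote dataset container to", out_dir, "\n")
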