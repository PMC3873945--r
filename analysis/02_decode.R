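#!/usr/bin/env Rscript
# Step 2 — decode the hand trajectory from the simulated session.
#
# Preprocesses the recording into the nine-band envelope feature tensor,
# lag-embeds it (20 lags x 30 ms), splits 150 s train / 60 s test, selects
# the number of latent variables by ten-fold cross-validated PRESS, fits
# the PLS decoder and evaluates held-out R-squared per axis. Writes the
# CV curve and the global scores under results/.

library(ecogpls)

ds <- read_dataset("scratch/session01")
cfg <- decoding_config(train_s = 150, test_s = 50)

ctx <- prepare_decoding(ds, cfg)
curve <- cross_validate(ctx$train$X, ctx$train$Y,
                        max_latent = cfg$max_latent, k_folds = cfg$k_folds)
n_latent <- select_n_latent(curve, cfg$plateau_tol, cfg$latent_cap)
fit <- decode_full(ctx, n_latent)

cat(sprintf("selected %d latent variables (PRESS plateau; baseline PRESS %.0f, min %.0f)\n",
            n_latent, attr(curve, "press0"), min(curve$press)))
cat(sprintf("held-out R2: x=%.4f y=%.4f z=%.4f mean=%.4f\n",
            fit$r2$per_axis[["x"]], fit$r2$per_axis[["y"]],
            fit$r2$per_axis[["z"]], fit$r2$mean))

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(curve), "results/cv_curve.csv", row.names = FALSE)
write.csv(data.frame(axis = c("x", "y", "z", "mean"),
                     r2 = c(fit$r2$per_axis, fit$r2$mean),
                     n_latent = n_latent),
          "results/global_r2.csv", row.names = FALSE)
cat("wrote results/cv_curve.csv and results/global_r2.csv\n")
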