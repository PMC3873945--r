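#' Write / read a dataset container
#'
#' A dataset is stored as a directory of paired CSV matrices plus a JSON
#' sidecar: `signals.csv` (samples x channels, one column per channel id),
#' `trajectory.csv` (samples x x,y,z), `layout.csv` (channel,row,col) and
#' `meta.json` (sampling rate, band set, ground truth, seed, generator
#' settings). Numeric round-trip is lossless to better than 1e-12 relative.
#' Files are written to a temporary name and renamed into place.
#'
#' @param dataset a `synthetic_dataset` from [make_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir` invisibly (`write_dataset`); a `synthetic_dataset`
#'   (`read_dataset`).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- as.data.frame(t(dataset$recording$data))
  names(sig) <- paste0("ch", layout_channels(dataset$recording$layout))
  atomic_write(file.path(dir, "signals.csv"), function(p)
    data.table::fwrite(sig, p))
  traj <- as.data.frame(t(dataset$trajectory$data))
  names(traj) <- c("x", "y", "z")
  atomic_write(file.path(dir, "trajectory.csv"), function(p)
    data.table::fwrite(traj, p))
  atomic_write(file.path(dir, "layout.csv"), function(p)
    data.table::fwrite(dataset$recording$layout$table, p))
  cfg <- dataset$config
  meta <- list(fs = dataset$recording$fs,
               n_rows = dataset$recording$layout$n_rows,
               n_cols = dataset$recording$layout$n_cols,
               seed = dataset$seed,
               truth = serialize_truth(dataset$truth),
               bands = as.data.frame(dataset$bands),
               generator = cfg[setdiff(names(cfg), c("bands", "truth"))])
  atomic_write(file.path(dir, "meta.json"), function(p)
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(dir)
}

# band_weights must stay a named JSON object even at length 1 (auto_unbox
# would strip the name from a length-1 named vector)
serialize_truth <- function(truth) {
  list(informative_channels = truth$informative_channels,
       band_weights = as.list(truth$band_weights),
       coupling_lag_s = truth$coupling_lag_s,
       snr = truth$snr)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  lay_tab <- as.data.frame(data.table::fread(file.path(dir, "layout.csv")))
  layout <- electrode_layout(meta$n_rows, meta$n_cols, table = lay_tab)
  sig <- as.matrix(data.table::fread(file.path(dir, "signals.csv")))
  rec <- ecog_recording(t(sig), meta$fs, layout)
  traj_m <- as.matrix(data.table::fread(file.path(dir, "trajectory.csv")))
  traj <- trajectory(t(traj_m), meta$fs)
  bw <- unlist(meta$truth$band_weights)
  truth <- ground_truth(
    informative_channels = as.integer(unlist(meta$truth$informative_channels)),
    band_weights = if (length(bw)) bw else numeric(0),
    coupling_lag_s = meta$truth$coupling_lag_s,
    snr = meta$truth$snr)
  bands <- band_set(meta$bands$name, meta$bands$low_hz, meta$bands$high_hz)
  structure(list(recording = rec, trajectory = traj, truth = truth,
                 bands = bands, seed = as.integer(meta$seed),
                 config = c(meta$generator, list(bands = bands, truth = truth))),
            class = "synthetic_dataset")
}
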