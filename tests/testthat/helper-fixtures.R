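# Shared fixtures, built once per test run and cached. All synthetic and
# seeded; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small multi-band session: 8 channels on a 4x2 grid, 60 s, channels 1-3
# informative in the default bands (gamma3/gamma4/delta).
small_signal_dataset <- function() fixture("sig_ds", function()
  make_dataset(list(duration_s = 60, fs = 500, n_rows = 4L, n_cols = 2L,
                    truth = ground_truth(informative_channels = 1:3, snr = 10),
                    seed = 7L)))

small_cfg <- function() decoding_config(train_s = 40, test_s = 15, n_latent = 8L)

small_signal_ctx <- function() fixture("sig_ctx", function()
  prepare_decoding(small_signal_dataset(), small_cfg()))

# Session with coupling planted in gamma3 only, high SNR.
small_g3_dataset <- function() fixture("g3_ds", function()
  make_dataset(list(duration_s = 60, fs = 500, n_rows = 4L, n_cols = 2L,
                    truth = ground_truth(informative_channels = 1:3,
                                         band_weights = c(gamma3 = 1),
                                         snr = 25),
                    seed = 9L)))

small_g3_ctx <- function() fixture("g3_ctx", function()
  prepare_decoding(small_g3_dataset(), small_cfg()))

# Feature tensor with prescribed values, bypassing preprocessing, for
# embedding/decoder algebra tests.
fake_tensor <- function(n_ch, n_bands, n, fs = 100,
                        fill = function(i, b, t) sin(i + 2 * b + t / 7)) {
  vals <- array(0, dim = c(n_ch, n_bands, n))
  for (i in seq_len(n_ch)) for (b in seq_len(n_bands))
    vals[i, b, ] <- fill(i, b, seq_len(n))
  bands <- band_set(paste0("band", seq_len(n_bands)),
                    low_hz = seq_len(n_bands) * 2,
                    high_hz = seq_len(n_bands) * 2 + 1)
  structure(list(values = vals, fs = fs, band_set = bands,
                 layout = electrode_layout(n_ch, 1L), valid_from = 1L),
            class = "feature_tensor")
}

fake_trajectory <- function(n, fs = 100, fun = function(t) cbind(sin(t / 11), cos(t / 13), sin(t / 17)))
  trajectory(t(fun(seq_len(n))), fs)

# Independent evaluator of the decoder's explicit lag-sum form:
# p_a(t) = sum_{i,j,k} w_a(i,j,k) S(i,j,t - k*step) + a_a,
# computed by direct summation from the reshaped weight tensor.
eq2_predict <- function(model, feat, t_idx, step_n) {
  channels <- layout_channels(feat$layout)
  bands <- feat$band_set$name
  out <- matrix(0, length(t_idx), ncol(model$B))
  for (a in seq_len(ncol(model$B))) {
    W <- weight_tensor(model, a)
    for (ti in seq_along(t_idx)) {
      s <- 0
      for (ci in seq_along(channels)) for (bi in seq_along(bands))
        for (k in seq_len(dim(W)[3]))
          s <- s + W[as.character(channels[ci]), bands[bi], k] *
            feat$values[ci, bi, t_idx[ti] - k * step_n]
      out[ti, a] <- s + model$intercept[a]
    }
  }
  out
}
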