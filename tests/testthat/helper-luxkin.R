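# shared fixtures: buffer-medium constants and standard assay conditions

buffer_k <- function(km1 = NULL)
  rate_constants(kd = 7.85, kdd = 0.15, k1 = 1.55, k2 = 400, k3 = 0.42,
                 km3 = 10.90, k4 = 0.46, km1 = km1)

buffer_cond <- function(A0 = 40)
  assay_conditions(E0 = 0.95, F0 = 15, A0 = A0)

# coarse grid for tests that do not probe integration accuracy
grid_coarse <- seq(0, 15, by = 0.01)

no_noise <- function(seed = 1L) noise_model(sigma_rel = 0, seed = seed)

# fast fit settings for self-consistency refits on noiseless families
fast_fit <- function(n_starts = 1L, seed = 1L, km1 = NULL)
  fit_options(n_starts = n_starts, seed = seed, km1 = km1, maxit = 200L)
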