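# shared fixtures: ground-truth fit results and fast optimizer settings

# reference ground truth as a known-upstream input
make_truth_result <- function(unit) reference_fit_result(unit)

# reduced multi-start count: recovery problems here start from the
# moment-based guess, which converges without wide restarts
fast_control <- function(...) fit_control(n_starts = 2, ...)

noiseless <- function() noise_model(nir_sigma = 0, hplc_sigma = 0)
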