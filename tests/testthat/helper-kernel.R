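# shared photon kernels, built once per test run
.kernel_cache <- new.env(parent = emptyenv())

test_kernel <- function() {
  if (is.null(.kernel_cache$k)) {
    .kernel_cache$k <- build_lut(simulate_baseline(n_photons = 2e5, seed = 11))
  }
  .kernel_cache$k
}

# small kernel for cheap structural tests
test_kernel_small <- function() {
  if (is.null(.kernel_cache$ks)) {
    .kernel_cache$ks <- build_lut(simulate_baseline(n_photons = 3e4, seed = 7))
  }
  .kernel_cache$ks
}

local_minima <- function(x) which(diff(sign(diff(x))) == 2) + 1
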