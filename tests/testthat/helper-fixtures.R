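# Shared fixtures: a strongly asymmetric Gaussian-mixture phantom (no
# near-centrosymmetry, so projections determine the pose uniquely) and a
# default CTF used across pose tests.

asym_phantom <- function(D = 32) default_phantom(D)

test_ctf <- function() {
  ctf_params(defocus_u = 12000, defocus_v = 11000, astigmatism_angle = 30)
}

# cached slicer for the D = 32 phantom (built once per test run)
.fixture_env <- new.env()
asym_slicer <- function(D = 32, oversample = 2L) {
  key <- paste0("sl", D, "_", oversample)
  if (is.null(.fixture_env[[key]])) {
    vol <- make_phantom(asym_phantom(D), D)
    .fixture_env[[key]] <- prep_slicer(dht(vol), oversample)
  }
  .fixture_env[[key]]
}
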