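# Hand-written .Call wrappers for the compiled alignment core.
.kabsch3_cpp <- function(P, Q) {
  .Call("_fragsite_kabsch3_cpp", P, Q, PACKAGE = "fragsite")
}
.pair_distance_cpp <- function(R, t, sigma, tau) {
  .Call("_fragsite_pair_distance_cpp", R, t, sigma, tau, PACKAGE = "fragsite")
}
.grid_align_cpp <- function(qtrip, ttrip, d0, resid_max) {
  .Call("_fragsite_grid_align_cpp", qtrip, ttrip, d0, resid_max, PACKAGE = "fragsite")
}
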