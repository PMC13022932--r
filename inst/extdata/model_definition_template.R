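# Server-side model definition: exports build_model(), which the server
# calls to construct the network whose weights the federation trains.
build_model <- function(spec = fedbids::densenet_spec(), seed = 99L) {
  fedbids::build_densenet(spec, seed = seed)
}
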