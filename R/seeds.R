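# Deterministic derivation of sub-seeds from one master seed.
# Every source of randomness in the package draws its seed through this,
# so a stage (or a single simulated occasion) can be reproduced in
# isolation without replaying everything before it.
stage_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1014741823
  as.integer((as.numeric(seed) %% 65011 * 33029 + h) %% 2147483629L)
}
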