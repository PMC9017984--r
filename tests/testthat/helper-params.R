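# Shared fixtures: standard resting parameters and probe variants.

basal_phys <- function(...) phys_params(...)
basal_probe <- function(...) probe_params(...)

# Scale the membrane coefficient beta by scaling the perfusate flow
# (beta depends only on the product R0 * f).
with_beta_mult <- function(probe, m) {
  probe_params(R0 = probe$R0, f = probe$f * m, L = probe$L,
               r1 = probe$r1, Cp = probe$Cp)
}

with_cp <- function(probe, cp) {
  probe_params(R0 = probe$R0, f = probe$f, L = probe$L,
               r1 = probe$r1, Cp = cp)
}
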