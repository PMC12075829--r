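# Loaded once per test run; the bundle is read-only so sharing is safe.
ref <- reference_bundle()

# A representative synthetic record spec used across files.
base_spec <- function(seed = 101, ...) {
  synthetic_spec(seed = seed, n_atoms = 12, target_ip = 7.5, target_ea = 0.4,
                 target_gap = 4.2, target_entropy = 232, ...)
}
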