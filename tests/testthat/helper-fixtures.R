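# Shared small-scale fixtures, built once per test run.  The 160x160 SLM
# region maps to a 128x128 camera grid under the default configuration
# (52 nm / 65 nm sample pixels, 4:5 commensurate).
fixture_config <- optical_config()
fixture_seq <- build_repertoire("bio12", c(160, 160), 4)
fixture_phantom <- generate_bead_phantom(
  6, c(128, 128), sample_pixel(fixture_config),
  min_separation = 1500, margin = 1500, seed = 11)
fixture_stack <- simulate_acquisition(
  fixture_phantom, fixture_seq, fixture_config,
  noise_model(1e4, 2, seed = 12))
fixture_stack_clean <- simulate_acquisition(
  fixture_phantom, fixture_seq, fixture_config,
  noise_model(1e4, 0, seed = 12, shot_noise = FALSE))

# A single-orientation pattern sequence (angle 0, three phases) assembled
# from the same building blocks, for orientation-count error tests.
fixture_seq_one_angle <- local({
  specs <- lapply(0:2, function(p) pattern_spec(0, 4, p, 3))
  masks <- lapply(specs, make_line_pattern, shape = c(160, 160))
  structure(list(masks = masks, specs = specs, shape = c(160L, 160L),
                 preset = NULL, base_period = 4),
            class = "pattern_sequence")
})
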