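# One shared synthetic study bundle for the whole suite (regenerating it
# per test file would dominate runtime). Seed fixed so expected values
# frozen in the tests are reproducible.
demo_dir <- file.path(tempdir(), "psikit-demo-bundle")
demo_config <- simulation_config(seed = 101)
demo_bundle <- generate_study(demo_config, demo_dir)
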