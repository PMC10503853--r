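# Example configuration for the fluorotherm command-line shell
# (inst/cli/fluorotherm.R). Every key mirrors a function argument; omitted
# keys fall back to the package defaults documented on the help pages.

# `generate` subcommand -> make_benchmark_dataset()
n_images: 10        # field/image pairs to generate
shape: [48, 48]     # pixels, rows x cols
t_range: [298, 308] # kelvin window of the study
noise_sd: 0.1       # pixelwise Gaussian temperature noise, K (benchmark)

# `chipseries` / `sweep` subcommands -> build_chip_series()
heater_dts_k: [1, 6, 14, 24, 38, 56, 80]  # heater excess over ambient, K
noise_sd_counts: 50 # chip camera read noise in grayscale counts
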