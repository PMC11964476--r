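# shared fixtures, built in code at test time

# a single-Gaussian spectrum on a uniform grid
gauss_spectrum <- function(center = 455, sigma = 10, height = 1,
                           grid = seq(200, 900, by = 1), offset = 0,
                           role = "emission", source = "none") {
  spectrum1d(grid, offset + height * exp(-(grid - center)^2 / (2 * sigma^2)),
             role = role, source = source)
}

# noise-free default-library EEM on the default grids
clean_blood_eem <- function() {
  generate_eem(blood_fluorophores(), source = excitation_source(),
               noise_sd = 0)
}

# the Table-V-style two-patient pair: patient 1 higher Hb, oxygenation
# and plasma; patient 2 less oxygenated, less plasma
table5_band_pair <- function(noise_sd = 0, seed = 1L) {
  profs <- demo_patient_profiles(noise_sd = noise_sd, seed = seed)
  lapply(profs, function(p) {
    band_summary(generate_patient_spectrum(p))
  })
}
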