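#' Pipeline configuration
#'
#' A single validated object holding every default that influences a
#' number downstream: grid bounds and step, preprocessing parameters,
#' photophysics constants, biophysics defaults, and the diagnostics tie
#' threshold.  The effective config is echoed into every report's
#' metadata.
#'
#' @param grid_min,grid_max,grid_step Wavelength grid, nm.
#' @param baseline_window Baseline window, nm.
#' @param smooth_sigma Smoothing sigma, nm.
#' @param prominence Peak prominence threshold (fraction of max).
#' @param epsilon540 Hemoglobin molar absorptivity at 540 nm,
#'   L mol^-1 cm^-1.
#' @param hb_molar_mass Hemoglobin molar mass, g/mol.
#' @param di_a,di_b,di_c Deformability model constants.
#' @param scatter_k Scattering size calibration, um/nm.
#' @param tie_threshold Relative difference treated as a band tie.
#' @param seed Global seed; per-stage child seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_min = 200, grid_max = 900, grid_step = 0.5,
                            baseline_window = 50, smooth_sigma = 2,
                            prominence = 0.05,
                            epsilon540 = 54000, hb_molar_mass = 64500,
                            di_a = 1.5, di_b = -0.05, di_c = 0.5,
                            scatter_k = 0.009,
                            tie_threshold = 0.01, seed = 1L) {
  if (grid_min >= grid_max || grid_step <= 0) stop("invalid grid")
  if (tie_threshold < 0) stop("tie_threshold must be >= 0")
  structure(
    list(grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
         baseline_window = baseline_window, smooth_sigma = smooth_sigma,
         prominence = prominence, epsilon540 = epsilon540,
         hb_molar_mass = hb_molar_mass, di_a = di_a, di_b = di_b,
         di_c = di_c, scatter_k = scatter_k,
         tie_threshold = tie_threshold, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_grid <- function(cfg) seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step)

#' Default two-patient demonstration profiles
#'
#' A pair of profiles mirroring the qualitative clinical contrast the
#' band comparison is designed to expose: patient 1 with higher
#' hemoglobin, near-complete oxygenation and more plasma; patient 2
#' mildly anemic, less oxygenated, with less plasma (higher
#' hematocrit).
#'
#' @param noise_sd Per-spectrum noise sd.
#' @param seed Base seed; the two patients draw independent child
#'   seeds.
#' @return A list of two [patient_profile()] objects.
#' @export
demo_patient_profiles <- function(noise_sd = 0, seed = 1L) {
  list(
    patient_1 = patient_profile(hemoglobin_gdl = 16.4,
                                oxygen_fraction = 0.96,
                                plasma_fraction = 0.53,
                                lifecycle_phase = "mature",
                                noise_sd = noise_sd,
                                seed = child_seed(seed, "patient_1")),
    patient_2 = patient_profile(hemoglobin_gdl = 12.6,
                                oxygen_fraction = 0.80,
                                plasma_fraction = 0.40,
                                lifecycle_phase = "mature",
                                noise_sd = noise_sd,
                                seed = child_seed(seed, "patient_2"))
  )
}

#' Matching CBC records for the demonstration patients
#'
#' Hemoglobin, RBC count, hematocrit and the WBC differential for the
#' two demonstration subjects (adult ages assumed).
#'
#' @return A list of two [cbc_record()] objects.
#' @export
demo_cbc_records <- function() {
  list(
    patient_1 = cbc_record(hb_gdl = 16.4, rbc_1e6_per_ul = 5.32,
                           hct_pct = 46.9, age_years = 35, sex = "M",
                           neutrophils_pct = 48.1, lymphocytes_pct = 37.3,
                           eosinophils_pct = 7.2, basophils_pct = 4.2),
    patient_2 = cbc_record(hb_gdl = 12.6, rbc_1e6_per_ul = 4.36,
                           hct_pct = 38.5, age_years = 35, sex = "F",
                           neutrophils_pct = 65.4, lymphocytes_pct = 24.0,
                           eosinophils_pct = 2.1, basophils_pct = 0.5)
  )
}

#' Run the full two-patient comparison pipeline
#'
#' Simulates (or ingests) two patient spectra, preprocesses both with
#' the configured chain, computes the three-band summaries, compares
#' the patients, and — when CBC records are supplied — annotates the
#' comparison with CBC concordance.  Deterministic for a fixed config:
#' each random stage draws a child seed from the global seed, so adding
#' a stage never perturbs earlier draws.
#'
#' @param config A [pipeline_config()].
#' @param profiles Two [patient_profile()]s; default
#'   [demo_patient_profiles()] at the config seed.
#' @param spectra Optional pre-acquired pair of [spectrum1d()]s,
#'   bypassing simulation.
#' @param cbc Optional list of two [cbc_record()]s (or `NULL`: the
#'   concordance section is marked absent).
#' @param source An [excitation_source()].
#' @return A list of class `pipeline_report`: `bands` (per-patient
#'   [band_summary()]), `comparison`, `concordance` (or `NULL`),
#'   `config` echo, and a `log` of stages with parameters.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         profiles = demo_patient_profiles(seed = config$seed),
                         spectra = NULL, cbc = demo_cbc_records(),
                         source = excitation_source("deuterium+halogen")) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  grid <- config_grid(config)
  if (is.null(spectra)) {
    spectra <- lapply(profiles, generate_patient_spectrum,
                      source = source, grid = grid)
    log$simulate <- list(source = source$kind, n_grid = length(grid),
                         seed = config$seed)
  } else {
    log$ingest <- list(n = length(spectra))
  }
  # joint maximum-intensity scaling: dividing both spectra by the shared
  # maximum keeps the cross-patient amplitude ordering intact (a
  # per-spectrum max would pin both dominant bands to 1 and erase it)
  shared_max <- max(vapply(spectra, function(s) max(abs(s$intensity)),
                           numeric(1)))
  if (shared_max == 0) stop("both spectra are all-zero")
  clean <- lapply(spectra, function(s) {
    s$intensity <- s$intensity / shared_max
    s <- baseline_correct(s, window = config$baseline_window)
    s <- gaussian_smooth(s, sigma_nm = config$smooth_sigma)
    # role-based clipping: emission intensities are physical (>= 0)
    # except under UV, where difference spectra carry negative lobes
    if (s$role == "emission" && !identical(s$source, "UV")) {
      s$intensity <- pmax(s$intensity, 0)
    }
    s
  })
  log$preprocess <- list(normalization = "joint-max",
                         baseline_window_nm = config$baseline_window,
                         smooth_sigma_nm = config$smooth_sigma)
  bands <- lapply(clean, band_summary)
  comparison <- compare_patients(bands[[1]], bands[[2]],
                                 tie_threshold = config$tie_threshold)
  log$compare <- list(tie_threshold = config$tie_threshold)
  concordance <- NULL
  if (!is.null(cbc)) {
    concordance <- cbc_concordance(cbc[[1]], cbc[[2]], comparison,
                                   tie_threshold = config$tie_threshold)
    log$concordance <- list(tie_threshold = config$tie_threshold)
  }
  structure(list(bands = bands, comparison = comparison,
                 concordance = concordance, config = unclass(config),
                 log = log),
            class = "pipeline_report")
}

#' Serialize a pipeline report to JSON
#'
#' Writes the band integrals, winners, interpretations, concordance
#' flags, implied MCH and the full config echo.  Deterministic for a
#' fixed config and seed (no timestamps).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  payload <- list(
    bands = lapply(report$bands, unclass),
    comparison = as.data.frame(report$comparison),
    concordance = if (is.null(report$concordance)) "absent" else
      list(bands = report$concordance$bands, mch = report$concordance$mch),
    config = report$config,
    log = report$log
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Command-line entry point
#'
#' Umbrella CLI over the pipeline stages.  Subcommands:
#' \describe{
#'   \item{simulate}{`simulate eem|absorption|patient|cbc|scattering
#'     --seed S --out FILE` — write one synthetic dataset.}
#'   \item{preprocess}{`preprocess --in raw.tsv --out clean.tsv
#'     --baseline-window 50 --smooth-sigma 2`.}
#'   \item{compare}{`compare --a p1.tsv --b p2.tsv [--cbc cbc.csv]
#'     --out report.json`.}
#'   \item{report}{`report --seed S --out report.json` — full demo
#'     pipeline on the bundled two-patient emulation.}
#' }
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly; stops on usage errors.
#' @export
hemospec_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: hemospec <simulate|preprocess|compare|report> [options]")
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i[1] < length(rest)) rest[i[1] + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", NULL)
  switch(cmd,
    simulate = {
      what <- rest[1]
      if (is.null(out)) stop("simulate requires --out")
      switch(what,
        eem = write_eem(generate_eem(blood_fluorophores(), seed = seed), out),
        absorption = write_spectrum(
          generate_absorption_spectrum(0.9, 5), out),
        patient = write_spectrum(generate_patient_spectrum(
          patient_profile(noise_sd = 0.02, seed = seed)), out),
        cbc = write_cbc(generate_cbc(35, "M", seed = seed), out),
        scattering = write_spectrum(generate_scattering_profile(
          7.2, noise_sd = 1, seed = seed), out),
        stop("unknown simulate target: ", what))
      message("wrote ", out)
    },
    preprocess = {
      infile <- opt("--in")
      if (is.null(infile) || is.null(out)) {
        stop("preprocess requires --in and --out")
      }
      s <- read_spectrum(infile)
      s <- preprocess_spectrum(
        s, baseline_window = as.numeric(opt("--baseline-window", "50")),
        smooth_sigma = as.numeric(opt("--smooth-sigma", "2")))
      write_spectrum(s, out)
      message("wrote ", out)
    },
    compare = {
      fa <- opt("--a")
      fb <- opt("--b")
      if (is.null(fa) || is.null(fb) || is.null(out)) {
        stop("compare requires --a, --b and --out")
      }
      spectra <- list(read_spectrum(fa), read_spectrum(fb))
      cbc_path <- opt("--cbc")
      cbc <- if (is.null(cbc_path)) NULL else read_cbc(cbc_path)
      rep <- run_pipeline(pipeline_config(seed = seed), spectra = spectra,
                          cbc = cbc)
      write_report(rep, out)
      message("wrote ", out)
    },
    report = {
      if (is.null(out)) stop("report requires --out")
      rep <- run_pipeline(pipeline_config(seed = seed))
      write_report(rep, out)
      message("wrote ", out)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
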