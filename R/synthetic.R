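#' Configuration of the synthetic rib cohort generator
#'
#' Describes a synthetic cohort of rib specimens with the statistical
#' structure the analysis pipeline assumes. Donor age and BMI are drawn
#' from truncated normal distributions matching the study cohort moments
#' (age 50.9 +/- 10.9 years on 26--62; BMI 32.6 +/- 6.2 kg/m^2 on
#' 24.2--42.7; n = 15). A single latent degradation factor z -- a
#' standardized combination of age and BMI plus noise -- drives all three
#' specimen parameters: the rate ratio alpha through a logit link, the
#' baseline rate lambda through a log link, and the Pareto exponent nu
#' linearly with a floor just above 1. One factor (rather than separate
#' covariate effects) is deliberate: cohort PCA should find one dominant
#' component, mirroring the aging/degradation axis seen in real rib data.
#'
#' The default loadings were calibrated once by Monte Carlo so that large
#' synthetic cohorts reproduce the qualitative correlation pattern of real
#' cohorts (alpha and lambda rising with the factor, nu falling, event
#' counts rising, fracture strain falling) and are frozen as package
#' constants; they are not fitted to any particular dataset's correlation
#' magnitudes.
#'
#' @param n_specimens cohort size (default 15, the study cohort).
#' @param age_mean,age_sd,age_range years; truncated-normal age model.
#' @param bmi_mean,bmi_sd,bmi_range kg/m^2; truncated-normal BMI model.
#' @param z_age,z_bmi loadings of standardized age and BMI on the latent
#'   factor.
#' @param z_noise_sd standard deviation of the latent factor noise.
#' @param alpha_intercept,alpha_loading,alpha_noise_sd logit-scale model
#'   for the rate ratio alpha.
#' @param lambda_intercept,lambda_loading,lambda_noise_sd log-scale model
#'   for the baseline rate lambda (intercept in log(1/strain)).
#' @param nu_intercept,nu_loading,nu_noise_sd,nu_floor linear model for
#'   the Pareto exponent (loading enters with a negative sign).
#' @param e_m_true minimum energy of genuine microfailure signals (energy
#'   units); friction energies fall below it.
#' @param friction_rate expected number of friction events per specimen
#'   (Poisson).
#' @param guard_channels sensor ids of the two guard sensors at the rib
#'   ends.
#' @param max_events,min_increment simulation truncation; `min_increment`
#'   plays the role of the strain resolution of the acquisition chain, so
#'   the event count saturates at a realistic value instead of running to
#'   machine precision.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_specimens = 15L,
                          age_mean = 50.9, age_sd = 10.9,
                          age_range = c(26, 62),
                          bmi_mean = 32.6, bmi_sd = 6.2,
                          bmi_range = c(24.2, 42.7),
                          z_age = 1, z_bmi = 1, z_noise_sd = 0.35,
                          alpha_intercept = 3.0, alpha_loading = 0.55,
                          alpha_noise_sd = 0.08,
                          lambda_intercept = log(300), lambda_loading = 1.1,
                          lambda_noise_sd = 0.15,
                          nu_intercept = 1.65, nu_loading = 0.3,
                          nu_noise_sd = 0.06, nu_floor = 1.05,
                          e_m_true = 1, friction_rate = 8,
                          guard_channels = c("guard_left", "guard_right"),
                          max_events = 2000L, min_increment = 1e-8) {
  cfg <- list(n_specimens = as.integer(n_specimens),
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
              z_age = z_age, z_bmi = z_bmi, z_noise_sd = z_noise_sd,
              alpha_intercept = alpha_intercept,
              alpha_loading = alpha_loading,
              alpha_noise_sd = alpha_noise_sd,
              lambda_intercept = lambda_intercept,
              lambda_loading = lambda_loading,
              lambda_noise_sd = lambda_noise_sd,
              nu_intercept = nu_intercept, nu_loading = nu_loading,
              nu_noise_sd = nu_noise_sd, nu_floor = nu_floor,
              e_m_true = e_m_true, friction_rate = friction_rate,
              guard_channels = guard_channels,
              max_events = as.integer(max_events),
              min_increment = min_increment)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_specimens >= 2L,
            cfg$age_sd > 0, cfg$bmi_sd > 0,
            length(cfg$age_range) == 2L, length(cfg$bmi_range) == 2L,
            cfg$age_range[1L] < cfg$age_range[2L],
            cfg$bmi_range[1L] < cfg$bmi_range[2L],
            cfg$z_noise_sd >= 0, cfg$alpha_noise_sd >= 0,
            cfg$lambda_noise_sd >= 0, cfg$nu_noise_sd >= 0,
            cfg$nu_floor > 1, cfg$e_m_true > 0, cfg$friction_rate >= 0,
            cfg$max_events >= 1L, cfg$min_increment >= 0)
  if (cfg$age_mean < cfg$age_range[1L] || cfg$age_mean > cfg$age_range[2L])
    stop("age_range must contain age_mean", call. = FALSE)
  if (cfg$bmi_mean < cfg$bmi_range[1L] || cfg$bmi_mean > cfg$bmi_range[2L])
    stop("bmi_range must contain bmi_mean", call. = FALSE)
  invisible(cfg)
}

#' Moments of a truncated normal distribution
#'
#' Mean and standard deviation of N(mean, sd^2) truncated to
#' `[lower, upper]`; used both to standardize covariates inside the
#' generator (so each specimen can be generated independently) and as the
#' oracle for the cohort-moment tests.
#'
#' @param mean,sd parent normal parameters.
#' @param lower,upper truncation bounds.
#' @return Named numeric vector `c(mean, sd)` of the truncated law.
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  zden <- pnorm(b) - pnorm(a)
  m1 <- mean + sd * (dnorm(a) - dnorm(b)) / zden
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / zden -
                 ((dnorm(a) - dnorm(b)) / zden)^2)
  c(mean = m1, sd = sqrt(v))
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  # rejection sampling; acceptance region is ~2 sd wide, cost negligible
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

latent_factor <- function(age, bmi, cfg) {
  am <- truncnorm_moments(cfg$age_mean, cfg$age_sd,
                          cfg$age_range[1L], cfg$age_range[2L])
  bm <- truncnorm_moments(cfg$bmi_mean, cfg$bmi_sd,
                          cfg$bmi_range[1L], cfg$bmi_range[2L])
  raw <- cfg$z_age * (age - am[["mean"]]) / am[["sd"]] +
         cfg$z_bmi * (bmi - bm[["mean"]]) / bm[["sd"]]
  raw / sqrt(cfg$z_age^2 + cfg$z_bmi^2)
}

#' Generate one synthetic rib specimen
#'
#' Draws the specimen's latent degradation factor from its age and BMI,
#' maps it to the process parameters (alpha, lambda) and the energy
#' exponent nu, simulates the microfailure strain sequence, attaches
#' Pareto energies to the microfailure events on the central channel, and
#' appends low-energy friction events on the guard channels (energies
#' below `e_m_true`, strains uniform over the loading ramp). The true
#' parameters are carried in the record for validation only; fitting never
#' sees them.
#'
#' @param age,bmi donor covariates.
#' @param cfg a [cohort_config()].
#' @param specimen_id label.
#' @param seed optional integer for a reproducible record.
#' @return A list of class `"specimen_record"` with elements `meta`
#'   (specimen_id, age, bmi), `true_params` (alpha, lambda, nu, z),
#'   `events` (an [ae_events()] table including friction artifacts),
#'   `n_ae` (microfailure count, i.e. after friction filtering),
#'   `eps_max`, and `stop_reason`.
#' @export
generate_specimen <- function(age, bmi, cfg = cohort_config(),
                              specimen_id = "S1", seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  z <- latent_factor(age, bmi, cfg) + rnorm(1L, 0, cfg$z_noise_sd)
  alpha <- plogis(cfg$alpha_intercept + cfg$alpha_loading * z +
                    rnorm(1L, 0, cfg$alpha_noise_sd))
  alpha <- min(max(alpha, 1e-6), 1 - 1e-6)
  lambda <- exp(cfg$lambda_intercept + cfg$lambda_loading * z +
                  rnorm(1L, 0, cfg$lambda_noise_sd))
  nu <- max(cfg$nu_floor,
            cfg$nu_intercept - cfg$nu_loading * z +
              rnorm(1L, 0, cfg$nu_noise_sd))
  params <- coxplosive_params(alpha, lambda)
  sim <- simulate_coxplosive(params, max_events = cfg$max_events,
                             min_increment = cfg$min_increment)
  strains <- sim$cum_strains
  n_micro <- length(strains)
  energies <- rpareto(n_micro, nu = nu, e_m = cfg$e_m_true)
  n_fric <- rpois(1L, cfg$friction_rate)
  if (n_fric > 0L && length(cfg$guard_channels)) {
    fric_strain <- runif(n_fric, 0, max(strains))
    fric_energy <- cfg$e_m_true * runif(n_fric, 0.05, 0.95)
    fric_channel <- sample(cfg$guard_channels, n_fric, replace = TRUE)
    events <- ae_events(c(strains, fric_strain),
                        c(energies, fric_energy),
                        c(rep("central", n_micro), fric_channel),
                        specimen_id = specimen_id)
  } else {
    events <- ae_events(strains, energies, "central",
                        specimen_id = specimen_id)
  }
  structure(list(meta = list(specimen_id = specimen_id,
                             age = age, bmi = bmi),
                 true_params = list(alpha = alpha, lambda = lambda,
                                    nu = nu, z = z),
                 events = events,
                 n_ae = n_micro,
                 eps_max = max(strains),
                 stop_reason = sim$stop_reason),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf(
    "Synthetic specimen %s: age %.1f, BMI %.1f | alpha %.3f, lambda %.3g, nu %.2f | %d AE events, eps_max %.4g\n",
    x$meta$specimen_id, x$meta$age, x$meta$bmi, x$true_params$alpha,
    x$true_params$lambda, x$true_params$nu, x$n_ae, x$eps_max))
  invisible(x)
}

#' Generate a synthetic rib cohort
#'
#' Draws ages and BMI values from the truncated normal cohort model
#' (independently: the study sample shows no significant age--BMI
#' correlation) and generates one specimen record per donor via
#' [generate_specimen()]. Specimen-level randomness uses child seeds
#' derived deterministically from `seed`, so the whole cohort is
#' reproducible.
#'
#' @param cfg a [cohort_config()].
#' @param seed master seed (integer).
#' @return A list of class `"ae_cohort"`: `specimens` (list of
#'   `"specimen_record"`), `cfg`, `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(), seed = 1)
#' coh$specimens[[1]]
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  validate_cohort_config(cfg)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- cfg$n_specimens
  age <- rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                    cfg$age_range[1L], cfg$age_range[2L])
  bmi <- rtruncnorm(n, cfg$bmi_mean, cfg$bmi_sd,
                    cfg$bmi_range[1L], cfg$bmi_range[2L])
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("S%02d", seq_len(n))
  specimens <- lapply(seq_len(n), function(i)
    generate_specimen(age[i], bmi[i], cfg, specimen_id = ids[i],
                      seed = child_seeds[i]))
  structure(list(specimens = specimens, cfg = cfg,
                 seed = as.integer(seed)),
            class = "ae_cohort")
}

#' @export
print.ae_cohort <- function(x, ...) {
  n <- length(x$specimens)
  ages <- vapply(x$specimens, function(s) s$meta$age, numeric(1L))
  bmis <- vapply(x$specimens, function(s) s$meta$bmi, numeric(1L))
  nev <- vapply(x$specimens, function(s) s$n_ae, numeric(1L))
  cat(sprintf("Synthetic AE cohort: %d specimens (seed %d)\n", n, x$seed))
  cat(sprintf("  age %.1f +/- %.1f, BMI %.1f +/- %.1f, N_AE %d .. %d\n",
              mean(ages), stats::sd(ages), mean(bmis), stats::sd(bmis),
              min(nev), max(nev)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one event CSV per specimen (`<id>_events.csv`, schema
#' `strain,energy,channel`), a `metadata.csv`
#' (`specimen_id,age,bmi`), and a `truth.json` holding the hidden true
#' parameters (for validation only; the fitting stage must not read it).
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ae_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- data.frame(
    specimen_id = vapply(cohort$specimens, function(s) s$meta$specimen_id,
                         character(1L)),
    age = vapply(cohort$specimens, function(s) s$meta$age, numeric(1L)),
    bmi = vapply(cohort$specimens, function(s) s$meta$bmi, numeric(1L)),
    stringsAsFactors = FALSE)
  write_specimen_meta(meta, file.path(dir, "metadata.csv"))
  for (s in cohort$specimens)
    write_ae_events(s$events,
                    file.path(dir, paste0(s$meta$specimen_id, "_events.csv")))
  truth <- lapply(cohort$specimens, function(s)
    c(list(specimen_id = s$meta$specimen_id), s$true_params,
      list(n_ae = s$n_ae, eps_max = s$eps_max)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or real data in the same
#' layout) back into memory
#'
#' @param dir directory containing `metadata.csv` and one
#'   `<specimen_id>_events.csv` per specimen.
#' @return A list with `meta` (data frame) and `events` (named list of
#'   [ae_events()] tables).
#' @export
read_cohort_dir <- function(dir) {
  meta <- read_specimen_meta(file.path(dir, "metadata.csv"))
  events <- lapply(meta$specimen_id, function(id)
    read_ae_events(file.path(dir, paste0(id, "_events.csv")),
                   specimen_id = id))
  names(events) <- meta$specimen_id
  list(meta = meta, events = events)
}
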