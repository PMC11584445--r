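#' Fit one specimen end to end
#'
#' Applies the friction filter, fits the explosive process parameters by
#' penalty minimization and the Pareto exponent of the surviving energies,
#' and returns one record row for the cohort table. Energies may be
#' absent (all `NA`) for purely simulated sequences, in which case the
#' Pareto stage is skipped and `nu`/`e_m` are `NA`.
#'
#' @param events an [ae_events()] table (raw, friction events included).
#' @param age,bmi donor covariates for the record (may be `NA`).
#' @param guard_channels,e_min passed to [filter_friction_events()].
#' @param threshold_q quantile for [select_threshold()] on the filtered
#'   energies.
#' @param ... further arguments to [fit_coxplosive()].
#' @return A one-row data frame with the specimen record columns (see
#'   [write_specimen_records()]).
#' @export
fit_specimen <- function(events, age = NA_real_, bmi = NA_real_,
                         guard_channels = c("guard_left", "guard_right"),
                         e_min = 0, threshold_q = 0.05, ...) {
  stopifnot(inherits(events, "ae_events"))
  clean <- filter_friction_events(events, guard_channels, e_min)
  if (nrow(clean) < 2L)
    stop("specimen ", attr(events, "specimen_id"),
         ": fewer than 2 microfailure events after friction filtering",
         call. = FALSE)
  fit <- fit_coxplosive(clean, ...)
  nu <- NA_real_; e_m <- NA_real_
  if (!anyNA(clean$energy)) {
    e_m <- select_threshold(clean$energy, q = threshold_q)
    pf <- try(fit_pareto(clean$energy, e_m = e_m), silent = TRUE)
    if (!inherits(pf, "try-error")) nu <- pf$nu
  }
  data.frame(specimen_id = attr(events, "specimen_id"),
             age = age, bmi = bmi,
             alpha = fit$params$alpha,
             lambda = fit$params$lambda,
             beta = deterioration_rate(fit$params),
             nu = nu, e_m = e_m,
             n_ae = nrow(clean),
             eps_max = eps_max(clean),
             mu_inf = fit$mu_inf_hat,
             phi_min = fit$phi_min,
             converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Fit every specimen of a cohort
#'
#' Accepts either an in-memory synthetic cohort ([generate_cohort()]) or a
#' directory in the [write_cohort()] layout (real data can be supplied
#' that way). Per-specimen failures are caught and logged; the run
#' continues and the failing specimens are reported in the
#' `"failures"` attribute.
#'
#' @param cohort an `"ae_cohort"` or a directory path.
#' @param guard_channels,e_min,threshold_q,... passed to [fit_specimen()].
#' @return A data frame of specimen records (class `"cohort_records"`),
#'   one row per successfully fitted specimen.
#' @export
fit_cohort <- function(cohort,
                       guard_channels = c("guard_left", "guard_right"),
                       e_min = 0, threshold_q = 0.05, ...) {
  if (is.character(cohort)) {
    meta <- read_specimen_meta(file.path(cohort, "metadata.csv"))
    # read lazily so one corrupt file fails one specimen, not the run
    dir <- cohort
    events <- NULL
    get_events <- function(id)
      read_ae_events(file.path(dir, paste0(id, "_events.csv")),
                     specimen_id = id)
  } else if (inherits(cohort, "ae_cohort")) {
    meta <- data.frame(
      specimen_id = vapply(cohort$specimens, function(s) s$meta$specimen_id,
                           character(1L)),
      age = vapply(cohort$specimens, function(s) s$meta$age, numeric(1L)),
      bmi = vapply(cohort$specimens, function(s) s$meta$bmi, numeric(1L)),
      stringsAsFactors = FALSE)
    events <- lapply(cohort$specimens, function(s) s$events)
    names(events) <- meta$specimen_id
    guard_channels <- cohort$cfg$guard_channels
    get_events <- function(id) events[[id]]
  } else stop("'cohort' must be an ae_cohort or a directory path",
              call. = FALSE)
  rows <- vector("list", nrow(meta))
  failures <- character(0)
  for (i in seq_len(nrow(meta))) {
    id <- meta$specimen_id[i]
    rec <- try(fit_specimen(get_events(id), age = meta$age[i],
                            bmi = meta$bmi[i],
                            guard_channels = guard_channels,
                            e_min = e_min, threshold_q = threshold_q, ...),
               silent = TRUE)
    if (inherits(rec, "try-error")) {
      failures <- c(failures, id)
      message("specimen ", id, " failed to fit: ",
              attr(rec, "condition")$message)
    } else rows[[i]] <- rec
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  structure(out, failures = failures,
            class = c("cohort_records", "data.frame"))
}

#' Cohort-level statistical report
#'
#' Runs the full cohort stage on fitted specimen records: Spearman
#' correlation matrix of the seven magnitudes, standardized PCA with
#' variance fractions, the regression of PC1 on age and BMI, and the
#' agreement between the fitted expected total strain `mu_inf` and the
#' observed fracture strain `eps_max` (both Pearson r and Spearman rho,
#' since the two are reported in different conventions in practice).
#'
#' @param records fitted records ([fit_cohort()] output or equivalent
#'   data frame).
#' @param standardize passed to [cohort_pca()].
#' @return A list of class `"cohort_report"` with elements `n`,
#'   `spearman` (`rho`, `p`), `pca` (`variance_fractions`, `loadings`),
#'   `pc1_regression` (`coefficients`, `p_values`, `r_squared`),
#'   `mu_inf_vs_eps_max` (`pearson_r`, `spearman_rho`), and
#'   `sign_pattern` (named logicals, see [sign_pattern_holds()]).
#' @export
cohort_report <- function(records, standardize = TRUE) {
  tab <- cohort_table(records)
  sp <- spearman_matrix(tab)
  pca <- cohort_pca(tab, standardize = standardize)
  reg <- regress_pc1(pca, tab$age, tab$bmi)
  agr <- list(
    pearson_r = if ("mu_inf" %in% names(tab))
      stats::cor(tab$mu_inf, tab$eps_max) else NA_real_,
    spearman_rho = if ("mu_inf" %in% names(tab))
      stats::cor(tab$mu_inf, tab$eps_max, method = "spearman") else NA_real_)
  structure(list(n = nrow(tab),
                 spearman = list(rho = sp$rho, p = sp$p),
                 pca = list(variance_fractions = pca$variance_fractions,
                            loadings = pca$loadings),
                 pc1_regression = list(coefficients = reg$coefficients,
                                       p_values = reg$p_values,
                                       r_squared = reg$r_squared),
                 mu_inf_vs_eps_max = agr,
                 sign_pattern = sign_pattern_holds(sp$rho)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d specimens\n", x$n))
  cat(sprintf("  PC1 variance fraction: %.1f%%\n",
              100 * x$pca$variance_fractions[1L]))
  co <- x$pc1_regression$coefficients
  cat(sprintf("  PC1 = %.3f + %.3f * age + %.3f * BMI  (r^2 = %.3f)\n",
              co[["intercept"]], co[["age"]], co[["bmi"]],
              x$pc1_regression$r_squared))
  cat(sprintf("  E(total strain) vs eps_max: Pearson r = %.3f\n",
              x$mu_inf_vs_eps_max$pearson_r))
  cat(sprintf("  correlation sign pattern: %d of %d conditions hold\n",
              sum(x$sign_pattern), length(x$sign_pattern)))
  invisible(x)
}

#' Qualitative correlation sign pattern of a healthy cohort
#'
#' The eight sign conditions a cohort with the expected degradation
#' structure satisfies: alpha rises with age and BMI, lambda rises with
#' BMI, nu falls with age and BMI, event count rises with age, fracture
#' strain falls with BMI, and alpha and lambda are positively coupled.
#'
#' @param rho a 7x7 correlation matrix with the cohort magnitude names.
#' @return Named logical vector of the eight conditions.
#' @export
sign_pattern_holds <- function(rho) {
  c(alpha_age_pos   = rho["alpha", "age"] > 0,
    alpha_bmi_pos   = rho["alpha", "bmi"] > 0,
    lambda_bmi_pos  = rho["lambda", "bmi"] > 0,
    nu_age_neg      = rho["nu", "age"] < 0,
    nu_bmi_neg      = rho["nu", "bmi"] < 0,
    n_ae_age_pos    = rho["n_ae", "age"] > 0,
    eps_max_bmi_neg = rho["eps_max", "bmi"] < 0,
    alpha_lambda_pos = rho["alpha", "lambda"] > 0)
}

#' Run the full synthetic pipeline
#'
#' Generate a synthetic cohort, fit every specimen, and produce the
#' cohort report -- the whole analysis with no external data. Fully
#' deterministic given `seed`. When `out_dir` is given, the generated
#' cohort and the report are also written to disk.
#'
#' @param cfg a [cohort_config()].
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @param ... passed to [fit_cohort()].
#' @return A list with `cohort`, `records`, `report`.
#' @export
run_pipeline <- function(cfg = cohort_config(), seed = 1L, out_dir = NULL,
                         ...) {
  cohort <- generate_cohort(cfg, seed = seed)
  records <- fit_cohort(cohort, ...)
  report <- cohort_report(records)
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    write_specimen_records(records, file.path(out_dir, "records.csv"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  list(cohort = cohort, records = records, report = report)
}

#' Write a cohort report to JSON
#'
#' Floats are written at full precision so a report re-read from disk
#' compares bit-exactly; matrices are written with their dimnames.
#'
#' @param report a `"cohort_report"`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- report
  class(ser) <- NULL
  ser$spearman$rho <- matrix_to_named(ser$spearman$rho)
  ser$spearman$p <- matrix_to_named(ser$spearman$p)
  ser$pca$loadings <- matrix_to_named(ser$pca$loadings)
  ser$sign_pattern <- as.list(ser$sign_pattern)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

matrix_to_named <- function(m) {
  rows <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(rows) <- rownames(m)
  rows
}

#' Read or write a cohort configuration as YAML
#'
#' Round-trips a [cohort_config()] through a YAML file so that a study
#' configuration can live beside its outputs and be logged with every run.
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return `load_cohort_config()`: a validated [cohort_config()].
#' @export
load_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(cohort_config, vals)
}

#' @rdname load_cohort_config
#' @param cfg a [cohort_config()].
#' @export
save_cohort_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}
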