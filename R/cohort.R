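#' Assemble the cohort analysis table
#'
#' One row per specimen with the seven magnitudes entering the cohort
#' statistics: the fitted process parameters `alpha` and `lambda`, the
#' Pareto exponent `nu`, the observed event count `n_ae` and fracture
#' strain `eps_max`, and the donor covariates `age` and `bmi`. Rows with
#' any missing cell are dropped (with a message) before analysis.
#'
#' @param records a data frame containing at least the seven columns
#'   (extra columns such as `mu_inf` are carried through).
#' @return A data frame of class `"cohort_table"`.
#' @export
cohort_table <- function(records) {
  need <- c("alpha", "lambda", "nu", "n_ae", "eps_max", "age", "bmi")
  if (!is.data.frame(records)) records <- as.data.frame(records)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(records[need])
  if (any(!complete))
    message("dropping ", sum(!complete),
            " specimen(s) with missing fitted values")
  out <- records[complete, , drop = FALSE]
  if (nrow(out) < 3L)
    stop("at least 3 complete specimens are required", call. = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cohort_table", "data.frame"))
}

cohort_magnitudes <- function() {
  c("alpha", "lambda", "nu", "n_ae", "eps_max", "age", "bmi")
}

#' Spearman correlation matrix of the cohort magnitudes
#'
#' Pairwise Spearman rank correlations among the seven magnitudes, with
#' two-sided p-values. Ties receive average ranks. For small cohorts
#' (n < 10, and no ties in the pair) the exact permutation null is used;
#' otherwise the t approximation. A constant column yields `NA`
#' correlations (undefined, not zero).
#'
#' @param tab a [cohort_table()] (or data frame with the seven columns).
#' @param vars columns to correlate (default the seven magnitudes).
#' @return An object of class `"spearman_matrix"`: list with `rho`
#'   (symmetric, unit diagonal), `p` (two-sided), `n`.
#' @export
spearman_matrix <- function(tab, vars = cohort_magnitudes()) {
  stopifnot(all(vars %in% names(tab)))
  x <- as.data.frame(tab)[vars]
  n <- nrow(x)
  if (n < 3L) stop("at least 3 specimens are required", call. = FALSE)
  p <- length(vars)
  rho <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  pval <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pval) <- 0
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      xi <- x[[i]]; xj <- x[[j]]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) next  # undefined
      ct <- suppressWarnings(
        stats::cor.test(xi, xj, method = "spearman",
                        exact = n < 10L, alternative = "two.sided"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pval, n = n), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Spearman correlation matrix (n = %d)\n", x$n))
  print(round(x$rho, digits))
  cat("two-sided p-values:\n")
  print(signif(x$p, 2))
  invisible(x)
}

#' Principal component analysis of the cohort magnitudes
#'
#' Eigendecomposition of the covariance matrix of the seven magnitudes,
#' by default after standardization to z-scores (the magnitudes carry
#' incommensurate units -- strain, counts, years, kg/m^2 -- so the
#' correlation-matrix PCA is the defensible default; `standardize =
#' FALSE` gives the raw-covariance variant). Components are ordered by
#' decreasing variance; each loading vector is sign-fixed so its
#' largest-magnitude entry is positive. The leading component of a
#' well-behaved cohort is the degradation ("inveteration") axis.
#'
#' @param tab a [cohort_table()].
#' @param standardize scale columns to unit variance first (default TRUE).
#' @param vars columns to analyse.
#' @return An object of class `"cohort_pca"`: `loadings` (p x p
#'   orthonormal, columns PC1..PCp), `variance_fractions` (descending,
#'   summing to 1), `scores` (n x p), `sdev`, `center`, `scale`.
#' @export
cohort_pca <- function(tab, standardize = TRUE,
                       vars = cohort_magnitudes()) {
  stopifnot(all(vars %in% names(tab)))
  x <- as.matrix(as.data.frame(tab)[vars])
  if (nrow(x) < 3L) stop("at least 3 specimens are required", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (standardize && any(sds == 0))
    stop("cannot standardize zero-variance column(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # sign convention: largest-|entry| of each loading vector positive
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = rot,
                 variance_fractions = fr,
                 scores = scores,
                 sdev = pc$sdev,
                 center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 standardize = standardize),
            class = "cohort_pca")
}

#' @export
print.cohort_pca <- function(x, digits = 3, ...) {
  cat("PCA of cohort magnitudes",
      if (x$standardize) "(standardized)" else "(raw covariance)", "\n")
  cat("variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$variance_fractions),
                    100 * x$variance_fractions), collapse = ", "), "\n")
  cat("leading loadings (PC1):\n")
  print(round(x$loadings[, 1L], digits))
  invisible(x)
}

#' Regress the leading component on age and BMI
#'
#' Ordinary least squares of the PC1 scores (the degradation factor) on
#' donor age and BMI: the practical use is predicting a specimen's
#' degradation state from anthropometry alone. Reports the coefficients
#' (intercept, per-year, per-unit-BMI), R^2 and two-sided p-values. A
#' near-collinear age/BMI pair is flagged with a warning but coefficients
#' are still returned.
#'
#' @param scores PC1 scores (or a `"cohort_pca"`, whose first column is
#'   taken).
#' @param age,bmi covariates, same length as the scores.
#' @return An object of class `"pc1_regression"`: `coefficients`
#'   (intercept, age, bmi), `r_squared`, `p_values`, `n`, `model` (the
#'   underlying `lm`).
#' @export
regress_pc1 <- function(scores, age, bmi) {
  if (inherits(scores, "cohort_pca")) scores <- scores$scores[, 1L]
  stopifnot(length(age) == length(scores), length(bmi) == length(scores))
  if (length(scores) < 4L)
    stop("at least 4 specimens are required for the regression",
         call. = FALSE)
  if (abs(stats::cor(age, bmi)) > 0.99)
    warning("age and BMI are nearly collinear; coefficients are unstable")
  fit <- stats::lm(scores ~ age + bmi,
                   data = data.frame(scores = scores, age = age, bmi = bmi))
  sm <- summary(fit)
  co <- stats::coef(sm)
  nm <- c("(Intercept)" = "intercept", age = "age", bmi = "bmi")
  est <- pv <- stats::setNames(rep(NA_real_, 3L), nm)
  est[nm[rownames(co)]] <- co[, "Estimate"]   # aliased terms stay NA
  pv[nm[rownames(co)]] <- co[, "Pr(>|t|)"]
  structure(list(coefficients = est,
                 p_values = pv,
                 r_squared = sm$r.squared,
                 n = length(scores),
                 model = fit),
            class = "pc1_regression")
}

#' @export
print.pc1_regression <- function(x, digits = 4, ...) {
  cat("PC1 (degradation factor) ~ age + BMI\n")
  cat(sprintf("  PC1 = %s + %s * age + %s * BMI\n",
              format(x$coefficients[["intercept"]], digits = digits),
              format(x$coefficients[["age"]], digits = digits),
              format(x$coefficients[["bmi"]], digits = digits)))
  cat(sprintf("  r^2 = %s, n = %d; p(age) = %s, p(BMI) = %s\n",
              format(x$r_squared, digits = digits), x$n,
              format(x$p_values[["age"]], digits = 2),
              format(x$p_values[["bmi"]], digits = 2)))
  invisible(x)
}
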