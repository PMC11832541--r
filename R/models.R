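#' Normalize gray-matter volume to total intracranial volume
#'
#' Head-size correction: cortical GM volume divided by total intracranial
#' volume, a dimensionless ratio in (0, 1).
#'
#' @param gm GM cortical volume (mm^3, positive).
#' @param tiv Total intracranial volume (mm^3, positive, > `gm`).
#' @return `gm / tiv`.
#' @export
normalize_gm_volume <- function(gm, tiv) {
  if (any(gm <= 0) || any(tiv <= 0)) stop("volumes must be positive")
  if (any(gm >= tiv)) stop("GM volume must be smaller than TIV")
  gm / tiv
}

#' Exclude subjects by maximum head displacement
#'
#' Keeps subjects whose maximum displacement does not exceed the threshold;
#' subjects strictly greater than the threshold are excluded (a value
#' exactly at the threshold is retained).
#'
#' @param subjects data.frame with a `max_displacement` column (mm).
#' @param threshold Exclusion threshold in mm (default 2.5).
#' @return The retained rows of `subjects`.
#' @export
exclude_by_motion <- function(subjects, threshold = 2.5) {
  if (!"max_displacement" %in% names(subjects)) {
    stop("'subjects' must contain a 'max_displacement' column")
  }
  if (anyNA(subjects$max_displacement)) {
    stop("missing max_displacement values")
  }
  subjects[subjects$max_displacement <= threshold, , drop = FALSE]
}

#' Fit the multivariate moderation regression
#'
#' Ordinary least squares of the retained cognitive components on a
#' brain-change measure, BFR, their interaction, and site/sex covariates
#' (plus chronological age where requested; by default age enters only the
#' brain-age model, where it controls the age bias of brain-age
#' predictions). Predictors enter uncentered. The multivariate fit is
#' per-outcome OLS on the shared design — point estimates identical to the
#' joint multivariate fit; the joint residual covariance is reported for
#' completeness.
#'
#' @param records data.frame with columns `bfr`, `site`, `sex`, the
#'   brain-change columns (`cortical_thickness`, `gm_volume_norm`,
#'   `brain_age`), optionally `age`, and outcome columns `PC1`, `PC2`, ...
#' @param brain_change One of `"thickness"`, `"gm_volume"`, `"brain_age"`.
#' @param include_chron_age Add chronological age as covariate; defaults to
#'   `TRUE` only for the brain-age model.
#' @param outcomes Character vector of outcome column names (default: all
#'   `PC*` columns).
#' @return Object of class `moderation_fit` with per-outcome coefficient
#'   tables (beta, SE, t, p), fit statistics (residual SE, R^2, adjusted
#'   R^2, F, model p), the underlying `lm` fit, and the residual
#'   covariance across outcomes.
#' @export
fit_moderation <- function(records,
                           brain_change = c("thickness", "gm_volume",
                                            "brain_age"),
                           include_chron_age = NULL,
                           outcomes = NULL) {
  brain_change <- match.arg(brain_change)
  bc_col <- switch(brain_change,
                   thickness = "cortical_thickness",
                   gm_volume = "gm_volume_norm",
                   brain_age = "brain_age")
  if (is.null(include_chron_age)) {
    include_chron_age <- identical(brain_change, "brain_age")
  }
  if (is.null(outcomes)) {
    outcomes <- grep("^PC[0-9]+$", names(records), value = TRUE)
  }
  needed <- c(bc_col, "bfr", "site", "sex", outcomes,
              if (include_chron_age) "age")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(records[needed])) stop("missing values in model columns")
  n_pred <- 5L + as.integer(include_chron_age)  # incl. intercept
  if (nrow(records) < n_pred + 10L) {
    stop("insufficient observations for the requested model")
  }

  rhs <- paste(c(bc_col, "bfr", sprintf("%s:bfr", bc_col), "site", "sex",
                 if (include_chron_age) "age"), collapse = " + ")
  fml <- stats::as.formula(sprintf("cbind(%s) ~ %s",
                                   paste(outcomes, collapse = ", "), rhs))
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)),
                            data = records)
  kap <- kappa(mm, exact = TRUE)
  if (kap > 1e10) {
    stop(sprintf("design matrix is near-collinear (condition number %.2g)",
                 kap))
  }
  fit <- stats::lm(fml, data = records)
  smry <- summary(fit)
  if (length(outcomes) == 1L) smry <- list(smry)

  coef_tables <- list()
  fit_stats <- list()
  for (j in seq_along(outcomes)) {
    s <- smry[[j]]
    ct <- as.data.frame(s$coefficients)
    names(ct) <- c("beta", "se", "t", "p")
    ct <- cbind(predictor = rownames(ct), ct, row.names = NULL)
    coef_tables[[outcomes[j]]] <- ct
    fstat <- s$fstatistic
    fit_stats[[outcomes[j]]] <- data.frame(
      residual_se = s$sigma,
      r_squared = s$r.squared,
      adj_r_squared = s$adj.r.squared,
      f = unname(fstat[1L]),
      model_p = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                          lower.tail = FALSE))
  }
  res <- stats::residuals(fit)
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  structure(
    list(model_id = brain_change,
         bc_col = bc_col,
         include_chron_age = include_chron_age,
         outcomes = outcomes,
         coefficients = coef_tables,
         fit_statistics = fit_stats,
         residual_covariance = stats::cov(res),
         n = nrow(records),
         lm_fit = fit),
    class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Moderation model (%s%s), n = %d, outcomes: %s\n\n",
    x$model_id, if (x$include_chron_age) " + chronological age" else "",
    x$n, paste(x$outcomes, collapse = ", ")))
  for (oc in x$outcomes) {
    cat(oc, "\n")
    tab <- x$coefficients[[oc]]
    tab[-1] <- lapply(tab[-1], signif, digits)
    print(tab, row.names = FALSE)
    fs <- x$fit_statistics[[oc]]
    cat(sprintf(
      "  Res. SE %.3g | R^2 %.3g | adj. R^2 %.3g | F %.4g | p %.3g\n\n",
      fs$residual_se, fs$r_squared, fs$adj_r_squared, fs$f, fs$model_p))
  }
  invisible(x)
}

#' @export
summary.moderation_fit <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.moderation_fit <- function(object, ...) {
  stats::coef(object$lm_fit)
}

#' @export
predict.moderation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$lm_fit)
  else stats::predict(object$lm_fit, newdata = newdata, ...)
}

#' @export
residuals.moderation_fit <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' Split subjects at the mean of a measure
#'
#' Values greater than or equal to the mean go to the `"high"` group, values
#' below to `"low"`.
#'
#' @param values Numeric vector (length >= 2).
#' @return Factor of `"low"` / `"high"` assignments.
#' @export
mean_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  factor(ifelse(values >= mean(values), "high", "low"),
         levels = c("low", "high"))
}

#' Split subjects at a fixed BFR threshold
#'
#' Values below `cut` form the low group; values at or above it the high
#' group. When outcome and brain-change vectors are supplied the per-group
#' linear slope of outcome on brain change is reported, the display used to
#' compare how strongly brain change tracks cognition at low vs high
#' redundancy.
#'
#' @param values BFR values in `[0, 1]`.
#' @param cut Threshold in (0, 1) (0.30 splits the study cohort roughly in
#'   half).
#' @param outcome,bc Optional outcome and brain-change vectors for per-group
#'   slopes.
#' @return List with `group` (factor), `n_low`, `n_high` and, when
#'   requested, `slope_low`, `slope_high`.
#' @export
threshold_split <- function(values, cut = 0.30, outcome = NULL, bc = NULL) {
  if (!is.numeric(cut) || length(cut) != 1L || cut <= 0 || cut >= 1) {
    stop("'cut' must lie strictly between 0 and 1")
  }
  if (any(values < 0 | values > 1)) stop("BFR values must lie in [0, 1]")
  group <- factor(ifelse(values < cut, "low", "high"),
                  levels = c("low", "high"))
  out <- list(group = group,
              n_low = sum(group == "low"),
              n_high = sum(group == "high"))
  if (!is.null(outcome) && !is.null(bc)) {
    slope_of <- function(idx) {
      if (sum(idx) < 3L) return(NA_real_)
      unname(stats::coef(stats::lm(outcome[idx] ~ bc[idx]))[2L])
    }
    out$slope_low <- slope_of(group == "low")
    out$slope_high <- slope_of(group == "high")
  }
  out
}
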