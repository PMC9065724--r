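# Distributional and mixed-effects modelling of entry-segment parameters:
# gamma fit to the expansion-accelerations, and linear mixed-effects models
# of log(rdot_e) / log(Ae_mean) with light, landing type and the kinematic
# covariates as fixed effects and day / approach / side random intercepts.

#' Fit a gamma distribution to expansion-acceleration samples
#'
#' Maximum-likelihood shape/scale fit (location fixed at 0) with asymptotic
#' 95% confidence intervals.
#'
#' @param samples positive values (1/s^2).
#' @return a list of class `"gamma_fit"`: `a` (shape), `b` (scale),
#'   `ci_a`, `ci_b` (95% CIs), `sample_median`, `n`.
#' @export
fit_gamma <- function(samples) {
  bad <- which(!is.finite(samples) | samples <= 0)
  if (length(bad))
    stop("non-positive or non-finite samples at indices: ",
         paste(head(bad, 10), collapse = ", "))
  if (length(samples) < 10L) stop("need at least 10 samples")
  # fit on mean-standardised data: better conditioned, and makes the MLE
  # scale-equivariant by construction (shape invariant, scale ~ mean)
  m <- mean(samples)
  fd <- fitdistrplus::fitdist(as.numeric(samples) / m, "gamma", method = "mle")
  shape <- unname(fd$estimate["shape"])
  rate <- unname(fd$estimate["rate"])
  sd_shape <- unname(fd$sd["shape"])
  sd_rate <- unname(fd$sd["rate"])
  z <- qnorm(0.975)
  b <- m / rate
  sd_b <- m * sd_rate / rate^2              # delta method for scale = m/rate
  structure(list(a = shape, b = b,
                 ci_a = c(shape - z * sd_shape, shape + z * sd_shape),
                 ci_b = c(b - z * sd_b, b + z * sd_b),
                 sample_median = median(samples), n = length(samples)),
            class = "gamma_fit")
}

#' @export
#' @method print gamma_fit
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> shape a = %.3f [%.3f, %.3f], scale b = %.3f [%.3f, %.3f]\n",
              x$a, x$ci_a[1], x$ci_a[2], x$b, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  n = %d, sample median = %.3f\n", x$n, x$sample_median))
  invisible(x)
}

.lmm_prepare <- function(table, response) {
  need <- c(response, "y0", "delta_re", "r_star", "light", "landing_type",
            "day", "approach_number", "landing_side")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("entries table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- table[complete.cases(table[, need]), need, drop = FALSE]
  if (any(df[[response]] <= 0) || any(df$y0 <= 0) || any(df$delta_re <= 0) ||
      any(df$r_star <= 0))
    stop("response and covariates must be positive for the log transform; ",
         "filter non-positive rows first")
  df$log_resp <- log(df[[response]])
  df$log_y0 <- log(df$y0)
  df$log_dre <- log(df$delta_re)
  df$log_rstar <- log(df$r_star)
  df$light <- factor(df$light, levels = .LIGHT_LEVELS)
  df$landing_type <- factor(df$landing_type, levels = .LANDING_TYPE_LEVELS)
  df$day <- factor(df$day)
  df$approach_number <- factor(df$approach_number)
  df$landing_side <- factor(df$landing_side)
  df
}

#' Fit the entry-segment linear mixed-effects model
#'
#' Fits, by REML, the natural-log-transformed response (expansion-
#' acceleration `rdot_e` or mean acceleration `Ae_mean`) on fixed effects
#' log(y0), light (treatment-coded against twilight), landing type
#' (against free flight), log(delta_re), log(r_star) and the
#' log(y0) x log(delta_re) interaction, with random intercepts for
#' experimental day, approach number and landing side. Singular
#' random-effect factors are dropped with a warning and the model refitted.
#'
#' p-values are large-sample normal approximations of the t-statistics.
#'
#' @param table entries data frame (see [entries_table()]); rows with
#'   non-positive response or covariates must be filtered beforehand.
#' @param response `"rdot_e"` or `"Ae_mean"`.
#' @return a list of class `"lmm_result"`: `response`, `fixed_effects`
#'   (term, estimate, SE, t, p), `random_sd` (named, incl. `residual`),
#'   `n_obs`, `model` (the underlying `lmerMod`), `data`.
#' @export
fit_lmm <- function(table, response = c("rdot_e", "Ae_mean")) {
  response <- match.arg(response)
  df <- .lmm_prepare(table, response)
  ran_terms <- c("(1 | day)", "(1 | approach_number)", "(1 | landing_side)")
  fixed <- "log_resp ~ log_y0 + light + landing_type + log_dre + log_rstar + log_y0:log_dre"
  fit_once <- function(rt) {
    fml <- stats::as.formula(paste(fixed, "+", paste(rt, collapse = " + ")))
    suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  }
  mod <- fit_once(ran_terms)
  while (lme4::isSingular(mod, tol = 1e-5) && length(ran_terms) > 1L) {
    vc <- as.data.frame(lme4::VarCorr(mod))
    vc <- vc[vc$grp != "Residual", ]
    drop_grp <- vc$grp[which.min(vc$sdcor)]
    drop_term <- ran_terms[grepl(drop_grp, ran_terms, fixed = TRUE)]
    warning("singular random-effects fit: dropping ", drop_term)
    ran_terms <- setdiff(ran_terms, drop_term)
    mod <- fit_once(ran_terms)
  }
  cf <- summary(mod)$coefficients
  fe <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                   SE = cf[, "Std. Error"], t = cf[, "t value"],
                   p = 2 * pnorm(-abs(cf[, "t value"])), row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(mod))
  random_sd <- setNames(vc$sdcor, ifelse(vc$grp == "Residual", "residual", vc$grp))
  structure(list(response = response, fixed_effects = fe,
                 random_sd = random_sd, n_obs = nrow(df),
                 model = mod, data = df),
            class = "lmm_result")
}

#' @export
#' @method print lmm_result
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> response:", x$response, " n =", x$n_obs, "\n")
  print(transform(x$fixed_effects, estimate = round(estimate, 3),
                  SE = round(SE, 3), t = round(t, 2), p = signif(p, 3)))
  cat("random-effect SDs:\n")
  print(round(x$random_sd, 4))
  invisible(x)
}

# Fixed-effect design row for one covariate setting.
.emm_row <- function(terms, y0, delta_re, r_star, light, landing_type) {
  x <- setNames(numeric(length(terms)), terms)
  x["(Intercept)"] <- 1
  x["log_y0"] <- log(y0)
  x["log_dre"] <- log(delta_re)
  x["log_rstar"] <- log(r_star)
  if (light == "medium") x["lightmedium"] <- 1
  if (light == "sunrise") x["lightsunrise"] <- 1
  if (landing_type == "after_takeoff") x["landing_typeafter_takeoff"] <- 1
  x["log_y0:log_dre"] <- log(y0) * log(delta_re)
  x
}

#' Model-predicted (estimated) means at given covariate settings
#'
#' Back-transformed predictions of the response at the requested covariate
#' settings, averaging over the random effects (random intercepts set to
#' their zero population mean), with delta-method 95% confidence intervals
#' on the log scale exponentiated to the response scale.
#'
#' Settings outside the fitted covariate range trigger a warning, not an
#' error.
#'
#' @param model an `"lmm_result"` from [fit_lmm()].
#' @param settings data frame with columns `y0`, `delta_re`, `r_star`,
#'   `light`, `landing_type` (one row per requested prediction).
#' @param level confidence level.
#' @return `settings` with added columns `emm`, `lwr`, `upr` (response
#'   scale) and `log_emm`, `log_se` (link scale).
#' @export
predict_emm <- function(model, settings, level = 0.95) {
  beta <- lme4::fixef(model$model)
  V <- as.matrix(vcov(model$model))
  rng_y0 <- range(model$data$y0)
  rng_dre <- range(model$data$delta_re)
  rng_rs <- range(model$data$r_star)
  z <- qnorm(1 - (1 - level) / 2)
  out <- settings
  out$log_emm <- NA_real_; out$log_se <- NA_real_
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    if (s$y0 < rng_y0[1] || s$y0 > rng_y0[2] ||
        s$delta_re < rng_dre[1] || s$delta_re > rng_dre[2] ||
        s$r_star < rng_rs[1] || s$r_star > rng_rs[2])
      warning("setting ", i, " extrapolates beyond the fitted covariate range")
    x <- .emm_row(names(beta), s$y0, s$delta_re, s$r_star,
                  as.character(s$light), as.character(s$landing_type))
    out$log_emm[i] <- sum(x * beta)
    out$log_se[i] <- sqrt(drop(t(x) %*% V %*% x))
  }
  out$emm <- exp(out$log_emm)
  out$lwr <- exp(out$log_emm - z * out$log_se)
  out$upr <- exp(out$log_emm + z * out$log_se)
  out
}

#' Post-hoc contrasts of the categorical conditions
#'
#' Pairwise light-condition contrasts (medium - twilight, sunrise -
#' twilight, sunrise - medium; Bonferroni-adjusted over the 3 comparisons)
#' and the landing-type contrast (after take-off - free flight; family of
#' 1), on the log-response scale.
#'
#' @param model an `"lmm_result"`.
#' @return data frame with contrast, estimate, SE, z, p_raw,
#'   p_adjusted, family.
#' @export
condition_contrasts <- function(model) {
  beta <- lme4::fixef(model$model)
  V <- as.matrix(vcov(model$model))
  cvec <- function(terms_w) {
    x <- setNames(numeric(length(beta)), names(beta))
    for (nm in names(terms_w)) x[nm] <- terms_w[[nm]]
    x
  }
  contrasts <- list(
    "medium - twilight" = cvec(list(lightmedium = 1)),
    "sunrise - twilight" = cvec(list(lightsunrise = 1)),
    "sunrise - medium" = cvec(list(lightsunrise = 1, lightmedium = -1)),
    "after_takeoff - free_flight" = cvec(list(landing_typeafter_takeoff = 1)))
  fam <- c(3, 3, 3, 1)
  rows <- lapply(seq_along(contrasts), function(i) {
    x <- contrasts[[i]]
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    zst <- est / se
    p <- 2 * pnorm(-abs(zst))
    data.frame(contrast = names(contrasts)[i], estimate = est, SE = se,
               z = zst, p_raw = p, p_adjusted = min(1, fam[i] * p),
               family = fam[i])
  })
  do.call(rbind, rows)
}
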