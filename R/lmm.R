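#' Linear mixed model for the common trend
#'
#' The first modeling stage: a Gaussian linear mixed model with a quadratic
#' time trend shared by all subjects, group dummy offsets relative to the
#' reference group, and subject-specific random intercept, slope and
#' curvature under an unstructured 3x3 covariance,
#'
#' \deqn{y_{ij} = b_0 + b_1 t + b_2 t^2 + \sum_g b_g \,\mathrm{1}[group_j = g]
#'   + u_{0j} + u_{1j} t + u_{2j} t^2 + \varepsilon_{ij}}
#'
#' where `t` is the integer time index `1..T` and `j` indexes subjects.
#' Fitting is by maximum likelihood by default so that models with different
#' fixed structures (e.g. adding a cubic term) are comparable by AIC; REML is
#' available behind a flag for less biased variance components but its
#' likelihood is not comparable across fixed structures.
#'
#' @name lmm_trend
NULL

#' Build design matrices for the trend model
#'
#' Fixed design `X` has columns (intercept, Time, Time^2, one dummy per
#' non-reference group); the random design `Z` per subject has columns
#' (intercept, Time, Time^2). The reference group's rows are all-zero in
#' the dummy block.
#'
#' @param panel a `tsgc_panel`.
#' @param include_cubic add a Time^3 column to the fixed design.
#' @return list with `X` (fixed design matrix), `Z` (random design matrix,
#'   shared columns 1/Time/Time^2), `y` (response vector), `subject`
#'   (factor aligning rows to subjects), `groups` (factor with the
#'   reference level first).
#' @export
build_design <- function(panel, include_cubic = FALSE) {
  stopifnot(inherits(panel, "tsgc_panel"))
  ref <- attr(panel, "reference")
  lev <- c(ref, setdiff(sort(unique(panel$group)), ref))
  grp <- factor(panel$group, levels = lev)
  t <- panel$time
  X <- cbind(`(Intercept)` = 1, Time = t, Time2 = t^2)
  if (include_cubic) X <- cbind(X, Time3 = t^3)
  if (length(lev) > 1L) {
    dummies <- sapply(lev[-1L], function(g) as.numeric(grp == g))
    colnames(dummies) <- paste0("group", lev[-1L])
    X <- cbind(X, dummies)
  }
  Z <- cbind(`(Intercept)` = 1, Time = t, Time2 = t^2)
  list(X = X, Z = Z, y = panel$value,
       subject = factor(panel$subject, levels = unique(panel$subject)),
       groups = grp)
}

#' Fit the mixed trend model
#'
#' Fits the quadratic-trend mixed model by ML (default) or REML through
#' [lme4::lmer()], and extracts everything downstream stages need: fixed
#' estimates with normal-reference (z) p-values, the unstructured
#' random-effect covariance, per-subject BLUPs, per-observation residuals
#' `eps_ij`, and information criteria. The AIC parameter count is the number
#' of fixed effects plus the 6 free elements of the 3x3 covariance plus the
#' residual variance.
#'
#' @param panel a `tsgc_panel`.
#' @param include_cubic include a fixed Time^3 term (candidate model for
#'   AIC comparison; random terms stay quadratic).
#' @param reml use REML instead of ML. REML fits cannot be compared by AIC.
#' @return an object of class `tsgc_lmm`; see Details.
#' @details The returned list contains `fixed` (term/estimate/se/z/p table),
#'   `random_cov`, `random_sd`, `random_cor`, `blups` (subjects x 3 matrix),
#'   `sigma2`, `residuals` (per-observation data.frame with `fitted`,
#'   conditional on the BLUPs, and `residual`), `loglik`, `aic`, `bic`,
#'   `n_obs`, `n_subjects`, `singular` (covariance estimated on the
#'   boundary), and the underlying `merMod` in `$model`.
#' @export
fit_lmm <- function(panel, include_cubic = FALSE, reml = FALSE) {
  stopifnot(inherits(panel, "tsgc_panel"))
  ref <- attr(panel, "reference")
  lev <- c(ref, setdiff(sort(unique(panel$group)), ref))
  dat <- data.frame(value = panel$value,
                    Time = as.numeric(panel$time),
                    subject = factor(panel$subject, levels = unique(panel$subject)),
                    group = factor(panel$group, levels = lev))
  dat$Time2 <- dat$Time^2
  dat$Time3 <- dat$Time^3
  n_par_fixed <- 3L + include_cubic + (length(lev) - 1L)
  if (nrow(dat) <= n_par_fixed)
    stop("not enough observations to fit the fixed effects", call. = FALSE)
  fixed_rhs <- if (include_cubic) "Time + Time2 + Time3" else "Time + Time2"
  if (length(lev) > 1L) fixed_rhs <- paste(fixed_rhs, "+ group")
  form <- stats::as.formula(paste("value ~", fixed_rhs, "+ (Time + Time2 | subject)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.scaleX = "ignore",
                            calc.derivs = FALSE)
  model <- tryCatch(
    lme4::lmer(form, data = dat, REML = reml, control = ctrl),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e),
                             call. = FALSE))

  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- beta / se
  fixed <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)

  vc <- lme4::VarCorr(model)$subject
  random_cov <- matrix(as.numeric(vc), 3L, 3L,
                       dimnames = list(rownames(vc), rownames(vc)))
  random_sd <- sqrt(diag(random_cov))
  random_cor <- stats::cov2cor(random_cov + diag(1e-300, 3L))
  blups <- as.matrix(lme4::ranef(model)$subject)

  fitted <- stats::fitted(model)
  resid_df <- data.frame(subject = as.character(dat$subject),
                         group = as.character(dat$group),
                         time = panel$time,
                         observed = dat$value,
                         fitted = as.numeric(fitted),
                         residual = as.numeric(dat$value - fitted),
                         stringsAsFactors = FALSE)

  structure(list(
    fixed = fixed,
    random_cov = random_cov,
    random_sd = random_sd,
    random_cor = random_cor,
    blups = blups,
    sigma2 = stats::sigma(model)^2,
    residuals = resid_df,
    loglik = as.numeric(stats::logLik(model)),
    aic = stats::AIC(model),
    bic = stats::BIC(model),
    n_obs = nrow(dat),
    n_subjects = nlevels(dat$subject),
    n_par = n_par_fixed + 6L + 1L,
    reml = reml,
    include_cubic = include_cubic,
    singular = lme4::isSingular(model),
    reference = ref,
    interval = attr(panel, "interval"),
    response_digest = sum(dat$value) + stats::var(dat$value),
    model = model), class = "tsgc_lmm")
}

#' Residual series of a mixed-model fit, split by subject
#'
#' @param fit a `tsgc_lmm`.
#' @return named list of numeric vectors, ordered by time index.
#' @export
residual_series <- function(fit) {
  stopifnot(inherits(fit, "tsgc_lmm"))
  rd <- fit$residuals[order(fit$residuals$subject, fit$residuals$time), ]
  split(rd$residual, rd$subject)
}

#' Rank candidate mixed-model fits by AIC
#'
#' All candidates must be ML fits of the same response; REML likelihoods are
#' not comparable across fixed structures, so mixing them is an error. Ties
#' are broken in favor of fewer parameters.
#'
#' @param fits list of `tsgc_lmm` objects.
#' @return list with `best` (the selected fit) and `ranking` (data.frame of
#'   model index, parameter count and AIC, best first).
#' @export
compare_by_aic <- function(fits) {
  if (inherits(fits, "tsgc_lmm")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "tsgc_lmm")))
  if (any(vapply(fits, function(f) isTRUE(f$reml), TRUE)))
    stop("comparability error: AIC comparison requires ML fits (found REML)",
         call. = FALSE)
  digests <- vapply(fits, function(f) f$response_digest, 0)
  if (length(unique(round(digests, 8L))) > 1L)
    stop("comparability error: fits are not on identical response data",
         call. = FALSE)
  aic <- vapply(fits, function(f) f$aic, 0)
  npar <- vapply(fits, function(f) f$n_par, 0L)
  ord <- order(aic, npar)
  ranking <- data.frame(model = ord, n_par = npar[ord], aic = aic[ord])
  list(best = fits[[ord[1L]]], ranking = ranking)
}

#' Model-summary table in the conventional mixed-model layout
#'
#' One block for fixed effects (estimate, SE, z, p) and one for the
#' random-effect variance components (variance, SD, correlations), plus
#' group/observation counts — the layout mixed-model reports in the
#' phenotyping literature use.
#'
#' @param fit a `tsgc_lmm`.
#' @return data.frame with columns `block`, `term`, `estimate`, `se`, `z`,
#'   `p`, `variance`, `sd`, `corr1`, `corr2`.
#' @export
lmm_summary_table <- function(fit) {
  stopifnot(inherits(fit, "tsgc_lmm"))
  fx <- cbind(block = "fixed", fit$fixed,
              variance = NA_real_, sd = NA_real_,
              corr1 = NA_real_, corr2 = NA_real_)
  rc <- fit$random_cor
  rnd <- data.frame(block = "random",
                    term = rownames(fit$random_cov),
                    estimate = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                    variance = diag(fit$random_cov),
                    sd = fit$random_sd,
                    corr1 = c(NA, rc[2, 1], rc[3, 1]),
                    corr2 = c(NA, NA, rc[3, 2]),
                    stringsAsFactors = FALSE)
  res <- data.frame(block = "residual", term = "sigma",
                    estimate = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                    variance = fit$sigma2, sd = sqrt(fit$sigma2),
                    corr1 = NA_real_, corr2 = NA_real_,
                    stringsAsFactors = FALSE)
  counts <- data.frame(block = "counts",
                       term = c("n_subjects", "n_obs"),
                       estimate = c(fit$n_subjects, fit$n_obs),
                       se = NA_real_, z = NA_real_, p = NA_real_,
                       variance = NA_real_, sd = NA_real_,
                       corr1 = NA_real_, corr2 = NA_real_,
                       stringsAsFactors = FALSE)
  out <- rbind(fx, rnd, res, counts)
  rownames(out) <- NULL
  out
}

#' @export
print.tsgc_lmm <- function(x, ...) {
  cat("Mixed trend model (", if (x$reml) "REML" else "ML", "), ",
      x$n_subjects, " subjects, ", x$n_obs, " observations\n", sep = "")
  cat("logLik ", format(x$loglik), "  AIC ", format(x$aic),
      "  BIC ", format(x$bic), "\n\nFixed effects:\n", sep = "")
  print(x$fixed, digits = 4, row.names = FALSE)
  cat("\nRandom-effect SDs: ", paste(format(x$random_sd, digits = 4),
                                     collapse = ", "), "\n", sep = "")
  cat("Residual SD: ", format(sqrt(x$sigma2), digits = 4), "\n", sep = "")
  if (x$singular) cat("Note: covariance estimated on the boundary (singular)\n")
  invisible(x)
}
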