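#' Fit a gamma log-link mixed model of AWP on CSFI
#'
#' Fits `AWP ~ CSFI [+ mixture + CSFI:mixture] + (1 | plot)` with a gamma
#' response and log link by Laplace-approximate maximum likelihood
#' (glmmTMB). The plot random intercept absorbs the nesting of subplots
#' within plots. Starting values for the fixed effects come from the
#' corresponding gamma GLM without the random effect, which makes the
#' optimisation deterministic and robust. Wald standard errors and z-test
#' p-values are reported on the link scale.
#'
#' Non-convergence (including rank-deficient designs such as a constant
#' CSFI column) yields a fit flagged `converged = FALSE` with diagnostics,
#' not an exception. Rows with non-positive AWP are an error: the gamma
#' support is (0, Inf) and filtering is the caller's explicit, logged step.
#'
#' @param data Data frame with columns `awp` (cm^3/yr, > 0), `csfi`,
#'   `plot_id`, and — when `interaction` or stratification is used —
#'   `mixture_type` (`"monoculture"` / `"mixture"`).
#' @param interaction Include mixture type and its interaction with CSFI as
#'   fixed effects (default `FALSE`; the plain CSFI slope model).
#' @param stratum Label recorded on the fit: `"across"`, `"mixtures"` or
#'   `"monocultures"`. Stratification itself (subsetting rows) is the
#'   caller's job; see [definition_comparison()].
#' @return A `csfi_glmm` object: `coefficients` table (term, estimate, se,
#'   p), `sd_plot`, `shape`, `r2_marginal`, `converged`, `n_obs`, `n_plots`,
#'   `stratum`, and the underlying `fit`.
#' @export
fit_csfi_glmm <- function(data, interaction = FALSE, stratum = "across") {
  stopifnot(all(c("awp", "csfi", "plot_id") %in% names(data)))
  if (any(data$awp <= 0)) {
    stop("non-positive AWP rows present; filter them (logged) before ",
         "gamma model fitting")
  }
  if (nrow(data) < 8 || length(unique(data$plot_id)) < 2) {
    stop("need >= 8 rows and >= 2 plots to fit the mixed model")
  }
  data$plot_id <- factor(data$plot_id)
  if (interaction) {
    stopifnot("mixture_type" %in% names(data))
    data$mixture_type <- factor(data$mixture_type,
                                levels = c("monoculture", "mixture"))
    fixed <- awp ~ csfi * mixture_type
  } else {
    fixed <- awp ~ csfi
  }
  form <- stats::update(fixed, . ~ . + (1 | plot_id))

  failed <- function(reason) {
    structure(list(coefficients = NULL, sd_plot = NA_real_,
                   shape = NA_real_, r2_marginal = NA_real_,
                   converged = FALSE, diagnostics = reason,
                   n_obs = nrow(data),
                   n_plots = length(unique(data$plot_id)),
                   stratum = stratum, fit = NULL),
              class = "csfi_glmm")
  }

  glm0 <- tryCatch(
    suppressWarnings(
      stats::glm(fixed, family = stats::Gamma(link = "log"), data = data)),
    error = function(e) NULL)
  start <- NULL
  if (!is.null(glm0) && all(is.finite(stats::coef(glm0)))) {
    start <- list(beta = unname(stats::coef(glm0)))
  }

  fit <- tryCatch(
    glmmTMB::glmmTMB(form, family = stats::Gamma(link = "log"), data = data,
                     start = start,
                     control = glmmTMB::glmmTMBControl(
                       optCtrl = list(iter.max = 1000, eval.max = 1000))),
    error = function(e) NULL, warning = function(w) {
      # refit without the warning handler to keep the object, but record it
      f <- suppressWarnings(
        glmmTMB::glmmTMB(form, family = stats::Gamma(link = "log"),
                         data = data, start = start))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  if (is.null(fit)) return(failed("glmmTMB error"))

  beta <- glmmTMB::fixef(fit)$cond
  sdr_ok <- isTRUE(fit$sdr$pdHess)
  conv <- isTRUE(fit$fit$convergence == 0) && sdr_ok && all(is.finite(beta))
  if (!conv) {
    out <- failed(paste0("non-convergence",
                         if (!sdr_ok) " (Hessian not positive definite)"))
    out$fit <- fit
    return(out)
  }
  sm <- summary(fit)$coefficients$cond
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL)
  sd_plot <- sqrt(glmmTMB::VarCorr(fit)$cond$plot_id[1, 1])
  shape <- 1 / glmmTMB::sigma(fit)^2  # gamma shape from glmmTMB dispersion
  obj <- structure(list(coefficients = coefs, sd_plot = sd_plot,
                        shape = shape, r2_marginal = NA_real_,
                        converged = TRUE,
                        diagnostics = attr(fit, "fit_warning") %||% "ok",
                        n_obs = nrow(data),
                        n_plots = length(unique(data$plot_id)),
                        stratum = stratum, fit = fit),
                   class = "csfi_glmm")
  obj$r2_marginal <- marginal_r2(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marginal R-squared of a gamma log-link mixed fit
#'
#' Proportion of link-scale variance attributable to the fixed effects:
#' `var(X beta) / (var(X beta) + sigma2_plot + sigma2_resid)`, where
#' `var(X beta)` is the variance of the fixed-effect linear predictor over
#' the observed design, `sigma2_plot` the random-intercept variance, and
#' `sigma2_resid` the gamma observation-level variance on the log scale —
#' `trigamma(shape)` by default (the variance of `log Y` for a gamma with
#' that shape), or the lognormal approximation `log(1 + 1/shape)` via
#' `method = "lognormal"`.
#'
#' @param fit A converged `csfi_glmm`.
#' @param method Residual-variance formulation, `"trigamma"` (default) or
#'   `"lognormal"`.
#' @return The marginal R-squared in [0, 1]; `NA` for non-converged fits.
#' @export
marginal_r2 <- function(fit, method = c("trigamma", "lognormal")) {
  method <- match.arg(method)
  if (!inherits(fit, "csfi_glmm")) stop("expected a csfi_glmm fit")
  if (!fit$converged) return(NA_real_)
  tmb <- fit$fit
  X <- stats::model.matrix(stats::formula(tmb, fixed.only = TRUE)[-2],
                           tmb$frame)
  eta_fixed <- as.numeric(X %*% glmmTMB::fixef(tmb)$cond)
  var_f <- stats::var(eta_fixed) * (length(eta_fixed) - 1) / length(eta_fixed)
  var_plot <- fit$sd_plot^2
  var_resid <- switch(method,
    trigamma = trigamma(fit$shape),
    lognormal = log1p(1 / fit$shape))
  var_f / (var_f + var_plot + var_resid)
}

#' Per-definition, per-stratum model comparison report
#'
#' Reproduces the comparison layout of the analysis: for each canopy space
#' definition, the gamma log-link mixed model of AWP on CSFI is fitted
#' across all subplots, for mixtures only, and for monocultures only
#' (stratified fits drop the mixture factor), and the across-subplots model
#' with the CSFI x mixture-type interaction supplies the interaction
#' p-value. A stratum with fewer than 2 plots or 8 rows is reported as a
#' flagged missing row.
#'
#' @param model_table Long data frame with columns `definition`, `plot_id`,
#'   `subplot_id`, `mixture_type`, `csfi`, `awp` (one row per subplot and
#'   definition; AWP > 0 rows only).
#' @return List with `coefficients` (definition, stratum, term, estimate,
#'   se, p, r2_marginal, n, converged) and `interactions` (definition,
#'   p_interaction).
#' @export
definition_comparison <- function(model_table) {
  need <- c("definition", "plot_id", "mixture_type", "csfi", "awp")
  stopifnot(all(need %in% names(model_table)))
  defs <- intersect(CANOPY_DEFINITIONS, unique(model_table$definition))
  strata <- c(across = NA, mixtures = "mixture", monocultures = "monoculture")
  rows <- list(); inter <- list()
  for (def in defs) {
    sub <- model_table[model_table$definition == def, , drop = FALSE]
    for (snm in names(strata)) {
      d <- if (is.na(strata[[snm]])) sub else
        sub[sub$mixture_type == strata[[snm]], , drop = FALSE]
      row <- data.frame(definition = def, stratum = snm, term = "csfi",
                        estimate = NA_real_, se = NA_real_, p = NA_real_,
                        r2_marginal = NA_real_, n = nrow(d),
                        converged = FALSE)
      if (nrow(d) >= 8 && length(unique(d$plot_id)) >= 2) {
        f <- fit_csfi_glmm(d, interaction = FALSE, stratum = snm)
        if (f$converged) {
          cf <- f$coefficients[f$coefficients$term == "csfi", ]
          row$estimate <- cf$estimate; row$se <- cf$se; row$p <- cf$p
          row$r2_marginal <- f$r2_marginal
          row$converged <- TRUE
        }
      }
      rows[[paste(def, snm)]] <- row
    }
    p_int <- NA_real_
    if (length(unique(sub$mixture_type)) == 2) {
      fi <- fit_csfi_glmm(sub, interaction = TRUE, stratum = "across")
      if (fi$converged) {
        ci <- fi$coefficients[grepl(":", fi$coefficients$term), ]
        if (nrow(ci) == 1) p_int <- ci$p
      }
    }
    inter[[def]] <- data.frame(definition = def, p_interaction = p_int)
  }
  list(coefficients = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       interactions = do.call(rbind, c(inter, list(make.row.names = FALSE))))
}

#' @export
print.csfi_glmm <- function(x, ...) {
  cat("Gamma log-link mixed model of AWP on CSFI (stratum: ", x$stratum,
      ")\n", sep = "")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  plot SD %.4f | gamma shape %.3f | marginal R2 %.3f | n = %d obs, %d plots\n",
              x$sd_plot, x$shape, x$r2_marginal, x$n_obs, x$n_plots))
  invisible(x)
}
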