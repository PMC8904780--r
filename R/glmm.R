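#' Fit a negative-binomial random-intercept mixed model
#'
#' The computational core shared by the moving-window scan and the
#' trophic-cascade suite: a negative-binomial (log link, Var = mu +
#' mu^2/theta) regression of a count response on ordered fixed-effect
#' covariates with a single random intercept per grouping level,
#' maximizing the marginal likelihood by the Laplace approximation
#' (`engine = "glmmTMB"`, the default) or by adaptive Gauss--Hermite
#' quadrature with `nAGQ` nodes (`engine = "lme4"`; `nAGQ = 1` is the
#' Laplace approximation). With `group = NULL` the model reduces to a
#' plain NB regression (MASS::glm.nb).
#'
#' @param response name of the count column.
#' @param fixed character vector of fixed-effect covariate names (may be
#'   empty for an intercept-only model), entered in this order.
#' @param data data.frame; the response must be nonnegative integers.
#' @param group name of the random-intercept grouping column (default
#'   `"plot"`), or `NULL` for no random effect.
#' @param engine `"glmmTMB"`, `"lme4"` or `"glm"`.
#' @param nAGQ quadrature nodes for the lme4 engine.
#' @return object of class `nbglmm_fit`: `beta`, `se`, `z`, `p_value`
#'   (Wald, two-sided normal), `theta`, `sigma_group`, `logLik`,
#'   `n_obs`, `converged`, plus the design matrix and response used.
#' @export
fit_nb_glmm <- function(response, fixed = character(0), data,
                        group = "plot",
                        engine = c("glmmTMB", "lme4", "glm"),
                        nAGQ = 1L) {
  engine <- match.arg(engine)
  y <- data[[response]]
  if (is.null(y)) stop(sprintf("response '%s' not in data", response),
                       call. = FALSE)
  if (any(y < 0) || any(y != round(y)))
    stop("response must be nonnegative integers", call. = FALSE)
  if (nrow(data) < 10L)
    stop("need at least 10 observations", call. = FALSE)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (is.null(group)) engine <- "glm"
  X <- model.matrix(as.formula(paste("~", rhs)), data)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient", call. = FALSE)

  if (engine == "glm") {
    ff <- as.formula(paste(response, "~", rhs))
    fit <- suppressWarnings(MASS::glm.nb(ff, data = data))
    sm <- summary(fit)
    beta <- coef(fit)
    se <- sm$coefficients[, "Std. Error"]
    out <- list(beta = beta, se = se, theta = fit$theta, sigma_group = 0,
                logLik = as.numeric(logLik(fit)),
                converged = isTRUE(fit$converged), engine = engine)
  } else if (engine == "glmmTMB") {
    ff <- as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
    fit <- suppressWarnings(glmmTMB::glmmTMB(ff, data = data,
                                             family = glmmTMB::nbinom2))
    sm <- summary(fit)$coefficients$cond
    beta <- glmmTMB::fixef(fit)$cond
    se <- sm[, "Std. Error"]
    vc <- glmmTMB::VarCorr(fit)$cond[[group]]
    pd <- fit$sdr$pdHess %||% TRUE
    out <- list(beta = beta, se = se, theta = stats::sigma(fit),
                sigma_group = sqrt(as.numeric(vc)),
                logLik = as.numeric(logLik(fit)),
                converged = isTRUE(fit$fit$convergence == 0) && isTRUE(pd),
                engine = engine)
  } else {
    ff <- as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer.nb(ff, data = data, nAGQ = nAGQ)))
    sm <- summary(fit)$coefficients
    beta <- lme4::fixef(fit)
    se <- sm[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(beta = beta, se = se,
                theta = lme4::getME(fit, "glmer.nb.theta"),
                sigma_group = vc$sdcor[vc$grp == group][1],
                logLik = as.numeric(logLik(fit)),
                converged = length(fit@optinfo$conv$lme4$messages %||%
                                     character(0)) == 0L,
                engine = engine)
  }
  out$z <- out$beta / out$se
  out$p_value <- 2 * pnorm(-abs(out$z))
  out$n_obs <- nrow(data)
  out$response <- response
  out$fixed <- fixed
  out$X <- X
  out$y <- y
  # population-level (random effect at zero) fitted means
  out$mu_pop <- as.numeric(exp(X %*% out$beta[colnames(X)]))
  out$poisson_limit <- is.finite(out$theta) && out$theta > 1e4
  class(out) <- "nbglmm_fit"
  out
}

#' @export
print.nbglmm_fit <- function(x, ...) {
  cat(sprintf("NB GLMM (%s): %s ~ %s; theta = %.3f, sigma_group = %.3f%s\n",
              x$engine, x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$theta, x$sigma_group,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$z,
                    p_value = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Negative-binomial deviance
#'
#' 2 * sum(y log(y / mu) - (y + theta) log((y + theta) / (mu + theta))),
#' with the first term zero where y = 0.
#'
#' @param y observed counts.
#' @param mu fitted means.
#' @param theta NB dispersion.
#' @return the deviance (scalar).
#' @export
nb_deviance <- function(y, mu, theta) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(t1 - t2)
}

#' Deviance-based adjusted R-squared for the fixed effects
#'
#' R2 = 1 - D_full / D_null, where D is the NB deviance evaluated at the
#' population-level fitted means (random effect at zero) and the full
#' model's dispersion estimate is used for both models; the null model
#' has intercept-only fixed effects but the same random-effect structure.
#' The small-sample (Ezekiel) adjustment is R2_adj = 1 - (1 - R2) *
#' (n - 1) / (n - p - 1) with p the number of non-intercept fixed
#' effects. R2_adj can be negative for uninformative covariates; the raw
#' value is reported with a flag.
#'
#' @param fit full-model `nbglmm_fit`.
#' @param null_fit intercept-only `nbglmm_fit` on the same data.
#' @return list with `r2`, `r2_adj`, `n`, `p`, `negative_adj` flag.
#' @export
adjusted_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "nbglmm_fit"), inherits(null_fit, "nbglmm_fit"))
  if (fit$n_obs != null_fit$n_obs)
    stop("full and null fits use different data", call. = FALSE)
  theta <- fit$theta
  d_full <- nb_deviance(fit$y, fit$mu_pop, theta)
  d_null <- nb_deviance(null_fit$y, null_fit$mu_pop, theta)
  if (d_null <= 0)
    stop("null deviance is zero: R2 undefined", call. = FALSE)
  r2 <- 1 - d_full / d_null
  n <- fit$n_obs
  p <- ncol(fit$X) - 1L
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(r2 = r2, r2_adj = r2_adj, n = n, p = p,
       negative_adj = r2_adj < 0)
}
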