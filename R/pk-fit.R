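#' Fit the population two-compartment infusion model
#'
#' Maximum-likelihood estimation of `CL`, `V1`, `Q`, `V2` (log scale) and the
#' proportional residual SD from timed concentrations of several subjects on
#' known infusion regimens. Two estimation modes:
#'
#' * `"pooled"` — naive pooling: one parameter vector for all subjects, no
#'   between-subject variability. Fast and robust; consistent for the typical
#'   values when between-subject variability is moderate.
#' * `"laplace"` — marginal likelihood with lognormal subject random effects
#'   on `CL` (and `V1` when `re = c("CL","V1")`), integrated out by the
#'   Laplace approximation: for each subject the random-effect mode is found
#'   by an inner optimization and the Gaussian curvature correction applied.
#'
#' The residual model is proportional: observation = prediction x (1 + e),
#' e ~ Normal(0, cv^2), so each observation's SD is cv x prediction
#' (prediction-based weighting).
#'
#' @param observations Data frame with columns `subject_id`, `time_h`,
#'   `conc_mg_per_L`.
#' @param regimens Either a single `dose_regimen` shared by all subjects or a
#'   named list of `dose_regimen`s keyed by subject id.
#' @param init A `pk_params` giving starting values (its `cv_prop` seeds the
#'   residual SD; 0 is replaced by 0.2).
#' @param method `"pooled"` or `"laplace"`.
#' @param re Random-effect parameters for the Laplace mode, subset of
#'   `c("CL", "V1")`.
#' @param one_compartment Fit the degenerate model without a peripheral
#'   compartment (drops `Q`, `V2`); used for model comparison by AIC.
#' @param control List with `rel_tol` (default 1e-8) and `max_iter`
#'   (default 500) passed to the outer optimizer.
#' @return A list of class `pk_fit`: `params` (a `pk_params` with the
#'   estimated typical values and omegas), `logLik`, `AIC`, `n_obs`,
#'   `n_subjects`, `converged`, `se` (approximate log-scale standard errors),
#'   `method`, and `message` from the optimizer.
#' @export
fit_population <- function(observations, regimens, init = pk_params_default(),
                           method = c("pooled", "laplace"),
                           re = "CL", one_compartment = FALSE,
                           control = list(rel_tol = 1e-8, max_iter = 500)) {
  method <- match.arg(method)
  stopifnot(all(c("subject_id", "time_h", "conc_mg_per_L") %in% names(observations)))
  subjects <- unique(observations$subject_id)
  if (length(subjects) < 2L) stop("need >= 2 subjects")
  obs_by <- split(observations, observations$subject_id)
  if (any(vapply(obs_by, nrow, 0L) < 2L)) stop("need >= 2 samples per subject")
  get_reg <- function(id) {
    if (inherits(regimens, "dose_regimen")) regimens
    else regimens[[as.character(id)]]
  }

  cv0 <- if (init$cv_prop > 0) init$cv_prop else 0.2
  if (one_compartment) {
    theta0 <- c(lCL = log(init$CL), lV1 = log(init$V1), lcv = log(cv0))
    build <- function(th) pk_params(exp(th[["lCL"]]), exp(th[["lV1"]]))
  } else {
    theta0 <- c(lCL = log(init$CL), lV1 = log(init$V1),
                lQ = log(max(init$Q, 1e-3)), lV2 = log(max(init$V2, 1e-3)),
                lcv = log(cv0))
    build <- function(th) pk_params(exp(th[["lCL"]]), exp(th[["lV1"]]),
                                    exp(th[["lQ"]]), exp(th[["lV2"]]))
  }

  # -loglik of one subject given its structural params and cv
  nll_subject <- function(p, cv, ob, reg) {
    pred <- pk_concentration(ob$time_h, reg, p)
    if (any(pred <= 0)) return(1e10) # observation before any dose: undefined weight
    sd <- cv * pred
    -sum(stats::dnorm(ob$conc_mg_per_L, mean = pred, sd = sd, log = TRUE))
  }

  scale_params <- function(p, eta) {
    # apply subject random effects (log scale) to the typical values
    pk_params(p$CL * exp(if ("CL" %in% names(eta)) eta[["CL"]] else 0),
              p$V1 * exp(if ("V1" %in% names(eta)) eta[["V1"]] else 0),
              p$Q, p$V2)
  }

  if (method == "pooled") {
    objective <- function(th) {
      p <- tryCatch(build(th), error = function(e) NULL)
      if (is.null(p)) return(1e10)
      cv <- exp(th[["lcv"]])
      sum(vapply(subjects, function(id) {
        nll_subject(p, cv, obs_by[[as.character(id)]], get_reg(id))
      }, 0))
    }
    n_par <- length(theta0)
  } else {
    re <- match.arg(re, c("CL", "V1"), several.ok = TRUE)
    theta0 <- c(theta0, stats::setNames(log(rep(0.25, length(re))),
                                        paste0("lom_", re)))
    d_re <- length(re)
    # warm starts: the per-subject mode moves little between outer steps
    warm <- new.env(parent = emptyenv())
    objective <- function(th) {
      p <- tryCatch(build(th), error = function(e) NULL)
      if (is.null(p)) return(1e10)
      cv <- exp(th[["lcv"]])
      om <- exp(th[paste0("lom_", re)])
      total <- 0
      for (id in subjects) {
        key <- as.character(id)
        ob <- obs_by[[key]]; reg <- get_reg(id)
        joint <- function(eta) {
          names(eta) <- re
          nll_subject(scale_params(p, eta), cv, ob, reg) -
            sum(stats::dnorm(eta, 0, om, log = TRUE))
        }
        eta0 <- if (!is.null(warm[[key]])) warm[[key]] else rep(0, d_re)
        if (d_re == 1L) {
          opt <- newton_1d(joint, eta0)
          mode <- opt$x; f_mode <- opt$f; h <- matrix(opt$h, 1, 1)
        } else {
          inner <- stats::nlminb(eta0, joint,
                                 control = list(rel.tol = 1e-8,
                                                iter.max = 200))
          mode <- inner$par; f_mode <- inner$objective
          h <- numeric_hessian(joint, mode)
        }
        warm[[key]] <- mode
        det_h <- det(as.matrix(h))
        if (!is.finite(det_h) || det_h <= 0) return(1e10)
        # Laplace: -log integral ~ joint(mode) - (d/2) log(2 pi) + 0.5 log|H|
        total <- total + f_mode - 0.5 * d_re * log(2 * pi) + 0.5 * log(det_h)
      }
      total
    }
    n_par <- length(theta0)
  }

  # box constraints keep the parameters in a physically sensible range and
  # stop the residual SD collapsing to zero on noise-free data
  lower <- rep(-12, length(theta0)); upper <- rep(12, length(theta0))
  lower[names(theta0) == "lcv"] <- log(1e-4)
  fit <- stats::nlminb(theta0, objective, lower = lower, upper = upper,
                       control = list(rel.tol = control$rel_tol,
                                      iter.max = control$max_iter,
                                      eval.max = 4 * control$max_iter))
  # nlminb reports codes > 0 for benign stopping messages too; accept the
  # relative/X-convergence conditions as converged
  converged <- is.finite(fit$objective) &&
    (fit$convergence == 0 ||
       grepl("relative convergence|X-convergence|x convergence",
             fit$message %||% "", ignore.case = TRUE))
  th <- fit$par
  p_hat <- build(th)
  p_hat$cv_prop <- exp(th[["lcv"]])
  if (method == "laplace") {
    p_hat$omega <- stats::setNames(exp(th[paste0("lom_", re)]), re)
  } else {
    p_hat$omega <- c(CL = 0, V1 = 0)
  }
  se <- tryCatch(suppressWarnings({
    h <- numeric_hessian(objective, th)
    v <- diag(solve(h))
    ifelse(v > 0, sqrt(v), NA_real_)
  }), error = function(e) rep(NA_real_, length(th)))
  names(se) <- names(th)
  structure(list(params = p_hat, logLik = -fit$objective,
                 AIC = 2 * fit$objective + 2 * n_par,
                 n_obs = nrow(observations), n_subjects = length(subjects),
                 converged = converged, se = se, method = method,
                 message = fit$message),
            class = "pk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# safeguarded 1-D Newton minimizer with numeric derivatives; returns the
# mode, objective value and second derivative (reused for the Laplace
# curvature term). Falls back to optimize() when curvature is unusable.
newton_1d <- function(f, x0, h = 1e-4, tol = 1e-7, max_steps = 20) {
  x <- x0
  f0 <- f(x)
  for (s in seq_len(max_steps)) {
    fp <- f(x + h); fm <- f(x - h)
    g <- (fp - fm) / (2 * h)
    hess <- (fp - 2 * f0 + fm) / h^2
    if (!is.finite(g) || !is.finite(hess) || hess <= 0) {
      opt <- stats::optimize(f, c(x - 2, x + 2), tol = tol)
      x <- opt$minimum; f0 <- opt$objective
      fp <- f(x + h); fm <- f(x - h)
      hess <- max((fp - 2 * f0 + fm) / h^2, 1e-8)
      return(list(x = x, f = f0, h = hess))
    }
    step <- g / hess
    step <- max(min(step, 1), -1)  # trust region: one SD of eta at a time
    x_new <- x - step
    f_new <- f(x_new)
    while (f_new > f0 + 1e-12 && abs(step) > 1e-10) {  # backtrack
      step <- step / 2
      x_new <- x - step
      f_new <- f(x_new)
    }
    converged <- abs(x_new - x) < tol
    x <- x_new; f0 <- f_new
    if (converged) break
  }
  fp <- f(x + h); fm <- f(x - h)
  list(x = x, f = f0, h = max((fp - 2 * f0 + fm) / h^2, 1e-8))
}

# central-difference Hessian; adequate for the smooth likelihoods here
numeric_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h^2)
      }
    }
  }
  H
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (", x$method, " mode)\n", sep = "")
  cat(sprintf("  CL = %.4g L/h, V1 = %.4g L, Q = %.4g L/h, V2 = %.4g L\n",
              x$params$CL, x$params$V1, x$params$Q, x$params$V2))
  cat(sprintf("  cv_prop = %.3f; omega: %s\n", x$params$cv_prop,
              paste(names(x$params$omega), round(x$params$omega, 3),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, %d obs / %d subjects, converged: %s\n",
              x$logLik, x$AIC, x$n_obs, x$n_subjects, x$converged))
  invisible(x)
}
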