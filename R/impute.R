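#' Multiple imputation by chained equations
#'
#' Normal-linear chained-equation imputation for a numeric data frame with
#' missing cells. Missing entries are initialised by random draws from each
#' column's observed values, then for a fixed number of cycles each
#' incomplete column is regressed on all other columns (current completed
#' values); regression coefficients and the residual SD are drawn from their
#' Bayesian posterior (flat prior) and the missing cells replaced by
#' posterior-predictive draws. Observed cells are never altered. Repeating
#' with the same seed reproduces the imputations exactly.
#'
#' @param data Data frame; columns used for imputation must be numeric.
#'   Complete non-numeric columns (e.g. arm, sex factors) are carried along
#'   as predictors via dummy coding but never imputed.
#' @param n_imputations Number of completed datasets (default 5).
#' @param n_cycles Chained-equation cycles per imputation (default 10).
#' @param seed Integer seed.
#' @return A list of `n_imputations` completed data frames.
#' @export
impute_chained <- function(data, n_imputations = 5, n_cycles = 10, seed = 1L) {
  stopifnot(is.data.frame(data), n_imputations >= 1)
  num_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  other <- setdiff(names(data), num_cols)
  if (any(vapply(data[other], anyNA, TRUE))) {
    stop("non-numeric columns must be complete (they are predictors only)")
  }
  miss <- vapply(data[num_cols], anyNA, TRUE)
  n_obs <- vapply(data[num_cols], function(x) sum(!is.na(x)), 0L)
  if (any(n_obs < 2L)) {
    stop(sprintf("column '%s' has fewer than 2 observed values",
                 num_cols[which(n_obs < 2L)[1L]]))
  }
  if (!any(miss)) return(replicate(n_imputations, data, simplify = FALSE))
  set.seed(seed)

  # fixed dummy coding of complete non-numeric predictors
  extra <- if (length(other)) {
    stats::model.matrix(~ ., data = data[other])[, -1, drop = FALSE]
  } else NULL

  lapply(seq_len(n_imputations), function(m) {
    comp <- data
    for (j in num_cols[miss]) {
      na_j <- is.na(comp[[j]])
      comp[[j]][na_j] <- sample(comp[[j]][!na_j], sum(na_j), replace = TRUE)
    }
    for (cyc in seq_len(n_cycles)) {
      for (j in num_cols[miss]) {
        na_j <- is.na(data[[j]])
        preds <- setdiff(num_cols, j)
        X <- cbind(1, as.matrix(comp[preds]))
        if (!is.null(extra)) X <- cbind(X, extra)
        # drop aliased columns to keep the draw well defined
        qrX <- qr(X)
        X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
        y <- comp[[j]]
        yo <- y[!na_j]; Xo <- X[!na_j, , drop = FALSE]
        nf <- length(yo); p <- ncol(X)
        if (nf <= p) { # too few cases to regress: fall back to mean + noise
          mu <- mean(yo); s <- stats::sd(yo)
          comp[[j]][na_j] <- stats::rnorm(sum(na_j), mu, max(s, 1e-8))
          next
        }
        xtx <- crossprod(Xo)
        bhat <- solve(xtx, crossprod(Xo, yo))
        ssr <- sum((yo - Xo %*% bhat)^2)
        sig <- sqrt(ssr / stats::rchisq(1, df = nf - p))
        bstar <- bhat + backsolve(chol(xtx), stats::rnorm(p)) * sig
        comp[[j]][na_j] <- as.numeric(X[na_j, , drop = FALSE] %*% bstar) +
          stats::rnorm(sum(na_j), 0, sig)
      }
    }
    comp
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and standard errors into a pooled
#' estimate, total SE (within + between-imputation variance with the finite-m
#' correction), Barnard-Rubin adjusted degrees of freedom, and a two-sided
#' p-value.
#'
#' @param est Numeric vector of per-imputation estimates.
#' @param se Per-imputation standard errors.
#' @param df_com Complete-data degrees of freedom of the analysis model.
#' @return A list: `estimate`, `se`, `df`, `statistic`, `p`, `between_var`,
#'   `within_var`.
#' @export
rubin_pool <- function(est, se, df_com) {
  m <- length(est)
  stopifnot(length(se) == m, m >= 1)
  qbar <- mean(est)
  ubar <- mean(se^2)
  b <- if (m > 1) stats::var(est) else 0
  t_var <- ubar + (1 + 1 / m) * b
  if (m == 1 || b == 0) {
    df <- df_com
  } else {
    r <- (1 + 1 / m) * b / ubar
    df_old <- (m - 1) * (1 + 1 / r)^2
    lam <- (1 + 1 / m) * b / t_var
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
    df <- 1 / (1 / df_old + 1 / df_obs)
  }
  stat <- qbar / sqrt(t_var)
  list(estimate = qbar, se = sqrt(t_var), df = df, statistic = stat,
       p = 2 * stats::pt(-abs(stat), df), between_var = b, within_var = ubar)
}
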