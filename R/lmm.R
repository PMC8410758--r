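#' Random-intercept linear mixed model fitted by maximum likelihood
#'
#' Fits \eqn{y = X\beta + b_{line} + \epsilon} with one Gaussian random
#' intercept per cell line, \eqn{b \sim N(0, \sigma_{line}^2)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, by full maximum likelihood (not
#' REML, so that likelihood-ratio tests between models differing in fixed
#' effects are valid). The likelihood is profiled: for a candidate variance
#' ratio \eqn{\lambda = \sigma_{line}^2/\sigma^2} the fixed effects are the
#' generalized-least-squares solution and \eqn{\sigma^2} has a closed form;
#' the outer 1-D search over \eqn{\lambda} runs on a log-spaced grid
#' (1e-6 to 1e3, 60 points, plus the \eqn{\lambda = 0} boundary) refined by
#' golden-section search. Everything is deterministic.
#'
#' @param data A data.frame of organoid records, e.g. one week's slice of
#'   [gen_morphometry()] output.
#' @param response One of `"log_area"`, `"log_volume"`,
#'   `"log_total_cells"`, `"labeling_index"`, or the name of a numeric
#'   column in `data` (prefix `log_` to model its log).
#' @param include_genotype If `TRUE` genotype enters as a fixed effect;
#'   if `FALSE` the model is intercept-only (the LRT null).
#' @param group Name of the grouping (cell line) column.
#' @param genotype_col Name of the genotype column.
#' @return An object of class `lmm_ri` with components `beta`, `se`,
#'   `sigma_line`, `sigma_resid`, `lambda`, `loglik`, `n_obs`, `n_groups`,
#'   `fitted`, `residuals`, `response`, `call`.
#' @seealso [lrt_genotype()] for the genotype likelihood-ratio test.
#' @export
fit_lmm <- function(data, response, include_genotype = TRUE,
                    group = "line_id", genotype_col = "genotype") {
  y <- resolve_response(data, response)
  if (!group %in% names(data)) stop_cfg("grouping column '%s' not found", group)
  g <- factor(data[[group]])
  if (include_genotype) {
    if (!genotype_col %in% names(data))
      stop_cfg("genotype column '%s' not found", genotype_col)
    geno <- factor(data[[genotype_col]])
    if ("control" %in% levels(geno))
      geno <- stats::relevel(geno, ref = "control")
    if (nlevels(geno) < 2L)
      stop_cfg("genotype has a single level: design is singular")
    X <- stats::model.matrix(~geno)
    colnames(X) <- c("(Intercept)", paste0("genotype", levels(geno)[-1L]))
  } else {
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  }
  ok <- stats::complete.cases(y, X, g)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; g <- droplevels(g[ok])
  n <- length(y)
  if (n < ncol(X) + 1L) stop_cfg("too few observations for the design")

  prof <- make_profiler(y, X, g)

  # lambda = 0 boundary plus a log grid, then golden-section refinement
  grid <- c(0, exp(seq(log(1e-6), log(1e3), length.out = 60L)))
  ll <- vapply(grid, function(l) prof(l)$loglik, numeric(1L))
  i <- which.max(ll)
  lambda <- grid[i]
  if (i > 1L) {  # interior (or right-edge) maximum: refine on log scale
    lo <- if (i == 2L) log(grid[2L] / 10) else log(grid[i - 1L])
    hi <- if (i == length(grid)) log(grid[i] * 10) else log(grid[i + 1L])
    opt <- stats::optimize(function(ll_) prof(exp(ll_))$loglik,
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    if (opt$objective >= ll[i]) lambda <- exp(opt$maximum)
    # keep the boundary if it is as good as the refined interior point
    if (prof(0)$loglik >= prof(lambda)$loglik) lambda <- 0
  }
  fit <- prof(lambda)

  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$cov_beta))
  names(se) <- colnames(X)
  fitted <- drop(X %*% fit$beta)
  structure(list(beta = beta, se = se,
                 sigma_line = sqrt(lambda * fit$sigma2),
                 sigma_resid = sqrt(fit$sigma2),
                 lambda = lambda, loglik = fit$loglik,
                 n_obs = n, n_groups = nlevels(g),
                 fitted = fitted, residuals = y - fitted,
                 group = g, X = X, y = y,
                 response = if (is.character(response)) response else "response",
                 include_genotype = include_genotype,
                 call = match.call()),
            class = "lmm_ri")
}

# map a response alias onto the data's columns
resolve_response <- function(data, response) {
  if (is.numeric(response)) return(as.numeric(response))
  aliases <- list(area = c("area_mm2", "area"),
                  volume = c("volume_mm3", "volume"),
                  total_cells = c("total_cells", "n_cells"))
  take_log <- startsWith(response, "log_")
  base <- sub("^log_", "", response)
  cand <- c(response, base, aliases[[base]] %||% character())
  col <- cand[cand %in% names(data)][1L]
  if (is.na(col)) stop_cfg("response '%s' not found in data", response)
  v <- as.numeric(data[[col]])
  if (take_log && !col %in% c(response)) {
    if (any(v <= 0, na.rm = TRUE)) stop_cfg("log response requires positive values")
    v <- log(v)
  }
  v
}

# closure evaluating the profile likelihood at a variance ratio lambda;
# V = sigma2 * (I + lambda * J) blockwise per group, inverted analytically
make_profiler <- function(y, X, g) {
  idx <- split(seq_along(y), g)
  n <- length(y)
  p <- ncol(X)
  XtX_i <- lapply(idx, function(ii) crossprod(X[ii, , drop = FALSE]))
  Xs_i <- lapply(idx, function(ii) colSums(X[ii, , drop = FALSE]))
  Xty_i <- lapply(idx, function(ii) crossprod(X[ii, , drop = FALSE], y[ii]))
  ys_i <- vapply(idx, function(ii) sum(y[ii]), numeric(1L))
  yty_i <- vapply(idx, function(ii) sum(y[ii]^2), numeric(1L))
  ni <- lengths(idx)

  function(lambda) {
    ci <- unname(lambda / (1 + lambda * ni))
    A <- matrix(0, p, p); b <- numeric(p)
    for (k in seq_along(idx)) {
      A <- A + XtX_i[[k]] - ci[k] * tcrossprod(Xs_i[[k]])
      b <- b + drop(Xty_i[[k]]) - ci[k] * Xs_i[[k]] * ys_i[k]
    }
    beta <- solve(A, b)
    # weighted residual quadratic form, groupwise
    quad <- 0
    for (k in seq_along(idx)) {
      ii <- idx[[k]]
      r <- y[ii] - drop(X[ii, , drop = FALSE] %*% beta)
      quad <- quad + sum(r^2) - ci[k] * sum(r)^2
    }
    sigma2 <- unname(quad) / n
    loglik <- -0.5 * (n * log(2 * pi * sigma2) + n + sum(log1p(lambda * ni)))
    list(beta = beta, sigma2 = sigma2, loglik = loglik,
         cov_beta = sigma2 * solve(A))
  }
}

#' @export
print.lmm_ri <- function(x, ...) {
  cat("Random-intercept linear mixed model (ML)\n")
  cat(sprintf("  response: %s, n = %d observations in %d lines\n",
              x$response, x$n_obs, x$n_groups))
  cat("  fixed effects:\n")
  print(round(x$beta, 5))
  cat(sprintf("  sigma_line = %.5g, sigma_resid = %.5g, logLik = %.4f\n",
              x$sigma_line, x$sigma_resid, x$loglik))
  invisible(x)
}

#' @export
summary.lmm_ri <- function(object, ...) {
  z <- object$beta / object$se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma_line = object$sigma_line,
              sigma_resid = object$sigma_resid, loglik = object$loglik,
              n_obs = object$n_obs, n_groups = object$n_groups,
              response = object$response)
  class(out) <- "summary.lmm_ri"
  out
}

#' @export
print.summary.lmm_ri <- function(x, ...) {
  cat("Random-intercept LMM (ML) on", x$response, "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nRandom effects: sigma_line = %.5g, sigma_resid = %.5g\n",
              x$sigma_line, x$sigma_resid))
  cat(sprintf("logLik = %.4f  (n = %d, lines = %d)\n",
              x$loglik, x$n_obs, x$n_groups))
  invisible(x)
}

#' @export
coef.lmm_ri <- function(object, ...) object$beta

#' @export
logLik.lmm_ri <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta) + 2L, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.lmm_ri <- function(object, ...) object$fitted

#' @export
residuals.lmm_ri <- function(object, ...) object$residuals

#' @export
simulate.lmm_ri <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ng <- object$n_groups
  out <- replicate(nsim, {
    b <- stats::rnorm(ng, 0, object$sigma_line)
    object$fitted + b[as.integer(object$group)] +
      stats::rnorm(object$n_obs, 0, object$sigma_resid)
  })
  as.data.frame(out)
}

#' Likelihood-ratio test for a genotype effect
#'
#' Compares the full random-intercept model (genotype as fixed effect) with
#' the nested intercept-only model, both fitted by full ML on the same data:
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{null})} on `df` degrees of freedom
#' (the number of genotype contrasts, 1 for two genotypes), with the
#' chi-square upper-tail p-value. Tiny negative statistics from optimizer
#' round-off (> -1e-8) are clamped to 0; anything more negative is an error.
#'
#' @inheritParams fit_lmm
#' @return A list of class `lrt_result` with `chi2`, `df`, `p_value`,
#'   `fit_full`, `fit_null`.
#' @export
lrt_genotype <- function(data, response, group = "line_id",
                         genotype_col = "genotype") {
  y <- resolve_response(data, response)
  if (stats::var(y, na.rm = TRUE) == 0)  # constant response: no evidence either way
    return(structure(list(chi2 = 0, df = 1L, p_value = 1,
                          fit_full = NULL, fit_null = NULL),
                     class = "lrt_result"))
  full <- fit_lmm(data, response, include_genotype = TRUE,
                  group = group, genotype_col = genotype_col)
  null <- fit_lmm(data, response, include_genotype = FALSE,
                  group = group, genotype_col = genotype_col)
  chi2 <- 2 * (full$loglik - null$loglik)
  if (chi2 < -1e-8)
    stop_cfg("negative LR statistic (%.3g): optimizer failure", chi2)
  chi2 <- max(chi2, 0)
  df <- length(full$beta) - length(null$beta)
  structure(list(chi2 = chi2, df = df,
                 p_value = chi2_upper_tail(chi2, df),
                 fit_full = full, fit_null = null),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi2, x$p_value))
  invisible(x)
}
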