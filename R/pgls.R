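#' Phylogenetic generalized least squares fit
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V)` with the Brownian-motion
#' rate `sigma2` profiled by maximum likelihood:
#' `beta-hat = (X' V^-1 X)^-1 X' V^-1 y`, `sigma2-hat = RSS_V / n`.
#' Standard errors use the unbiased residual variance (`RSS_V / (n - p)`).
#' A Shapiro-Wilk test on the V-whitened residuals reports the residual
#' normality check.
#'
#' @param y response vector (e.g. derived-allele frequency, raw or logit).
#' @param X predictor matrix including the intercept column, or `NULL` for
#'   intercept only.
#' @param V error covariance structure over observations (from
#'   [bm_covariance()]); positive definite after jitter.
#' @param jitter ridge added as `jitter * mean(diag(V))` when the Cholesky
#'   factorization fails.
#' @param label model label carried into summaries.
#' @return a `pgls_fit`: coefficients with standard errors, `sigma2` (ML),
#'   `loglik`, `aic` (`2k - 2 loglik`, k = coefficients + 1 variance
#'   parameter), `shapiro_p`, fitted values and whitened residuals.
#' @export
pgls_fit <- function(y, X = NULL, V = diag(length(y)), jitter = 1e-10,
                     label = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) stop("dimension mismatch")
  L <- tryCatch(chol(V), error = function(e) chol(V + jitter * mean(diag(V)) * diag(n)))
  # whiten: solve L' z = x  (V = L'L with R's upper-triangular chol)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  qr_wX <- qr(wX)
  if (qr_wX$rank < ncol(X)) {
    stop(sprintf("singular X'V^-1X (condition number %.3g)", kappa(wX)))
  }
  beta <- qr.coef(qr_wX, wy)
  resid_w <- wy - wX %*% beta
  rss <- sum(resid_w^2)
  p <- ncol(X)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdetV / 2
  XtX_inv <- chol2inv(qr.R(qr_wX))
  se <- sqrt(diag(XtX_inv) * rss / (n - p))
  names(beta) <- names(se) <- colnames(X)
  shap <- if (n >= 3 && n <= 5000 && stats::sd(resid_w) > 0)
    tryCatch(stats::shapiro.test(as.numeric(resid_w))$p.value,
             error = function(e) NA_real_) else NA_real_
  structure(list(coefficients = beta, se = se, sigma2 = sigma2,
                 loglik = loglik, aic = 2 * (p + 1) - 2 * loglik,
                 n = n, k = p + 1, shapiro_p = shap,
                 fitted = drop(X %*% beta), residuals_whitened = drop(resid_w),
                 predictors = setdiff(colnames(X), "(Intercept)"),
                 label = label %||% paste(setdiff(colnames(X), "(Intercept)"),
                                          collapse = "+")),
            class = "pgls_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("pgls_fit [%s]: n = %d, loglik = %.3f, AIC = %.3f\n",
              if (nzchar(x$label)) x$label else "intercept", x$n, x$loglik, x$aic))
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat(sprintf("sigma2 (ML) = %.4g; Shapiro-Wilk residual p = %.3g\n",
              x$sigma2, x$shapiro_p))
  invisible(x)
}

#' Likelihood-ratio test between nested PGLS fits
#'
#' @param null_fit,full_fit [pgls_fit()] objects on the same data; the null
#'   predictor set must be nested in the full set.
#' @return list with `lr` (= 2 * (loglik_full - loglik_null)), `df`
#'   (difference in coefficient count) and chi-square `p`.
#' @export
likelihood_ratio_test <- function(null_fit, full_fit) {
  if (null_fit$n != full_fit$n) stop("fits are on different data")
  if (!all(null_fit$predictors %in% full_fit$predictors))
    stop("models are not nested")
  df <- (full_fit$k - 1) - (null_fit$k - 1)
  if (df < 0) stop("models are not nested")
  lr <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p = p)
}

#' Akaike weights and per-predictor summed weights over a model set
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min AIC`; a predictor's weight is the sum of weights
#' of the models containing it.
#'
#' @param fits list of [pgls_fit()] objects on identical data.
#' @return list with `models` (data.frame: label, aic, delta, weight) and
#'   `predictor_weights` (named vector).
#' @export
akaike_model_average <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 models")
  aic <- vapply(fits, `[[`, 0, "aic")
  labels <- vapply(fits, `[[`, "", "label")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  preds <- unique(unlist(lapply(fits, `[[`, "predictors")))
  pw <- vapply(preds, function(pr)
    sum(w[vapply(fits, function(f) pr %in% f$predictors, TRUE)]), 0)
  list(models = data.frame(label = labels, aic = aic, delta = delta,
                           weight = w, row.names = NULL),
       predictor_weights = pw)
}

#' Fit the cline model set on a dataset and tree
#'
#' Convenience wrapper fitting the null (intercept-only) model and all
#' predictor subsets of {latitude, temperature} under the Brownian
#' covariance of the supplied tree, with the likelihood-ratio test of the
#' full vs null model and Akaike weights over the set.
#'
#' @param cline data.frame with `population`, `frequency`, `latitude_deg`,
#'   `temp_c` (as produced by [simulate_cline()]).
#' @param tree a `phylo` whose tips match `cline$population`.
#' @param response `"logit"` (default) models logit-frequency;
#'   `"raw"` models the frequency directly.
#' @return list with `fits` (null, latitude, temperature, full), `lrt`
#'   (full vs null), and `akaike` (from [akaike_model_average()]).
#' @export
fit_cline_models <- function(cline, tree, response = c("logit", "raw")) {
  response <- match.arg(response)
  if (!all(tree$tip.label %in% cline$population))
    stop("tree tips and cline populations must match")
  cline <- cline[match(tree$tip.label, cline$population), ]
  V <- bm_covariance(tree)[cline$population, cline$population]
  y <- if (response == "logit") logit(pmin(pmax(cline$frequency, 1e-6), 1 - 1e-6))
       else cline$frequency
  n <- nrow(cline)
  Xi <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Xl <- cbind(Xi, latitude = cline$latitude_deg)
  Xt <- cbind(Xi, temperature = cline$temp_c)
  Xf <- cbind(Xi, latitude = cline$latitude_deg, temperature = cline$temp_c)
  fits <- list(null = pgls_fit(y, Xi, V, label = "null"),
               latitude = pgls_fit(y, Xl, V, label = "latitude"),
               temperature = pgls_fit(y, Xt, V, label = "temperature"),
               full = pgls_fit(y, Xf, V, label = "latitude+temperature"))
  list(fits = fits, lrt = likelihood_ratio_test(fits$null, fits$full),
       akaike = akaike_model_average(fits))
}

#' Leave-one-out stability of the full cline model
#'
#' Refits the full model dropping one population (pruning its tip) at a
#' time and reports each latitude slope with the min/max envelope.
#'
#' @inheritParams fit_cline_models
#' @return list with `slopes` (data.frame: left_out, slope) and `range`.
#' @export
leave_one_out_stability <- function(cline, tree, response = c("logit", "raw")) {
  response <- match.arg(response)
  if (nrow(cline) < 4) stop("need at least 4 populations")
  slopes <- vapply(cline$population, function(pop) {
    sub <- cline[cline$population != pop, ]
    tr <- ape::drop.tip(tree, pop)
    if (is.null(tr) || length(tr$tip.label) < 3) return(NA_real_)
    fit <- fit_cline_models(sub, tr, response)$fits$full
    unname(fit$coefficients["latitude"])
  }, 0)
  kept <- !is.na(slopes)
  if (any(!kept)) warning("skipped deletions leaving < 3 tips: ",
                          paste(cline$population[!kept], collapse = ", "))
  list(slopes = data.frame(left_out = cline$population, slope = slopes,
                           row.names = NULL),
       range = range(slopes[kept]))
}
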