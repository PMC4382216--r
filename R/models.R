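#' Center the fixed covariates of a daily-range table
#'
#' Subtracts the mean from every covariate column; a factor-like sex column
#' is coded 0/1 first. Constant columns are centered to all-zero and
#' flagged. The report of means allows back-transformation of intercepts.
#'
#' @param records data frame with columns `bat_id`, `log_area` and the
#'   covariates in `terms`.
#' @param terms covariate names (default the four candidates).
#' @return list with `data` (centered copy) and `means` (named vector);
#'   attribute `constant` names any constant columns.
#' @export
center_covariates <- function(records,
                              terms = c("disturbance", "day", "moon", "sex")) {
  stopifnot(nrow(records) >= 2, all(terms %in% names(records)))
  constant <- character(0)
  means <- numeric(0)
  for (t in terms) {
    v <- records[[t]]
    if (is.factor(v) || is.character(v))
      v <- as.numeric(factor(v)) - 1 # 0/1 coding before centering
    if (stats::sd(v) == 0) constant <- c(constant, t)
    means[t] <- mean(v)
    records[[t]] <- v - means[t]
  }
  out <- list(data = records, means = means)
  attr(out, "constant") <- constant
  out
}

#' Random-intercept Gaussian mixed model by profiled maximum likelihood
#'
#' Fits `y = X beta + b_group + e`, `b ~ N(0, sigma_b^2)`,
#' `e ~ N(0, sigma_e^2)` by ML. The likelihood is profiled down to the
#' single variance ratio `lambda = sigma_b^2 / sigma_e^2`: at each lambda,
#' `beta` is the GLS solution and `sigma_e^2` has a closed form, so the fit
#' is a deterministic one-dimensional optimisation over
#' `log(lambda) in [-12, 12]`.
#'
#' @param records data frame with `log_area` (response), `bat_id`
#'   (grouping factor) and covariate columns.
#' @param terms character vector of fixed-effect terms (possibly empty for
#'   the intercept-only model).
#' @param response name of the response column (default `"log_area"`).
#' @param group name of the grouping column (default `"bat_id"`).
#' @param bounds profiling bounds on `log(lambda)` (default `c(-12, 12)`).
#' @param tol optimisation tolerance (default 1e-10).
#' @return object of class `lmm_fit`: `terms`, `beta`, `se` (GLS standard
#'   errors), `sigma_b2`, `sigma_e2`, `loglik`, `n`, `K` (parameters:
#'   fixed effects + 2 variances), `fitted_fixed` (X beta), `boundary`.
#' @export
fit_lmm <- function(records, terms = character(0), response = "log_area",
                    group = "bat_id", bounds = c(-12, 12), tol = 1e-10) {
  y <- records[[response]]
  g <- factor(records[[group]])
  n <- length(y)
  if (nlevels(g) < 2) stop("need >= 2 groups for a random intercept")
  X <- stats::model.matrix(
    stats::reformulate(if (length(terms)) terms else "1"), data = records)
  if (qr(X)$rank < ncol(X)) stop("rank deficiency in the fixed-effect design")
  if (n <= ncol(X) + 2) stop("too few observations for this model")

  idx <- split(seq_len(n), g)
  nj <- unname(lengths(idx))

  profile <- function(loglam) {
    lam <- exp(loglam)
    # V_j = I + lam J ; V_j^{-1} = I - lam/(1 + lam n_j) J (Woodbury)
    w <- lam / (1 + lam * nj)
    Vx <- X
    Vy <- y
    for (j in seq_along(idx)) {
      ii <- idx[[j]]
      Vx[ii, ] <- X[ii, , drop = FALSE] -
        w[j] * matrix(colSums(X[ii, , drop = FALSE]),
                      nrow = nj[j], ncol = ncol(X), byrow = TRUE)
      Vy[ii] <- y[ii] - w[j] * sum(y[ii])
    }
    XtVX <- crossprod(X, Vx)
    beta <- solve(XtVX, crossprod(X, Vy))
    r <- y - X %*% beta
    rVr <- 0
    for (j in seq_along(idx)) {
      ii <- idx[[j]]
      rVr <- rVr + sum(r[ii]^2) - w[j] * sum(r[ii])^2
    }
    sigma_e2 <- rVr / n
    logdetV <- sum(log1p(lam * nj))
    loglik <- -n / 2 * (log(2 * pi) + log(sigma_e2) + 1) - logdetV / 2
    list(loglik = loglik, beta = drop(beta), sigma_e2 = sigma_e2,
         XtVX = XtVX, lam = lam)
  }

  opt <- stats::optimize(function(l) -profile(l)$loglik,
                         interval = bounds, tol = tol)
  boundary <- min(abs(opt$minimum - bounds)) < 1e-3
  best <- profile(opt$minimum)
  # the sigma_b = 0 boundary (lambda = 0) in exact closed form
  ols <- stats::lm.fit(X, y)
  rss <- sum(ols$residuals^2)
  ll0 <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  if (ll0 >= best$loglik) {
    best <- list(loglik = ll0, beta = ols$coefficients,
                 sigma_e2 = rss / n, XtVX = crossprod(X), lam = 0)
    boundary <- FALSE
  }

  se <- sqrt(diag(solve(best$XtVX)) * best$sigma_e2)
  fit <- list(terms = terms, beta = best$beta, se = se,
              sigma_b2 = best$lam * best$sigma_e2,
              sigma_e2 = best$sigma_e2,
              loglik = best$loglik, n = n,
              K = length(best$beta) + 2L,
              fitted_fixed = drop(X %*% best$beta),
              boundary = boundary)
  class(fit) <- "lmm_fit"
  if (boundary && fit$sigma_b2 > 1e-4)
    warning("variance-ratio profile hit its upper bound; fit may not have converged")
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> terms: %s | logLik %.3f | sigma_b^2 %.4g | sigma_e^2 %.4g\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "(intercept only)",
              x$loglik, x$sigma_b2, x$sigma_e2))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n - K - 1)`, where `K` counts the
#' fixed-effect coefficients (including the intercept) plus the two
#' variance parameters.
#'
#' @param fit an `lmm_fit` (or any list with `loglik`, `K`, `n`).
#' @return numeric AICc.
#' @export
aicc <- function(fit) {
  K <- fit$K; n <- fit$n
  if (n - K - 1 <= 0) stop("AICc undefined: n <= K + 1")
  -2 * fit$loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc_values numeric vector.
#' @return list with `delta` (AICc differences from the best model) and
#'   `weight` (normalized `exp(-delta/2)`).
#' @export
akaike_weights <- function(aicc_values) {
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' All-subset model set over the four daily-range covariates
#'
#' Fits all `2^p` subsets of the candidate terms by ML, ranks them by AICc
#' and identifies the top set within `cutoff` AICc of the best model.
#'
#' @param records centered daily-range table (see [center_covariates()]).
#' @param terms candidate terms (default the four daily-range covariates).
#' @param cutoff top-set delta-AICc cutoff (default 2).
#' @return object of class `model_set`: `fits` (list of `lmm_fit`), `table`
#'   (data frame `model`, `K`, `r2c`, `aicc`, `delta`, `weight`,
#'   `weight_acc`, sorted by AICc), `top_set` (indices into `fits`).
#' @export
all_subsets <- function(records,
                        terms = c("disturbance", "day", "moon", "sex"),
                        cutoff = 2) {
  subsets <- lapply(0:(2^length(terms) - 1), function(m)
    terms[bitwAnd(m, 2^(seq_along(terms) - 1)) > 0])
  fits <- lapply(subsets, function(s) fit_lmm(records, s))
  a <- vapply(fits, aicc, numeric(1))
  wts <- akaike_weights(a)
  ord <- order(a)
  tab <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept)",
      character(1)),
    K = vapply(fits, `[[`, integer(1), "K"),
    r2c = vapply(fits, conditional_r2, numeric(1)),
    aicc = a, delta = wts$delta, weight = wts$weight
  )[ord, ]
  tab$weight_acc <- cumsum(tab$weight)
  rownames(tab) <- NULL
  structure(list(fits = fits[ord], table = tab,
                 top_set = which(tab$delta <= cutoff), cutoff = cutoff),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("<model_set> all-subset AICc ranking\n")
  print(transform(x$table, r2c = round(r2c, 2), aicc = round(aicc, 1),
                  delta = round(delta, 2), weight = round(weight, 2),
                  weight_acc = round(weight_acc, 2)), ...)
  invisible(x)
}

#' Multimodel-averaged coefficients
#'
#' Averages coefficients over a scope of models with renormalized Akaike
#' weights. In `mode = "conditional"` (natural averaging) each term is
#' averaged over the scoped models that contain it; in `mode = "full"`
#' models without the term contribute 0. Unconditional standard errors use
#' `sqrt(sum w (se^2 + (beta - mean)^2))`; relative importance is always
#' the summed weight over the full model set. Confidence intervals are
#' `estimate +/- ci_multiplier * SE`.
#'
#' @param set a `model_set`.
#' @param scope `"delta2"` (the top set, default) or `"all"`.
#' @param mode `"conditional"` (default) or `"full"`.
#' @param ci_multiplier normal-quantile multiplier (default 1.96).
#' @return data frame `term`, `estimate`, `unconditional_se`,
#'   `rel_importance`, `ci_low`, `ci_high` (intercept first).
#' @export
model_average <- function(set, scope = c("delta2", "all"),
                          mode = c("conditional", "full"),
                          ci_multiplier = 1.96) {
  scope <- match.arg(scope); mode <- match.arg(mode)
  idx <- if (scope == "delta2") set$top_set else seq_along(set$fits)
  w <- set$table$weight[idx] / sum(set$table$weight[idx])
  fits <- set$fits[idx]
  all_terms <- c("(Intercept)",
                 unique(unlist(lapply(set$fits, `[[`, "terms"))))
  rows <- lapply(all_terms, function(t) {
    beta <- vapply(fits, function(f) {
      b <- f$beta[t]; if (is.na(b)) 0 else unname(b) }, numeric(1))
    se <- vapply(fits, function(f) {
      s <- f$se[t]; if (is.na(s)) 0 else unname(s) }, numeric(1))
    has <- vapply(fits, function(f)
      t == "(Intercept)" || t %in% f$terms, logical(1))
    if (mode == "conditional") {
      if (!any(has)) return(NULL) # absent from every scoped model
      wt <- w[has] / sum(w[has]); beta <- beta[has]; se <- se[has]
    } else wt <- w
    est <- sum(wt * beta)
    use <- sqrt(sum(wt * (se^2 + (beta - est)^2)))
    imp <- if (t == "(Intercept)") NA_real_ else
      sum(set$table$weight[vapply(set$fits, function(f)
        t %in% f$terms, logical(1))])
    data.frame(term = t, estimate = est, unconditional_se = use,
               rel_importance = imp,
               ci_low = est - ci_multiplier * use,
               ci_high = est + ci_multiplier * use)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional R-squared of a random-intercept fit
#'
#' Variance explained jointly by the fixed and random effects:
#' `(var(X beta) + sigma_b^2) / (var(X beta) + sigma_b^2 + sigma_e^2)`.
#'
#' @param fit an `lmm_fit`.
#' @return numeric in \[0, 1\].
#' @export
conditional_r2 <- function(fit) {
  vf <- stats::var(fit$fitted_fixed)
  tot <- vf + fit$sigma_b2 + fit$sigma_e2
  if (tot <= 0) stop("undefined: zero total variance")
  (vf + fit$sigma_b2) / tot
}

#' Variance inflation factors
#'
#' `VIF_t = 1 / (1 - R^2_t)` from the least-squares regression of each
#' term on the remaining terms. Perfect collinearity yields `Inf` with a
#' warning.
#'
#' @param records data frame holding the covariates.
#' @param terms covariate names (>= 2).
#' @return named numeric vector.
#' @export
vif <- function(records, terms = c("disturbance", "day", "moon", "sex")) {
  stopifnot(length(terms) >= 2, all(terms %in% names(records)))
  out <- vapply(terms, function(t) {
    f <- stats::reformulate(setdiff(terms, t), response = t)
    r2 <- summary(stats::lm(f, data = records))$r.squared
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity involving term '", t, "'")
      return(Inf)
    }
    1 / (1 - r2)
  }, numeric(1))
  out
}

#' Pearson correlation between log-transformed sizes and shape ratios
#'
#' Correlates `log(areas)` with `ratios`; the 95% CI uses the Fisher
#' z-transform and the two-sided p-value the t-statistic on `n - 2`
#' degrees of freedom. The coefficient is invariant to the logarithm base.
#'
#' @param areas positive values (e.g. home-range areas, ha).
#' @param ratios same-length values (e.g. compactness ratios).
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_log_correlation <- function(areas, ratios, conf = 0.95) {
  stopifnot(length(areas) == length(ratios), all(areas > 0))
  n <- length(areas)
  if (n < 4) stop("need >= 4 observations")
  la <- log(areas)
  if (stats::sd(la) == 0 || stats::sd(ratios) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(la, ratios)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
}
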