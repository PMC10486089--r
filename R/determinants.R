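#' Person-level agreement outcome
#'
#' The determinant analyses model *agreement* between the most permissive
#' administrative definition (30-year window) and self-reported
#' physician-diagnosed asthma: `TRUE` when the two sources concur (both yes or
#' both no), `FALSE` when they disagree, `NA` (excluded downstream) when
#' self-report is missing.
#'
#' @param admin Logical administrative status (complete).
#' @param self Logical self-report, possibly `NA`.
#' @return Logical vector.
#' @export
#' @examples
#' agreement_outcome(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, NA))
agreement_outcome <- function(admin, self) {
  if (anyNA(admin)) stop("administrative status must be complete",
                         call. = FALSE)
  admin == self
}

#' Weighted logistic regression with linearized variance
#'
#' Fits a design-weighted logistic regression: coefficients solve the
#' weighted score equations (iteratively reweighted least squares via
#' [stats::glm()] with a quasibinomial family), and the covariance is the
#' Taylor-linearization sandwich `B^-1 M B^-1`, where `B` is the weighted
#' information and `M` the outer product of per-person weighted score
#' contributions ([sandwich::vcovHC()] with `type = "HC0"`). Coefficients are
#' invariant to rescaling all weights by a constant.
#'
#' @param formula Model formula; categorical covariates are reference-coded.
#' @param data Data frame; rows with missing model variables are dropped.
#' @param weights Positive design weights aligned with `data`
#'   (default unit weights).
#' @return A `weighted_logit` object: `coef`, `vcov` (sandwich), `or_table`
#'   (per-coefficient OR with 95% CI and z p-value), `term_tests` (multi-df
#'   Wald test per model term on the sandwich covariance), `n`, plus the
#'   underlying `glm` fit.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200))
#' fit_weighted_logistic(y ~ x, d)
fit_weighted_logistic <- function(formula, data, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data), all(weights > 0))
  data <- as.data.frame(data)
  data$.w <- weights
  fit <- stats::glm(formula, family = stats::quasibinomial(), data = data,
                    weights = .w)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
  }
  if (!fit$converged ||
      (length(beta) > 1 && max(abs(beta[-1])) > 15)) {
    worst <- names(beta[-1])[which.max(abs(beta[-1]))]
    stop("weighted logistic fit did not converge (possible separation in '",
         worst, "')", call. = FALSE)
  }
  V <- sandwich::vcovHC(fit, type = "HC0")
  se <- sqrt(diag(V))
  or_table <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    or_lower = exp(unname(beta) - 1.96 * se),
    or_upper = exp(unname(beta) + 1.96 * se),
    p = 2 * stats::pnorm(-abs(unname(beta) / se)))
  structure(list(coef = beta, vcov = V, or_table = or_table,
                 term_tests = wald_term_tests(fit, V),
                 n = stats::nobs(fit), fit = fit, formula = formula),
            class = "weighted_logit")
}

# Multi-degree-of-freedom Wald chi-square per model term, using the `assign`
# attribute of the model matrix to group the reference-coded columns of each
# categorical variable.
wald_term_tests <- function(fit, V) {
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  beta <- stats::coef(fit)
  rows <- lapply(seq_along(labels), function(i) {
    idx <- which(asgn == i)
    b <- beta[idx]
    W <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    tibble::tibble(variable = labels[i], df = length(idx), chisq = W,
                   p = stats::pchisq(W, length(idx), lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.weighted_logit <- function(x, ...) {
  cat(sprintf("Weighted logistic fit (n = %d), sandwich variance\n", x$n))
  print(as.data.frame(x$or_table), digits = 3)
  invisible(x)
}

#' Purposeful selection of determinants
#'
#' Staged variable selection: (1) fit each candidate univariably and keep
#' those with a multi-df Wald p-value below `threshold` (0.25 by default, the
#' deliberately liberal screening level); (2) fit the initial multivariable
#' model with all kept candidates; (3) refit retaining only the candidates
#' whose multivariable Wald p-value is below `threshold`. Every decision is
#' recorded in the trace.
#'
#' @param data Data frame containing `outcome` and the candidates.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param candidates Character vector of candidate covariate names.
#' @param weights Design weights.
#' @param threshold Screening p-value threshold.
#' @param strict Use strict `<` (default) rather than `<=` at the threshold.
#' @return List with `trace` (tibble: variable, univariable_p, entered,
#'   multivariable_p, retained), `univariable` (list of fits), `initial` and
#'   `final` (`weighted_logit` or `NULL` when no candidate enters).
#' @export
purposeful_selection <- function(data, outcome, candidates, weights = NULL,
                                 threshold = 0.25, strict = TRUE) {
  passes <- function(p) if (strict) p < threshold else p <= threshold
  uni <- lapply(candidates, function(v) {
    tryCatch(
      fit_weighted_logistic(
        stats::reformulate(v, response = outcome), data, weights),
      error = function(e) {
        warning("candidate '", v, "' dropped at the univariable stage: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  })
  names(uni) <- candidates
  uni_p <- vapply(candidates, function(v) {
    if (is.null(uni[[v]])) NA_real_ else uni[[v]]$term_tests$p[1]
  }, numeric(1))
  entered <- !is.na(uni_p) & passes(uni_p)
  trace <- tibble::tibble(variable = candidates, univariable_p = uni_p,
                          entered = entered,
                          multivariable_p = NA_real_, retained = FALSE)
  if (!any(entered)) {
    warning("no candidate passed univariable screening; intercept-only model",
            call. = FALSE)
    final <- fit_weighted_logistic(
      stats::reformulate("1", response = outcome), data, weights)
    return(list(trace = trace, univariable = uni, initial = NULL,
                final = final))
  }
  initial <- fit_weighted_logistic(
    stats::reformulate(candidates[entered], response = outcome), data,
    weights)
  mv_p <- setNames(initial$term_tests$p, initial$term_tests$variable)
  trace$multivariable_p[entered] <- mv_p[trace$variable[entered]]
  retained <- entered & passes(dplyr::coalesce(trace$multivariable_p, Inf))
  trace$retained <- retained
  final <- if (any(retained)) {
    fit_weighted_logistic(
      stats::reformulate(candidates[retained], response = outcome), data,
      weights)
  } else {
    warning("no candidate retained at the multivariable stage; intercept-only model",
            call. = FALSE)
    fit_weighted_logistic(stats::reformulate("1", response = outcome), data,
                          weights)
  }
  list(trace = trace, univariable = uni, initial = initial, final = final)
}

#' Single stochastic imputation of categorical covariates
#'
#' For each variable with missing values, missing entries are drawn from the
#' weighted category distribution of the complete cases within the cell
#' defined by (outcome, sampling stratum); a cell without complete cases
#' falls back to the overall weighted distribution. A variable that is 100%
#' missing is an error.
#'
#' @param data Data frame.
#' @param vars Character vector of categorical columns to impute.
#' @param outcome,stratum Column names conditioning the draws.
#' @param weights Design weights.
#' @return Completed data frame.
#' @export
impute_categorical <- function(data, vars, outcome, stratum,
                               weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  cell <- interaction(data[[outcome]], data[[stratum]], drop = TRUE)
  for (v in vars) {
    x <- data[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x))) stop("variable '", v, "' is 100% missing",
                            call. = FALSE)
    lev <- if (is.factor(x)) levels(x) else sort(unique(x[!is.na(x)]))
    wdist <- function(idx) {
      tab <- vapply(lev, function(l) {
        sum(weights[idx][x[idx] == l], na.rm = TRUE)
      }, numeric(1))
      if (sum(tab) <= 0) NULL else tab / sum(tab)
    }
    overall <- wdist(which(!is.na(x)))
    for (cl in levels(cell)) {
      miss <- which(is.na(x) & cell == cl)
      if (length(miss) == 0) next
      comp <- which(!is.na(x) & cell == cl)
      pr <- wdist(comp) %||% overall
      x[miss] <- sample(lev, length(miss), replace = TRUE, prob = pr)
    }
    data[[v]] <- x
  }
  data
}

#' Rubin's rules over a list of fits
#'
#' Pools coefficient vectors and covariance matrices across multiply-imputed
#' fits: pooled estimate is the mean, pooled covariance the mean
#' within-imputation covariance plus `(1 + 1/m)` times the between-imputation
#' covariance of the estimates (zero when `m = 1`).
#'
#' @param fits List of `weighted_logit` fits on identically-specified models.
#' @return A `pooled_logit` object with `coef`, `vcov`, `or_table`, `m`,
#'   `within`, `between`.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  stopifnot(m >= 1)
  coefs <- do.call(rbind, lapply(fits, function(f) f$coef))
  qbar <- colMeans(coefs)
  W <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / m
  B <- if (m == 1) 0 * W else stats::cov(coefs)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(diag(Tv))
  or_table <- tibble::tibble(
    term = names(qbar), estimate = unname(qbar), se = unname(se),
    or = exp(unname(qbar)),
    or_lower = exp(unname(qbar) - 1.96 * se),
    or_upper = exp(unname(qbar) + 1.96 * se),
    p = 2 * stats::pnorm(-abs(unname(qbar) / se)))
  structure(list(coef = qbar, vcov = Tv, or_table = or_table, m = m,
                 within = W, between = B),
            class = "pooled_logit")
}

#' @export
print.pooled_logit <- function(x, ...) {
  cat(sprintf("Rubin-pooled weighted logistic fit over %d imputation(s)\n",
              x$m))
  print(as.data.frame(x$or_table), digits = 3)
  invisible(x)
}

#' Multiply impute, fit, and pool
#'
#' Draws `m` completed datasets with [impute_categorical()], fits the weighted
#' logistic model on each, and pools by Rubin's rules. With no missing data
#' every completed dataset is identical and the pooled fit equals the single
#' fit exactly.
#'
#' @param data Data frame.
#' @param formula Model formula.
#' @param weights Design weights.
#' @param stratum Name of the sampling-stratum column.
#' @param outcome Name of the outcome column (defaults to the formula LHS).
#' @param m Number of imputations (study convention: 20).
#' @param seed Optional integer seed for the imputation draws.
#' @return A `pooled_logit`.
#' @export
impute_and_pool <- function(data, formula, weights = NULL, stratum,
                            outcome = all.vars(formula)[1], m = 20,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vars <- setdiff(all.vars(formula), outcome)
  fits <- lapply(seq_len(m), function(i) {
    completed <- impute_categorical(data, vars, outcome, stratum, weights)
    fit_weighted_logistic(formula, completed, weights)
  })
  pool_rubin(fits)
}
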