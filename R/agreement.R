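#' Point estimate with a 95% confidence interval
#'
#' @param estimate,lower,upper Numbers with `lower <= estimate <= upper`
#'   after clipping to `range`.
#' @param range Valid range to clip the interval to (e.g. `c(0, 1)` for
#'   proportions, `c(-1, 1)` for kappa).
#' @return An `estimate_ci` list.
#' @export
estimate_ci <- function(estimate, lower, upper, range = c(-Inf, Inf)) {
  lower <- max(range[1], min(lower, estimate))
  upper <- min(range[2], max(upper, estimate))
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = 0.95), class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  cat(sprintf("%.3f (95%% CI: %.3f-%.3f)\n", x$estimate, x$lower, x$upper))
  invisible(x)
}

#' Weighted 2x2 cross-classification of two binary sources
#'
#' Builds the agreement table between administrative case status (`admin`) and
#' self-reported status (`self`). Cell `a` is admin+/self+, `b` admin+/self-,
#' `c` admin-/self+, `d` admin-/self-. Persons with missing self-report are
#' dropped pairwise; a missing administrative status is an error because the
#' claims source is complete by construction. Cell proportions are
#' design-weighted; `n_actual` (the count of retained respondents, not the
#' weight total) is the effective sample size used in all CI formulas.
#'
#' @param admin Logical vector of administrative case status.
#' @param self Logical vector of self-reported status (may contain `NA`).
#' @param weights Optional positive design weights; `NULL` for unit weights.
#' @return An `agreement_table`: raw counts `a,b,c,d`, weighted proportions
#'   `p_a,p_b,p_c,p_d`, and `n_actual`.
#' @export
#' @examples
#' build_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
build_table <- function(admin, self, weights = NULL) {
  stopifnot(length(admin) == length(self))
  if (anyNA(admin)) stop("administrative status must be complete",
                         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(admin))
  stopifnot(length(weights) == length(admin), all(weights > 0))
  ok <- !is.na(self)
  if (!any(ok)) stop("empty agreement table: no paired observations",
                     call. = FALSE)
  admin <- admin[ok]; self <- self[ok]; w <- weights[ok]
  cells <- list(a = admin & self, b = admin & !self,
                c = !admin & self, d = !admin & !self)
  counts <- vapply(cells, sum, integer(1))
  wsum <- vapply(cells, function(i) sum(w[i]), numeric(1))
  props <- wsum / sum(w)
  structure(list(a = counts[["a"]], b = counts[["b"]], c = counts[["c"]],
                 d = counts[["d"]],
                 p_a = props[["a"]], p_b = props[["b"]], p_c = props[["c"]],
                 p_d = props[["d"]], n_actual = sum(ok)),
            class = "agreement_table")
}

#' Build an agreement table directly from cell counts
#'
#' Convenience constructor for published 2x2 tables where only the raw cells
#' are available; proportions are the unit-weight `count / n`.
#'
#' @param a,b,c,d Cell counts (admin+/self+, admin+/self-, admin-/self+,
#'   admin-/self-).
#' @return An `agreement_table`.
#' @export
#' @examples
#' table_from_counts(741, 154, 66, 679)
table_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) stop("empty agreement table", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d,
                 p_a = a / n, p_b = b / n, p_c = c / n, p_d = d / n,
                 n_actual = n),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("2x2 agreement table (n = %d)\n", x$n_actual))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(admin = c("+", "-"), self = c("+", "-")))
  print(m)
  invisible(x)
}

check_table <- function(tab) {
  stopifnot(inherits(tab, "agreement_table"))
  if (tab$n_actual == 0) stop("empty agreement table", call. = FALSE)
  invisible(tab)
}

#' Proportion of overall agreement
#'
#' `p_a + p_d` on the weighted proportions, with a normal-approximation 95%
#' CI using the actual number of respondents as the effective sample size,
#' clipped to `[0, 1]`.
#'
#' @param tab An `agreement_table`.
#' @return An [estimate_ci()].
#' @export
overall_agreement <- function(tab) {
  check_table(tab)
  p <- tab$p_a + tab$p_d
  se <- sqrt(p * (1 - p) / tab$n_actual)
  estimate_ci(p, p - 1.96 * se, p + 1.96 * se, range = c(0, 1))
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` evaluated on the
#' weighted cell proportions, where `p_e` is the product-of-margins chance
#' agreement. The 95% CI uses the Fleiss--Cohen--Everitt large-sample
#' variance evaluated at the weighted proportions with `n_actual` as the
#' effective sample size, clipped to `[-1, 1]`.
#'
#' @param tab An `agreement_table`.
#' @return An [estimate_ci()].
#' @export
#' @examples
#' cohen_kappa(table_from_counts(741, 154, 66, 679))
cohen_kappa <- function(tab) {
  check_table(tab)
  p <- matrix(c(tab$p_a, tab$p_b, tab$p_c, tab$p_d), 2, byrow = TRUE)
  row_m <- rowSums(p)
  col_m <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(row_m * col_m)
  if (abs(1 - p_e) < 1e-12) {
    stop("kappa undefined: degenerate margins (chance agreement = 1)",
         call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt asymptotic variance for unweighted-category kappa
  off <- row(p) != col(p)
  A <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kappa))^2)
  B <- (1 - kappa)^2 * sum(p[off] * (outer(col_m, row_m, `+`)[off])^2)
  C <- (kappa - p_e * (1 - kappa))^2
  var_k <- (A + B - C) / (tab$n_actual * (1 - p_e)^2)
  se <- sqrt(max(0, var_k))
  estimate_ci(kappa, kappa - 1.96 * se, kappa + 1.96 * se, range = c(-1, 1))
}

#' Proportions of positive and negative agreement
#'
#' `Ppos = 2 p_a / (2 p_a + p_b + p_c)` and
#' `Pneg = 2 p_d / (2 p_d + p_b + p_c)` on the weighted proportions: the
#' chance of the two sources agreeing conditional on (either giving) a
#' positive, respectively negative, classification. CIs use the same
#' normal-approximation convention as [overall_agreement()] with `n_actual`;
#' a component whose denominator is zero is returned as `NA`.
#'
#' @param tab An `agreement_table`.
#' @return List with elements `Ppos` and `Pneg`, each an [estimate_ci()] (or
#'   `NA` estimate when undefined).
#' @export
pos_neg_agreement <- function(tab) {
  check_table(tab)
  one <- function(num, den) {
    if (den <= 0) return(estimate_ci(NA_real_, NA_real_, NA_real_))
    p <- num / den
    se <- sqrt(p * (1 - p) / tab$n_actual)
    estimate_ci(p, p - 1.96 * se, p + 1.96 * se, range = c(0, 1))
  }
  list(Ppos = one(2 * tab$p_a, 2 * tab$p_a + tab$p_b + tab$p_c),
       Pneg = one(2 * tab$p_d, 2 * tab$p_d + tab$p_b + tab$p_c))
}

#' Person-bootstrap confidence intervals for the agreement statistics
#'
#' Resamples respondents with replacement (carrying their weights) and
#' recomputes overall agreement, kappa, Ppos and Pneg; percentile intervals.
#' Provided as an alternative to the closed-form normal approximations, whose
#' exact form for Ppos/Pneg is a modelling choice.
#'
#' @param admin,self,weights As in [build_table()].
#' @param R Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @return List of four [estimate_ci()] objects: `agreement`, `kappa`,
#'   `Ppos`, `Pneg`.
#' @export
agreement_boot <- function(admin, self, weights = NULL, R = 500,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- rep(1, length(admin))
  ok <- !is.na(self)
  admin <- admin[ok]; self <- self[ok]; weights <- weights[ok]
  n <- length(admin)
  stat <- function(idx) {
    tab <- build_table(admin[idx], self[idx], weights[idx])
    pn <- pos_neg_agreement(tab)
    c(agreement = tab$p_a + tab$p_d, kappa = cohen_kappa(tab)$estimate,
      Ppos = pn$Ppos$estimate, Pneg = pn$Pneg$estimate)
  }
  boots <- vapply(seq_len(R), function(i) stat(sample.int(n, n, TRUE)),
                  numeric(4))
  point <- stat(seq_len(n))
  out <- lapply(seq_along(point), function(i) {
    q <- stats::quantile(boots[i, ], c(0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
    rng <- if (names(point)[i] == "kappa") c(-1, 1) else c(0, 1)
    estimate_ci(point[i], q[1], q[2], range = rng)
  })
  names(out) <- names(point)
  out
}

#' Verbal band for a kappa value
#'
#' Poor below 0.20, fair 0.20--0.39, moderate 0.40--0.59, good 0.60--0.79,
#' very good 0.80--1.00; boundaries inclusive at the lower edge.
#'
#' @param kappa Kappa value(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' kappa_band(c(0.63, 0.40, -0.5))
kappa_band <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  as.character(cut(kappa, c(-1, 0.20, 0.40, 0.60, 0.80, 1.0000001),
                   labels = c("poor", "fair", "moderate", "good",
                              "very good"),
                   right = FALSE, include.lowest = TRUE))
}

#' Agreement grid across algorithms and self-report items
#'
#' Builds the full agreement surface: for every window length in
#' `window_years` and both self-report items (`ever_asthma`,
#' `physician_diagnosed`), the weighted 2x2 cells, percent agreement, kappa,
#' Ppos and Pneg with 95% CIs.
#'
#' @param admin_status Named list of logical vectors, one per algorithm,
#'   names like `"k1"`, `"k30"`; all aligned with `self_reports`.
#' @param self_reports Tibble with `ever_asthma` and `physician_diagnosed`.
#' @param weights Optional design weights.
#' @return Tibble with one row per (algorithm, self item).
#' @export
agreement_summary <- function(admin_status, self_reports, weights = NULL) {
  items <- c("ever_asthma", "physician_diagnosed")
  rows <- list()
  for (alg in names(admin_status)) {
    for (item in items) {
      tab <- build_table(admin_status[[alg]], self_reports[[item]], weights)
      oa <- overall_agreement(tab)
      kp <- cohen_kappa(tab)
      pn <- pos_neg_agreement(tab)
      rows[[length(rows) + 1]] <- tibble::tibble(
        algorithm = alg, self_item = item, n = tab$n_actual,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        agreement_pct = 100 * oa$estimate,
        agreement_lo = 100 * oa$lower, agreement_hi = 100 * oa$upper,
        kappa = kp$estimate, kappa_lo = kp$lower, kappa_hi = kp$upper,
        kappa_band = kappa_band(kp$estimate),
        ppos = pn$Ppos$estimate, ppos_lo = pn$Ppos$lower,
        ppos_hi = pn$Ppos$upper,
        pneg = pn$Pneg$estimate, pneg_lo = pn$Pneg$lower,
        pneg_hi = pn$Pneg$upper)
    }
  }
  dplyr::bind_rows(rows)
}
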