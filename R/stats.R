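#' Shapiro-Wilk normality gate
#'
#' Thin wrapper over the standard Shapiro-Wilk test, with the input checks
#' the pipeline relies on (3 <= n <= 5000, non-degenerate variance). Every
#' dependent measure passes through this gate to choose between the
#' parametric and aligned-rank factorial branches.
#'
#' @param values numeric vector.
#' @return tibble with `W` and `p`.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    abort(sprintf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n))
  }
  if (sd(values) == 0) abort("normality test is undefined for a constant vector")
  sw <- shapiro.test(values)
  tibble(W = unname(sw$statistic), p = sw$p.value)
}

# Type-III factorial ANOVA core for a 2-factor between-subjects design.
# With sum-to-zero effects coding every effect of a 2x2 design is a single
# column of the full model matrix, so its type-III F is the squared t of
# that coefficient; SS_effect = bhat^2 / (X'X)^{-1}_jj.
factorial_core <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  if (nlevels(fa) != 2L || nlevels(fb) != 2L) {
    abort("both factors must have exactly 2 levels")
  }
  cells <- table(fa, fb)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    abort(sprintf("empty design cell: %s x %s",
                  levels(fa)[empty[1L]], levels(fb)[empty[2L]]))
  }
  a <- ifelse(fa == levels(fa)[1L], 1, -1)
  b <- ifelse(fb == levels(fb)[1L], 1, -1)
  X <- cbind(1, a, b, a * b)
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  df_den <- n - 4L
  rss <- sum(fit$residuals^2)
  mse <- rss / df_den
  xtxi <- chol2inv(chol(crossprod(X)))
  ss_eff <- fit$coefficients[2:4]^2 / diag(xtxi)[2:4]
  # snap round-off-scale sums of squares to zero so a constant response
  # yields F = 0 exactly rather than a ratio of numerical noise
  tol0 <- 1e-14 * max(sum(y^2), .Machine$double.xmin)
  ss_eff[ss_eff < tol0] <- 0
  if (rss < tol0) rss <- 0
  mse <- rss / df_den
  f <- if (mse > 0) ss_eff / mse else rep(Inf, 3L)
  f[ss_eff <= 0] <- 0
  p <- pf(f, 1, df_den, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  p[f == 0] <- 1
  eta <- if (rss > 0) ss_eff / (ss_eff + rss) else rep(1, 3L)
  eta[ss_eff <= 0] <- 0
  tibble(
    effect = c("group", "sex", "group:sex"),
    F = unname(f), df_num = 1L, df_den = df_den,
    p = unname(p), eta_p2 = unname(eta)
  )
}

new_factorial_fit <- function(table, method, response, factors, nobs,
                              extra = list()) {
  structure(
    c(list(table = table, method = method, response = response,
           factors = factors, nobs = nobs), extra),
    class = "factorial_fit"
  )
}

#' Two-way between-subjects ANOVA with partial eta squared
#'
#' Type-III sums of squares under sum-to-zero effects coding (the
#' appropriate choice for the unbalanced group x sex design), F and p for
#' both main effects and the interaction, and the effect size
#' `eta_p2 = SS_effect / (SS_effect + SS_error)`. The effect labels follow
#' the study design (`group`, `sex`, `group:sex`) whatever the column
#' names.
#'
#' @param data a data frame.
#' @param response,factor_a,factor_b bare column names: the measure and the
#'   two 2-level factors.
#' @return a `factorial_fit`; use [tidy()] for the effect table.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  response <- rlang::enquo(response)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  y <- rlang::eval_tidy(response, data)
  fa <- rlang::eval_tidy(factor_a, data)
  fb <- rlang::eval_tidy(factor_b, data)
  keep <- complete.cases(y, fa, fb)
  tab <- factorial_core(y[keep], fa[keep], fb[keep])
  new_factorial_fit(tab, "parametric", rlang::as_label(response),
                    c(rlang::as_label(factor_a), rlang::as_label(factor_b)),
                    sum(keep))
}

# Cell-mean effect estimates with unweighted marginal means (the estimates
# the aligned-rank construction aligns by).
cell_effect_estimates <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  cm <- tapply(y, list(fa, fb), mean)
  mu <- mean(cm)
  a_eff <- rowMeans(cm) - mu
  b_eff <- colMeans(cm) - mu
  ab_eff <- cm - outer(a_eff, b_eff, "+") - mu
  list(cm = cm, mu = mu, a = a_eff, b = b_eff, ab = ab_eff,
       cell_of = cbind(as.integer(fa), as.integer(fb)))
}

#' Aligned-rank-transform factorial ANOVA
#'
#' Nonparametric two-way between-subjects ANOVA by the aligned rank
#' transform: for each effect, the response is aligned by stripping the
#' cell-mean estimates of every *other* effect (leaving the residual plus
#' the effect of interest), aligned values are ranked with average ranks
#' on ties, a full type-III factorial ANOVA is run on the ranks, and only
#' the effect's own row is reported. The aligned responses sum to
#' (numerically) zero and carry no trace of the stripped effects — both
#' properties are exposed via the returned `alignment` element.
#'
#' @inheritParams two_way_anova
#' @return a `factorial_fit` with `method = "art"`; `$alignment` holds the
#'   aligned (unranked) responses per effect for diagnostics.
#' @export
art_anova <- function(data, response, factor_a, factor_b) {
  response <- rlang::enquo(response)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  y <- rlang::eval_tidy(response, data)
  fa <- rlang::eval_tidy(factor_a, data)
  fb <- rlang::eval_tidy(factor_b, data)
  keep <- complete.cases(y, fa, fb)
  y <- y[keep]; fa <- factor(fa[keep]); fb <- factor(fb[keep])
  est <- cell_effect_estimates(y, fa, fb)
  resid_cell <- y - est$cm[est$cell_of]
  aligned <- list(
    group = resid_cell + est$a[est$cell_of[, 1L]],
    sex = resid_cell + est$b[est$cell_of[, 2L]],
    `group:sex` = resid_cell + est$ab[est$cell_of]
  )
  rows <- purrr::imap(aligned, function(al, eff) {
    ranked <- rank(al, ties.method = "average")
    tab <- factorial_core(ranked, fa, fb)
    tab[tab$effect == eff, ]
  })
  tab <- dplyr::bind_rows(rows)
  new_factorial_fit(tab, "art", rlang::as_label(response),
                    c(rlang::as_label(factor_a), rlang::as_label(factor_b)),
                    length(y), extra = list(alignment = aligned))
}

#' Normality-gated factorial analysis
#'
#' The decision flow applied to every dependent measure: Shapiro-Wilk on
#' the measure; if `p >= alpha_gate` the parametric two-way ANOVA is used,
#' otherwise the aligned-rank branch. The gate result travels with the
#' fit.
#'
#' @inheritParams two_way_anova
#' @param alpha_gate gate level (default 0.05).
#' @return a `factorial_fit` with `$gate` (`W`, `p`, `branch`).
#' @export
factorial_analysis <- function(data, response, factor_a, factor_b,
                               alpha_gate = 0.05) {
  response <- rlang::enquo(response)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  y <- rlang::eval_tidy(response, data)
  gate <- normality_test(y)
  fit <- if (gate$p >= alpha_gate) {
    two_way_anova(data, !!response, !!factor_a, !!factor_b)
  } else {
    art_anova(data, !!response, !!factor_a, !!factor_b)
  }
  fit$gate <- tibble(W = gate$W, p = gate$p, branch = fit$method)
  fit
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("<factorial_fit> %s ~ %s * %s (%s, n = %d)\n",
              x$response, x$factors[1], x$factors[2], x$method, x$nobs))
  print(x$table)
  invisible(x)
}

#' @method tidy factorial_fit
#' @export
tidy.factorial_fit <- function(x, ...) {
  dplyr::mutate(x$table, method = x$method, response = x$response,
                .before = 1L)
}

#' @method glance factorial_fit
#' @export
glance.factorial_fit <- function(x, ...) {
  tibble(
    response = x$response, method = x$method, nobs = x$nobs,
    df_den = x$table$df_den[1L],
    n_significant = sum(x$table$p < 0.05)
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-ranked values; the p-value uses the
#' standard t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return tibble with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) abort("Spearman correlation needs at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("Spearman correlation is undefined for constant input")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving; `m` defaults to the family
#' size `length(p_values)`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m family size.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Bonferroni-adjusted pairwise cell contrasts
#'
#' All pairwise comparisons between the cells of the two-factor design,
#' with Welch two-sample t tests on the raw values (`method =
#' "parametric"`) or on the global average ranks (`method = "rank"`);
#' `"auto"` routes by the Shapiro-Wilk gate like [factorial_analysis()].
#' Contrasts involving a singleton cell are emitted but flagged
#' (`estimable = FALSE`). Adjusted and raw p-values are both reported; the
#' family is the emitted set of contrasts.
#'
#' @inheritParams two_way_anova
#' @param method `"auto"`, `"parametric"` or `"rank"`.
#' @param alpha_gate gate level for `"auto"`.
#' @return tibble, one row per unordered cell pair.
#' @export
pairwise_contrasts <- function(data, response, factor_a, factor_b,
                               method = c("auto", "parametric", "rank"),
                               alpha_gate = 0.05) {
  method <- match.arg(method)
  response <- rlang::enquo(response)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  y <- rlang::eval_tidy(response, data)
  fa <- rlang::eval_tidy(factor_a, data)
  fb <- rlang::eval_tidy(factor_b, data)
  keep <- complete.cases(y, fa, fb)
  y <- y[keep]; fa <- fa[keep]; fb <- fb[keep]
  if (method == "auto") {
    method <- if (normality_test(y)$p >= alpha_gate) "parametric" else "rank"
  }
  v <- if (method == "rank") rank(y, ties.method = "average") else y
  cell <- paste(fa, fb, sep = ":")
  cells <- sort(unique(cell))
  pairs <- utils::combn(cells, 2L)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    c1 <- pairs[1L, k]; c2 <- pairs[2L, k]
    v1 <- v[cell == c1]; v2 <- v[cell == c2]
    estimable <- length(v1) >= 2L && length(v2) >= 2L &&
      (sd(v1) > 0 || sd(v2) > 0)
    if (estimable) {
      tt <- stats::t.test(v1, v2)
      tibble(cell_1 = c1, cell_2 = c2, estimate = unname(diff(-tt$estimate)),
             statistic = unname(tt$statistic), p = tt$p.value,
             estimable = TRUE)
    } else if (length(v1) >= 1L && length(v2) >= 1L &&
               isTRUE(all.equal(c(v1, v2), rep(mean(c(v1, v2)),
                                               length(c(v1, v2)))))) {
      # identical constant cells: no evidence of a difference
      tibble(cell_1 = c1, cell_2 = c2, estimate = mean(v1) - mean(v2),
             statistic = 0, p = 1, estimable = TRUE)
    } else {
      tibble(cell_1 = c1, cell_2 = c2, estimate = NA_real_,
             statistic = NA_real_, p = NA_real_, estimable = FALSE)
    }
  })
  rows$p_adj <- bonferroni(rows$p, m = sum(!is.na(rows$p)))
  rows$method <- method
  rows
}
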