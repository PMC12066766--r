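design_8898 <- function(y) {
  data.frame(
    y = y,
    group = rep(c("AR", "AR", "video", "video"), c(8, 8, 9, 8)),
    sex = rep(c("male", "female", "male", "female"), c(8, 8, 9, 8))
  )
}

test_that("the normality gate behaves on Gaussian vs lognormal samples", {
  reps <- 100
  p_norm <- p_lnorm <- numeric(reps)
  withr::with_seed(61, {
    for (i in seq_len(reps)) {
      p_norm[i] <- normality_test(rnorm(50))$p
      p_lnorm[i] <- normality_test(exp(rnorm(50)))$p
    }
  })
  expect_gte(mean(p_norm > 0.05), 0.9)
  expect_gte(mean(p_lnorm < 0.05), 0.9)
  expect_error(normality_test(rep(1, 20)), "constant")
  expect_error(normality_test(c(1, 2)), "3 <= n")
})

test_that("type-III ANOVA matches car::Anova on the unbalanced design", {
  withr::with_seed(62, {
    d <- design_8898(rnorm(33))
    d$y[d$group == "AR" & d$sex == "female"] <-
      d$y[d$group == "AR" & d$sex == "female"] + 1.5
  })
  fit <- tidy(two_way_anova(d, y, group, sex))
  m <- lm(y ~ group * sex, data = d,
          contrasts = list(group = "contr.sum", sex = "contr.sum"))
  ca <- car::Anova(m, type = 3)
  expect_equal(fit$F, ca$`F value`[2:4], tolerance = 1e-10)
  expect_equal(fit$p, ca$`Pr(>F)`[2:4], tolerance = 1e-10)
  ss_err <- ca$`Sum Sq`[5]
  expect_equal(fit$eta_p2, ca$`Sum Sq`[2:4] / (ca$`Sum Sq`[2:4] + ss_err),
               tolerance = 1e-10)
})

test_that("degenerate responses give the exact boundary statistics", {
  d <- design_8898(rep(2, 33))
  fit <- tidy(two_way_anova(d, y, group, sex))
  expect_equal(fit$F, c(0, 0, 0))
  expect_equal(fit$p, c(1, 1, 1))
  expect_equal(fit$eta_p2, c(0, 0, 0))
  # cell-mean pattern with vanishing error: interaction F explodes,
  # eta_p2 -> 1; matches the hand-computed SS decomposition on 8 rows
  base <- data.frame(
    group = rep(c("a", "b"), each = 4),
    sex = rep(c("m", "f"), 4)
  )
  eps <- 1e-6
  base$y <- ifelse(base$group == "b" & base$sex == "f", 1, 0) +
    rep(c(-eps, -eps, eps, eps), 2)
  fit2 <- tidy(two_way_anova(base, y, group, sex))
  # hand oracle: balanced 2x2, cell means (0,0,0,1); each effect SS = n*mu^2
  # with effects-coded contrast value 0.25 -> SS = 8 * 0.25^2 = 0.5
  expect_equal(fit2$F[3] * (8 * eps^2 / 4), 0.5, tolerance = 1e-6)
  expect_gte(fit2$eta_p2[3], 0.999)
  # an empty cell is rejected by name
  d_empty <- d[!(d$group == "video" & d$sex == "female"), ]
  expect_error(two_way_anova(d_empty, y, group, sex), "empty design cell")
})

test_that("type-I error is nominal for both branches at the 8/8/9/8 design", {
  reps <- 400
  rej <- matrix(NA, reps, 2)
  for (i in seq_len(reps)) {
    d <- simulate_activation_table(cohort_spec(), seed = 3000 + i)
    rej[i, 1] <- tidy(two_way_anova(d, y, group, sex))$p[3] < 0.05
    rej[i, 2] <- tidy(art_anova(d, y, group, sex))$p[3] < 0.05
  }
  # 3-sigma binomial band around 0.05 at 400 reps: +/- 0.033
  expect_lt(abs(mean(rej[, 1]) - 0.05), 0.035)
  expect_lt(abs(mean(rej[, 2]) - 0.05), 0.035)
})

test_that("ART alignment strips the other effects exactly", {
  # centering: on a balanced design the aligned responses sum to zero
  withr::with_seed(72, {
    bal <- data.frame(
      y = rnorm(32),
      group = rep(c("AR", "video"), each = 16),
      sex = rep(rep(c("male", "female"), each = 8), 2)
    )
  })
  fit_bal <- art_anova(bal, y, group, sex)
  for (al in fit_bal$alignment) {
    expect_lt(abs(sum(al)), 1e-8)
  }
  withr::with_seed(63, {
    d <- design_8898(rnorm(33, sd = 2))
    d$y <- d$y + 3 * (d$group == "AR") - 2 * (d$sex == "male") +
      1.5 * (d$group == "AR") * (d$sex == "male")
  })
  fit <- art_anova(d, y, group, sex)
  # on the aligned (unranked) response for one effect, the other two
  # effects' F statistics vanish
  for (eff in names(fit$alignment)) {
    d2 <- d
    d2$y <- fit$alignment[[eff]]
    other <- tidy(two_way_anova(d2, y, group, sex))
    expect_lt(max(other$F[other$effect != eff]), 1e-8)
  }
})

test_that("ART tracks the parametric ANOVA on normal data", {
  reps <- 100
  diff_p <- p_par <- p_art <- numeric(reps)
  for (i in seq_len(reps)) {
    d <- simulate_activation_table(cohort_spec(n_participants = 120),
                                   group_effect = 1, seed = 5000 + i)
    p_par[i] <- tidy(two_way_anova(d, y, group, sex))$p[1]
    p_art[i] <- tidy(art_anova(d, y, group, sex))$p[1]
    diff_p[i] <- abs(p_par[i] - p_art[i])
  }
  # with a decisive normal-theory effect both branches agree closely
  expect_gte(mean(diff_p < 0.05), 0.95)
  expect_lt(stats::median(diff_p), 0.01)
})

test_that("ART is at least as powerful as parametric ANOVA on heavy tails", {
  reps <- 300
  rej <- matrix(NA, reps, 2)
  withr::with_seed(64, {
    for (i in seq_len(reps)) {
      d <- design_8898(rt(33, df = 2))
      d$y[d$group == "AR"] <- d$y[d$group == "AR"] + 1.5
      rej[i, 1] <- tidy(two_way_anova(d, y, group, sex))$p[1] < 0.05
      rej[i, 2] <- tidy(art_anova(d, y, group, sex))$p[1] < 0.05
    }
  })
  expect_gte(mean(rej[, 2]), mean(rej[, 1]))
})

test_that("rank-transformed one-factor ANOVA matches the Kruskal-Wallis relation", {
  withr::with_seed(65, {
    y <- c(rnorm(12), rnorm(12, 1), rnorm(12, 2))
    g <- factor(rep(letters[1:3], each = 12))
  })
  N <- length(y); k <- nlevels(g)
  r <- rank(y)
  fit <- stats::anova(lm(r ~ g))
  H <- stats::kruskal.test(y, g)$statistic
  f_from_h <- ((N - k) / (k - 1)) * H / (N - 1 - H)
  expect_equal(unname(fit$`F value`[1]), unname(f_from_h), tolerance = 1e-10)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(1, 4, 9, 16, 25, 36)
  expect_equal(spearman_cor(x, sqrt(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  withr::with_seed(66, {
    a <- sample(1:5, 30, replace = TRUE) # heavy ties
    b <- a + sample(0:3, 30, replace = TRUE)
  })
  got <- spearman_cor(a, b)
  oracle_rho <- cor(rank(a), rank(b))
  expect_equal(got$rho, oracle_rho, tolerance = 1e-12)
  tstat <- oracle_rho * sqrt((30 - 2) / (1 - oracle_rho^2))
  expect_equal(got$p, 2 * pt(abs(tstat), 28, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("Bonferroni adjustment is the capped monotone map", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 3), 1)
  withr::with_seed(67, p <- runif(20))
  adj <- bonferroni(p)
  expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving
  expect_equal(adj, pmin(1, 20 * p))
  expect_error(bonferroni(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("pairwise contrasts enumerate cells and flag degenerate ones", {
  withr::with_seed(68, d <- design_8898(rnorm(33)))
  ct <- pairwise_contrasts(d, y, group, sex, method = "parametric")
  expect_equal(nrow(ct), choose(4, 2))
  expect_true(all(ct$estimable))
  expect_equal(ct$p_adj, pmin(1, 6 * ct$p))
  # identical constant cells: no difference, p_adj = 1
  d2 <- data.frame(
    y = rep(1, 8),
    g = rep(c("a", "b"), each = 4), s = rep(c("m", "f"), 4)
  )
  ct2 <- pairwise_contrasts(d2, y, g, s, method = "parametric")
  expect_true(all(ct2$p_adj == 1))
  # singleton cell flagged, not dropped
  d3 <- design_8898(rnorm(33))
  d3 <- d3[!(d3$group == "AR" & d3$sex == "male"), ]
  d3 <- rbind(d3, data.frame(y = 0, group = "AR", sex = "male"))
  ct3 <- pairwise_contrasts(d3, y, group, sex, method = "parametric")
  expect_equal(sum(!ct3$estimable), 3L)
})

test_that("unadjusted contrast false positives stay near 5% under the null", {
  reps <- 200
  fp <- numeric(reps)
  withr::with_seed(69, {
    for (i in seq_len(reps)) {
      d <- design_8898(rnorm(33))
      ct <- pairwise_contrasts(d, y, group, sex, method = "parametric")
      fp[i] <- mean(ct$p < 0.05)
    }
  })
  expect_lt(abs(mean(fp) - 0.05), 0.03)
})

test_that("the gate routes measures to the documented branch", {
  withr::with_seed(70, {
    normal_d <- design_8898(rnorm(33))
    skewed_d <- design_8898(exp(rnorm(33, sd = 1.5)))
  })
  expect_equal(factorial_analysis(normal_d, y, group, sex)$method, "parametric")
  expect_equal(factorial_analysis(skewed_d, y, group, sex)$method, "art")
})

test_that("tidy and glance expose the fit in broom style", {
  withr::with_seed(71, d <- design_8898(rnorm(33)))
  fit <- two_way_anova(d, y, group, sex)
  td <- tidy(fit)
  expect_setequal(
    names(td),
    c("method", "response", "effect", "F", "df_num", "df_den", "p", "eta_p2")
  )
  gl <- glance(fit)
  expect_equal(gl$nobs, 33L)
  expect_equal(gl$df_den, 29L)
})
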