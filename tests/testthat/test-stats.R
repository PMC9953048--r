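mk_changes <- function(values, condition = "stim", parameter = "eye_opening") {
  out <- data.frame(animal_id = paste0("a", seq_along(values)),
                    condition = condition)
  out[[parameter]] <- values
  out
}

test_that("response_profile: one-sample t against zero with Bonferroni", {
  sym <- mk_changes(c(-0.1, 0.1, -0.3, 0.3))
  r <- response_profile(sym, "stim", m = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p_raw, 1)

  set.seed(5)
  x <- 0.2 + rnorm(10, sd = 0.05)
  r2 <- response_profile(mk_changes(x), "stim", m = 3)
  # textbook formula oracle
  t_oracle <- mean(x) / (sd(x) / sqrt(10))
  expect_equal(r2$t, t_oracle, tolerance = 1e-12)
  expect_equal(r2$df, 9)
  expect_equal(r2$p_raw, 2 * pt(-abs(t_oracle), 9), tolerance = 1e-12)
  expect_equal(r2$p_adj, min(1, 3 * r2$p_raw))
  expect_identical(sign(r2$t), sign(mean(x)))

  expect_error(response_profile(mk_changes(rep(0.2, 5)), "stim"),
               "degenerate sample")
})

test_that("one_way_anova: F and Tukey match independent computations", {
  d <- data.frame(y = rep(1:4, times = 3), g = rep(letters[1:3], each = 4))
  expect_equal(one_way_anova(d, "y", "g")$effects$F, 0)

  set.seed(12)
  d2 <- data.frame(y = rnorm(15) + rep(c(0, 0.5, 1.5), each = 5),
                   g = rep(letters[1:3], each = 5))
  res <- one_way_anova(d2, "y", "g")
  # brute-force sums of squares
  gm <- mean(d2$y)
  means <- tapply(d2$y, d2$g, mean)
  ssb <- sum(5 * (means - gm)^2)
  ssw <- sum((d2$y - means[d2$g])^2)
  F_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$effects$F, F_oracle, tolerance = 1e-9)
  expect_equal(res$effects$p, pf(F_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-9)
  # Tukey p via the studentized range distribution directly
  mse <- ssw / 12
  q_ba <- abs(means[["b"]] - means[["a"]]) / sqrt(mse / 5)
  p_ba <- ptukey(q_ba, 3, 12, lower.tail = FALSE)
  expect_equal(res$posthoc$p_adj[res$posthoc$pair == "b-a"], p_ba,
               tolerance = 1e-6)

  # two groups: Tukey collapses to the pooled two-sample t test
  d3 <- data.frame(y = rnorm(12), g = rep(c("a", "b"), each = 6))
  res3 <- one_way_anova(d3, "y", "g")
  tt <- t.test(y ~ g, data = d3, var.equal = TRUE)
  expect_equal(res3$posthoc$p_adj, tt$p.value, tolerance = 1e-9)

  expect_error(one_way_anova(data.frame(y = 1:3, g = c("a", "a", "b")),
                             "y", "g"), "fewer than 2")
})

test_that("two_way_anova (between-subjects): reference agreement", {
  set.seed(31)
  d <- expand.grid(hab = c("naive", "habituated"),
                   stim = c("poking", "petting", "brushing"),
                   rep = 1:6)
  d$y <- rnorm(nrow(d)) + as.numeric(d$stim == "petting")
  res <- two_way_anova(d, "y", "hab", "stim")
  # balanced design: Type II equals the sequential table
  ref <- anova(lm(y ~ hab * stim, data = d))
  expect_equal(res$effects$F[res$effects$effect == "hab"],
               ref["hab", "F value"], tolerance = 1e-9)
  expect_equal(res$effects$F[res$effects$effect == "stim"],
               ref["stim", "F value"], tolerance = 1e-9)
  expect_equal(res$effects$F[res$effects$effect == "hab:stim"],
               ref["hab:stim", "F value"], tolerance = 1e-9)
  expect_true(all(c("hab", "stim") %in% res$posthoc$effect))

  # interaction with all cell means equal -> F = 0
  d0 <- expand.grid(a = c("x", "y"), b = c("u", "v", "w"), rep = 1:4)
  set.seed(34)
  d0$y <- rnorm(24)
  d0$y <- d0$y - ave(d0$y, d0$a, d0$b) # force every cell mean to zero
  res0 <- two_way_anova(d0, "y", "a", "b")
  expect_equal(res0$effects$F[res0$effects$effect == "a:b"], 0,
               tolerance = 1e-12)
})

test_that("two_way_anova (mixed): GG epsilon and strata agreement", {
  set.seed(32)
  n <- 8
  d2 <- expand.grid(subject = paste0("s", 1:n),
                    stim = c("baseline", "stimulation"))
  d2$geno <- rep(rep(c("WT", "Het"), each = n / 2), 2)
  d2$y <- rnorm(nrow(d2))
  res2 <- two_way_anova(d2, "y", "geno", "stim",
                        repeated_on = "stim", subject = "subject")
  # a 2-level within factor is trivially spherical
  expect_equal(res2$effects$epsilon[res2$effects$effect == "stim"], 1)

  # 3 within levels: F values agree with the aov error-strata route
  d3 <- expand.grid(subject = paste0("s", 1:n),
                    stim = c("baseline", "stimulation", "recovery"))
  d3$geno <- rep(rep(c("WT", "Het"), each = n / 2), 3)
  set.seed(33)
  d3$y <- rnorm(nrow(d3)) + 2 * as.numeric(d3$stim == "stimulation")
  res3 <- two_way_anova(d3, "y", "geno", "stim",
                        repeated_on = "stim", subject = "subject")
  fit <- summary(aov(y ~ geno * stim + Error(subject / stim), data = d3))
  within_tab <- fit[["Error: subject:stim"]][[1]]
  expect_equal(res3$effects$F[res3$effects$effect == "stim"],
               within_tab["stim", "F value"], tolerance = 1e-6)
  expect_equal(res3$effects$F[res3$effects$effect == "geno:stim"],
               within_tab["geno:stim", "F value"], tolerance = 1e-6)
  eps <- res3$effects$epsilon[res3$effects$effect == "stim"]
  expect_true(eps > 0 && eps <= 1)
  # corrected dfs are fractional: df1 = eps * (levels - 1)
  expect_equal(res3$effects$df1[res3$effects$effect == "stim"], eps * 2)
  # within-factor Tukey flags the strong stimulation shift
  tks <- res3$posthoc[res3$posthoc$effect == "stim", ]
  expect_identical(nrow(tks), 3L)
  expect_lt(tks$p_adj[tks$pair == "baseline-stimulation"], 0.01)
  # within Tukey reproduces the studentized-range computation
  mse <- within_tab["Residuals", "Mean Sq"]
  dfe <- within_tab["Residuals", "Df"]
  mw <- tapply(d3$y, d3$stim, mean)
  q <- abs(mw[["baseline"]] - mw[["stimulation"]]) / sqrt(mse / n)
  expect_equal(tks$p_adj[tks$pair == "baseline-stimulation"],
               ptukey(q, 3, dfe, lower.tail = FALSE), tolerance = 1e-9)

  expect_error(two_way_anova(d3[-1, ], "y", "geno", "stim",
                             repeated_on = "stim", subject = "subject"),
               "incomplete")
})

mk_bins <- function(mat, labels = c("baseline", as.character(1:6))) {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(animal_id = paste0("a", i), bin_label = labels,
               eye_opening = mat[i, ])
  }))
}

test_that("rm_anova_dunnett: null bins give F = 0 and Dunnett p = 1", {
  set.seed(41)
  subj <- rnorm(8, 10)
  mat <- matrix(rep(subj, 7), 8, 7) # bins identical within subject
  # the degenerate covariance triggers an informative sphericity warning
  res <- suppressWarnings(rm_anova_dunnett(mk_bins(mat), "eye_opening"))
  expect_equal(res$effects$F[1], 0, tolerance = 1e-20)
  expect_true(all(res$posthoc$p_adj > 0.9999))
  expect_identical(res$posthoc$method, rep("dunnett", 6L))
})

test_that("rm_anova_dunnett: df arithmetic and agreement with emmeans", {
  set.seed(42)
  mat <- matrix(rnorm(10 * 7, 10), 10, 7)
  mat[, 2] <- mat[, 2] + 3 # bin 1 shifted
  bins <- mk_bins(mat)
  res <- rm_anova_dunnett(bins, "eye_opening")
  eps <- res$effects$epsilon[1]
  # uncorrected dfs for 7 conditions, n = 10 are (6, 54)
  expect_equal(res$effects$df1[1] / eps, 6, tolerance = 1e-9)
  expect_equal(res$effects$df2[1] / eps, 54, tolerance = 1e-9)
  # cross-check adjusted p against multcomp's Dunnett on the
  # fixed-block fit (same within-subject error term, independent code)
  d <- mk_bins(mat)
  d$bin_label <- factor(d$bin_label,
                        levels = c("baseline", as.character(1:6)))
  fit <- lm(eye_opening ~ factor(animal_id) + bin_label, data = d)
  set.seed(1)
  ref <- summary(multcomp::glht(
    fit, linfct = multcomp::mcp(bin_label = "Dunnett")))
  expect_equal(res$posthoc$estimate, unname(coef(ref)), tolerance = 1e-9)
  expect_equal(res$posthoc$p_adj, as.numeric(ref$test$pvalues),
               tolerance = 2e-3)
  # the shifted bin is detected, a null bin is not
  expect_lt(res$posthoc$p_adj[res$posthoc$pair == "1-baseline"], 0.05)
  expect_gt(res$posthoc$p_adj[res$posthoc$pair == "4-baseline"], 0.05)

  expect_error(rm_anova_dunnett(mk_bins(mat[1:2, ]), "eye_opening"),
               "at least 3")
})

test_that("rm_anova_dunnett flags a simulated biphasic effect", {
  set.seed(43)
  hits <- replicate(60, {
    mat <- matrix(rnorm(10 * 7, 10, 0.5), 10, 7)
    mat[, 2] <- mat[, 2] + 1.2      # early phase
    mat[, 6:7] <- mat[, 6:7] + 1.2  # late phase
    res <- rm_anova_dunnett(mk_bins(mat), "eye_opening")
    sig <- res$posthoc$p_adj < 0.05
    all(sig[c(1, 5, 6)]) && !any(sig[c(2, 3, 4)])
  })
  expect_gte(mean(hits), 0.9)
})

test_that("icc: ICC(2,1) agreement form", {
  set.seed(51)
  items <- rnorm(20, 10, 2)
  dup <- cbind(items, items, items)
  r <- icc(dup)
  expect_equal(r$value, 1)

  # seeded matrix vs an aov-decomposition oracle
  x <- matrix(rnorm(60), 20, 3) + items
  d <- data.frame(y = as.vector(x),
                  item = factor(rep(1:20, 3)),
                  rater = factor(rep(1:3, each = 20)))
  ms <- anova(lm(y ~ item + rater, data = d))
  MSR <- ms["item", "Mean Sq"]; MSC <- ms["rater", "Mean Sq"]
  MSE <- ms["Residuals", "Mean Sq"]
  oracle <- (MSR - MSE) / (MSR + 2 * MSE + 3 * (MSC - MSE) / 20)
  r2 <- icc(x)
  expect_equal(r2$value, oracle, tolerance = 1e-9)
  expect_true(r2$lower <= r2$value && r2$value <= r2$upper)

  # independent noise raters -> ICC near zero
  set.seed(52)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc(noise)$value), 0.2)

  expect_error(icc(matrix(1, 10, 3)), "constant")
  expect_error(icc(x[1:4, ]), "at least 5")
})

test_that("pearson_control reproduces rho/t/df relations", {
  x <- 1:20
  r <- pearson_control(x, 2 * x + 1)
  expect_equal(r$rho, 1)

  set.seed(61)
  x <- rnorm(50); y <- rnorm(50)
  r2 <- pearson_control(x, y)
  rho <- cor(x, y)
  expect_equal(r2$rho, rho, tolerance = 1e-12)
  expect_equal(r2$df, 48)
  expect_equal(r2$t, rho * sqrt(48 / (1 - rho^2)), tolerance = 1e-12)

  # a correlation of 0.20 at n = 121 corresponds to t(119) near 2.24
  set.seed(62)
  z1 <- rnorm(121); z2 <- residuals(lm(rnorm(121) ~ z1))
  z1s <- scale(z1)[, 1]; z2s <- scale(z2)[, 1]
  y3 <- 0.20 * z1s + sqrt(1 - 0.04) * z2s
  r3 <- pearson_control(z1s, y3)
  expect_equal(r3$rho, 0.20, tolerance = 1e-6)
  expect_equal(r3$t, 2.24, tolerance = 0.02)
  expect_equal(r3$p, 0.027, tolerance = 0.05)

  expect_error(pearson_control(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("welch_t: Satterthwaite limits and oracle", {
  x <- rnorm(10)
  expect_equal(welch_t(x, x)$t, 0)

  set.seed(71)
  a <- rnorm(12, sd = 1); b <- rnorm(12, sd = 1)
  # with exactly equal sample variances df hits the 2n-2 limit
  b_scaled <- (b - mean(b)) / sd(b) * sd(a) + mean(b)
  expect_equal(welch_t(a, b_scaled)$df, 22, tolerance = 1e-9)

  a2 <- rnorm(8, sd = 3); b2 <- rnorm(20, sd = 0.5)
  r <- welch_t(a2, b2)
  va <- var(a2) / 8; vb <- var(b2) / 20
  expect_equal(r$t, (mean(a2) - mean(b2)) / sqrt(va + vb),
               tolerance = 1e-12)
  expect_equal(r$df, (va + vb)^2 / (va^2 / 7 + vb^2 / 19),
               tolerance = 1e-9)
})

test_that("adjusted p-values dominate raw p-values across methods", {
  set.seed(81)
  d <- data.frame(y = rnorm(24) + rep(c(0, 0.3, 0.8), each = 8),
                  g = rep(letters[1:3], each = 8))
  res <- one_way_anova(d, "y", "g")
  for (i in seq_len(nrow(res$posthoc))) {
    pair <- strsplit(res$posthoc$pair[i], "-")[[1]]
    raw <- t.test(d$y[d$g == pair[1]], d$y[d$g == pair[2]],
                  var.equal = TRUE)$p.value
    expect_gte(res$posthoc$p_adj[i] + 1e-12, raw)
  }
  ch <- mk_changes(rnorm(10, 0.1, 0.1))
  r <- response_profile(ch, "stim", m = 3)
  expect_gte(r$p_adj, r$p_raw)
})

test_that("ANOVA F is invariant to affine rescaling of the response", {
  set.seed(91)
  d <- data.frame(y = rnorm(18), g = rep(letters[1:3], each = 6))
  f1 <- one_way_anova(d, "y", "g")$effects
  d$y <- 5 * d$y + 100
  f2 <- one_way_anova(d, "y", "g")$effects
  expect_equal(f1$F, f2$F, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})
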