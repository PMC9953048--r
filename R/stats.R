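#' Response profile: one-sample tests of proportional change
#'
#' Characterizes a stimulus by testing, per facial parameter, whether the
#' per-animal proportional changes from baseline differ from zero
#' (two-sided one-sample t test). Raw p-values are Bonferroni-adjusted for
#' the number of comparisons performed in the experiment, which the
#' analyst supplies as `m` (it is an experiment-level design quantity, not
#' something inferable from one table).
#'
#' @param changes Proportional-change table from [proportional_change()].
#' @param condition Stimulus label to profile.
#' @param m Number of comparisons corrected for (`p_adj = min(1, m * p)`).
#' @return Data frame, one row per parameter: `parameter`, `n`,
#'   `mean_change`, `t`, `df`, `p_raw`, `p_adj`, `m`.
#' @export
response_profile <- function(changes, condition, m = 1) {
  stopifnot(is.data.frame(changes), m >= 1)
  sub <- changes[changes$condition == condition, , drop = FALSE]
  if (nrow(sub) < 2L) {
    stop("need at least 2 animals with changes for condition '",
         condition, "'", call. = FALSE)
  }
  pars <- intersect(facial_parameters(), names(sub))
  rows <- lapply(pars, function(p) {
    x <- sub[[p]][!is.na(sub[[p]])]
    if (length(x) < 2L) {
      return(data.frame(parameter = p, n = length(x),
                        mean_change = if (length(x)) mean(x) else NA_real_,
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        p_adj = NA_real_, m = m))
    }
    if (stats::sd(x) == 0) {
      stop("degenerate sample: zero variance in ", p, " for condition '",
           condition, "'", call. = FALSE)
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(parameter = p, n = length(x), mean_change = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, m * tt$p.value), m = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Between-groups one-way ANOVA (subject repetition is not modeled, as in
#' designs where not all animals receive all stimuli) followed by Tukey's
#' honestly-significant-difference test on all pairwise contrasts via the
#' studentized-range distribution.
#'
#' @param data Data frame of units.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return List of class `fm_anova`: `effects` (effect, F, df1, df2, p)
#'   and `posthoc` (method, pair, estimate, p_adj).
#' @export
one_way_anova <- function(data, response, group) {
  stopifnot(is.data.frame(data))
  d <- data.frame(y = data[[response]], g = factor(data[[group]]))
  d <- d[stats::complete.cases(d), ]
  sizes <- table(d$g)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = d)
  tab <- summary(fit)[[1]]
  eff <- data.frame(effect = group,
                    F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
                    p = tab$`Pr(>F)`[1])
  tk <- stats::TukeyHSD(fit)$g
  ph <- data.frame(method = "tukey", pair = rownames(tk),
                   estimate = tk[, "diff"], p_adj = tk[, "p adj"])
  rownames(ph) <- NULL
  structure(list(effects = eff, posthoc = ph, alpha = 0.05,
                 ss_type = "I (balanced one-way)"),
            class = "fm_anova")
}

#' @export
print.fm_anova <- function(x, ...) {
  cat("ANOVA (", x$ss_type, ")\n", sep = "")
  print(x$effects, row.names = FALSE, digits = 4)
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("post hoc:\n")
    print(utils::head(x$posthoc, 20), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Univariate repeated-measures table with Greenhouse-Geisser correction,
# via the multivariate-model route. `within_levels` are the wide columns.
.rm_anova_gg <- function(wide, within_levels, between = NULL) {
  Y <- as.matrix(wide[, within_levels, drop = FALSE])
  idata <- data.frame(level = factor(within_levels, levels = within_levels))
  if (is.null(between)) {
    mlm <- stats::lm(Y ~ 1)
  } else {
    g <- factor(between)
    # sum-to-zero contrasts so the Type III decomposition is meaningful
    mlm <- stats::lm(Y ~ g, contrasts = list(g = stats::contr.sum))
  }
  A <- car::Anova(mlm, idata = idata, idesign = ~level, type = 3)
  s <- withCallingHandlers(
    summary(A, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  rows <- lapply(setdiff(rownames(ut), "(Intercept)"), function(term) {
    eps <- NA_real_
    Fv <- ut[term, "F value"]
    p <- ut[term, "Pr(>F)"]
    df1 <- ut[term, "num Df"]
    df2 <- ut[term, "den Df"]
    if (!is.null(adj) && term %in% rownames(adj) &&
        is.finite(adj[term, "GG eps"])) {
      eps <- adj[term, "GG eps"]
      p <- adj[term, "Pr(>F[GG])"]
      df1 <- df1 * eps
      df2 <- df2 * eps
    } else if (grepl("level", term)) {
      eps <- 1 # a 2-level (or degenerate) within factor: no correction
    }
    if (ut[term, "Sum Sq"] <= 0) { # exact null effect, even if MSe = 0
      Fv <- 0; p <- 1
    }
    data.frame(effect = term, F = Fv, df1 = df1, df2 = df2, p = p,
               epsilon = eps)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # error mean square and df of the within-subject stratum, for contrasts
  werr <- grep("^level", rownames(ut), value = TRUE)[1]
  list(effects = tab,
       ms_error_within = ut[werr, "Error SS"] / ut[werr, "den Df"],
       df_error_within = ut[werr, "den Df"])
}

# Post hoc battery for mixed (between x within) designs, built on the
# repeated-measures error term: Tukey for the within factor via the
# studentized range on the within-subject error, Tukey HSD on subject
# means for the between factor, and -- when the interaction is
# significant -- Sidak-adjusted cell comparisons (paired-style contrasts
# on the within error inside each group; Welch tests across groups at
# each within level).
.mixed_posthoc <- function(d, between, within, mse, dfe, int_sig,
                           int_label) {
  ph <- list()
  d$between <- factor(d$between)
  d$within <- factor(d$within)
  n_subj <- length(unique(d$subject))
  subj <- stats::aggregate(y ~ subject + between, data = d, FUN = mean)
  if (nlevels(subj$between) >= 2 && min(table(subj$between)) >= 2) {
    fitb <- stats::aov(y ~ between, data = subj)
    tk <- stats::TukeyHSD(fitb)$between
    ph[[between]] <- data.frame(method = "tukey", effect = between,
                                pair = rownames(tk),
                                estimate = tk[, "diff"],
                                p_adj = tk[, "p adj"])
  }
  wl <- levels(d$within)
  mw <- tapply(d$y, d$within, mean)
  wp <- utils::combn(wl, 2)
  q <- abs(mw[wp[1, ]] - mw[wp[2, ]]) / sqrt(mse / n_subj)
  ph[[within]] <- data.frame(
    method = "tukey", effect = within,
    pair = paste(wp[1, ], wp[2, ], sep = "-"),
    estimate = unname(mw[wp[1, ]] - mw[wp[2, ]]),
    p_adj = stats::ptukey(q, length(wl), dfe, lower.tail = FALSE))
  if (int_sig) {
    rows <- list()
    for (g in levels(d$between)) {
      sub <- d[d$between == g, ]
      n_g <- length(unique(sub$subject))
      mg <- tapply(sub$y, sub$within, mean)
      for (j in seq_len(ncol(wp))) {
        est <- mg[wp[1, j]] - mg[wp[2, j]]
        tt <- est / sqrt(2 * mse / n_g)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste0(g, ":", wp[1, j], "-", g, ":", wp[2, j]),
          estimate = unname(est),
          p_raw = 2 * stats::pt(-abs(tt), dfe))
      }
    }
    bp <- utils::combn(levels(d$between), 2)
    for (w in wl) {
      for (j in seq_len(ncol(bp))) {
        a <- d$y[d$between == bp[1, j] & d$within == w]
        b <- d$y[d$between == bp[2, j] & d$within == w]
        tt <- stats::t.test(a, b, var.equal = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste0(bp[1, j], ":", w, "-", bp[2, j], ":", w),
          estimate = mean(a) - mean(b), p_raw = tt$p.value)
      }
    }
    cells <- do.call(rbind, rows)
    m <- nrow(cells)
    ph[["interaction"]] <- data.frame(
      method = "sidak", effect = int_label, pair = cells$pair,
      estimate = cells$estimate,
      p_adj = 1 - (1 - cells$p_raw)^m)
  }
  ph
}

#' Two-way ANOVA (between-subjects or mixed) with post hoc tests
#'
#' Between-subjects designs use Type II sums of squares. When
#' `repeated_on` names a within-subject factor, the design is analyzed as
#' a mixed repeated-measures ANOVA with a Greenhouse-Geisser sphericity
#' correction (fractional degrees of freedom) applied to within-subject
#' effects whenever the repeated factor has more than two levels. Post hoc
#' policy: Tukey on main effects; if the interaction is significant at
#' `alpha`, Sidak-adjusted comparisons of interaction cells.
#'
#' @param data Long data frame of units.
#' @param response,factor_a,factor_b Column names.
#' @param repeated_on Optional: one of `factor_a`/`factor_b` that is
#'   within-subject.
#' @param subject Subject identifier column (required with `repeated_on`).
#' @param alpha Significance level gating the interaction post hoc.
#' @return `fm_anova` list: `effects` (with `epsilon` where applicable)
#'   and `posthoc`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          repeated_on = NULL, subject = NULL,
                          alpha = 0.05) {
  stopifnot(is.data.frame(data))
  d <- data.frame(y = data[[response]],
                  a = factor(data[[factor_a]]),
                  b = factor(data[[factor_b]]))
  names(d)[2:3] <- c(factor_a, factor_b)
  if (is.null(repeated_on)) {
    f <- stats::as.formula(paste("y ~", factor_a, "*", factor_b))
    fit <- stats::lm(f, data = d)
    tab <- car::Anova(fit, type = 2)
    terms <- setdiff(rownames(tab), "Residuals")
    eff <- data.frame(effect = terms,
                      F = tab[terms, "F value"],
                      df1 = tab[terms, "Df"],
                      df2 = tab["Residuals", "Df"],
                      p = tab[terms, "Pr(>F)"],
                      epsilon = NA_real_)
    emm_fit <- fit
    ss_type <- "II"
  } else {
    if (is.null(subject)) stop("repeated-measures design requires 'subject'")
    if (!repeated_on %in% c(factor_a, factor_b)) {
      stop("'repeated_on' must be one of the two factors")
    }
    within <- repeated_on
    between <- setdiff(c(factor_a, factor_b), within)
    d$subject <- factor(data[[subject]])
    d$within <- d[[within]]
    d$between <- d[[between]]
    wide <- stats::reshape(
      d[, c("subject", "between", "within", "y")],
      idvar = c("subject", "between"), timevar = "within",
      direction = "wide")
    lvls <- paste0("y.", levels(d$within))
    if (anyNA(wide[, lvls])) {
      stop("incomplete repeated-measures design: each subject must be ",
           "observed at every level of '", within, "'", call. = FALSE)
    }
    rm <- .rm_anova_gg(wide, lvls, between = wide$between)
    eff <- rm$effects
    eff$effect <- sub("^g$", between, eff$effect)
    eff$effect <- sub("^g:level$", paste0(between, ":", within), eff$effect)
    eff$effect <- sub("^level$", within, eff$effect)
    ss_type <- "III (repeated measures, Greenhouse-Geisser)"
  }
  rownames(eff) <- NULL
  ph <- list()
  int_row <- grep(":", eff$effect)
  int_sig <- length(int_row) && isTRUE(eff$p[int_row[1]] < alpha)
  if (is.null(repeated_on)) {
    for (fac in c(factor_a, factor_b)) {
      em <- emmeans::emmeans(fit, stats::as.formula(paste0("~", fac)),
                             data = d)
      pr <- as.data.frame(emmeans::contrast(em, "pairwise",
                                            adjust = "tukey"))
      ph[[fac]] <- data.frame(method = "tukey", effect = fac,
                              pair = pr$contrast, estimate = pr$estimate,
                              p_adj = pr$p.value)
    }
    if (int_sig) {
      em <- emmeans::emmeans(
        fit, stats::as.formula(paste0("~", factor_a, "*", factor_b)),
        data = d)
      pr <- as.data.frame(emmeans::contrast(em, "pairwise",
                                            adjust = "sidak"))
      ph[["interaction"]] <- data.frame(
        method = "sidak", effect = eff$effect[int_row[1]],
        pair = pr$contrast, estimate = pr$estimate, p_adj = pr$p.value)
    }
  } else {
    ph <- .mixed_posthoc(d, between = setdiff(c(factor_a, factor_b),
                                              repeated_on),
                         within = repeated_on,
                         mse = rm$ms_error_within,
                         dfe = rm$df_error_within,
                         int_sig = int_sig,
                         int_label = if (length(int_row))
                           eff$effect[int_row[1]] else NA_character_)
  }
  posthoc <- if (length(ph)) do.call(rbind, ph) else
    data.frame(method = character(), effect = character(),
               pair = character(), estimate = numeric(),
               p_adj = numeric())
  rownames(posthoc) <- NULL
  structure(list(effects = eff, posthoc = posthoc, alpha = alpha,
                 ss_type = ss_type),
            class = "fm_anova")
}

#' Repeated-measures one-way ANOVA with Dunnett comparisons to baseline
#'
#' Analyzes a temporal-bin table (one baseline reference plus ordered
#' post-injection bins per animal) with a within-subject ANOVA under a
#' Greenhouse-Geisser correction, followed by Dunnett's many-to-one test
#' of each bin against the baseline bin. Dunnett adjusted p-values are
#' computed numerically from the equicorrelated multivariate t
#' distribution (correlation 1/2) on the within-subject error term.
#'
#' @param bins Bin table (`bins` element of [formalin_bins()]).
#' @param parameter Facial parameter to analyze.
#' @param control Label of the control bin.
#' @return `fm_anova` list with Dunnett post hoc rows.
#' @export
rm_anova_dunnett <- function(bins, parameter, control = "baseline") {
  stopifnot(is.data.frame(bins), parameter %in% names(bins))
  d <- data.frame(subject = factor(bins$animal_id),
                  bin = bins$bin_label, y = bins[[parameter]])
  lv <- unique(d$bin)
  lv <- c(control, setdiff(lv, control))
  d$bin <- factor(d$bin, levels = lv)
  wide <- stats::reshape(d, idvar = "subject", timevar = "bin",
                         direction = "wide")
  cols <- paste0("y.", lv)
  complete <- stats::complete.cases(wide[, cols])
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) without all bins were dropped")
    wide <- wide[complete, , drop = FALSE]
  }
  n <- nrow(wide)
  if (n < 3L) stop("need at least 3 complete subjects", call. = FALSE)
  rm <- .rm_anova_gg(wide, cols)
  eff <- rm$effects
  eff$effect <- sub("^level$", "bin", eff$effect)
  mse <- rm$ms_error_within
  dfe <- rm$df_error_within
  k <- length(lv) - 1L
  se <- sqrt(2 * mse / n)
  diffs <- vapply(seq_len(k), function(j) {
    mean(wide[[cols[j + 1L]]]) - mean(wide[[cols[1L]]])
  }, numeric(1))
  tstat <- if (se > 0) diffs / se else ifelse(diffs == 0, 0,
                                              sign(diffs) * Inf)
  corr <- matrix(0.5, k, k); diag(corr) <- 1
  p_adj <- vapply(tstat, function(tj) {
    if (!is.finite(tj)) return(0)
    if (tj == 0) return(1)
    1 - mvtnorm::pmvt(lower = rep(-abs(tj), k), upper = rep(abs(tj), k),
                      corr = corr, df = round(dfe),
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
  }, numeric(1))
  ph <- data.frame(method = "dunnett",
                   pair = paste(lv[-1], control, sep = "-"),
                   estimate = diffs,
                   t = tstat, p_adj = pmin(1, pmax(0, p_adj)))
  structure(list(effects = eff, posthoc = ph, alpha = 0.05,
                 ss_type = "repeated measures (Greenhouse-Geisser)",
                 n_subjects = n),
            class = "fm_anova")
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Inter-observer reliability of frame measurements: two-way random
#' effects, absolute agreement, single measure. Computed from the two-way
#' ANOVA mean squares (rows = items/frames, columns = raters):
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with the usual F-based confidence bounds.
#'
#' @param ratings Numeric matrix, items x raters (at least 5 items and 2
#'   raters, no missing cells).
#' @param conf_level Confidence level for the bounds.
#' @return List of class `fm_icc`: `value`, `lower`, `upper`, `model`,
#'   `n`, `k`, and the mean squares.
#' @export
icc <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (anyNA(x)) {
    x <- x[stats::complete.cases(x), , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 items")
  if (stats::var(rowMeans(x)) == 0 && all(apply(x, 2, stats::var) == 0)) {
    stop("ICC undefined: ratings constant across items", call. = FALSE)
  }
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom <= 0) stop("ICC undefined: zero total variance", call. = FALSE)
  val <- (MSR - MSE) / denom
  alpha <- 1 - conf_level
  # Satterthwaite df for the agreement form (McGraw & Wong 1996)
  Fj <- MSC / MSE
  a <- k * val / (n * (1 - val))
  b <- 1 + k * val * (n - 1) / (n * (1 - val))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(value = val, lower = lower, upper = upper,
                 model = "two-way random, absolute agreement, single measure",
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE,
                 conf_level = conf_level),
            class = "fm_icc")
}

#' @export
print.fm_icc <- function(x, ...) {
  cat("ICC(2,1) [", x$model, "]\n", sep = "")
  cat(sprintf("  %.3f  (%d%% CI %.3f-%.3f; n=%d items, k=%d raters)\n",
              x$value, round(100 * x$conf_level), x$lower, x$upper,
              x$n, x$k))
  invisible(x)
}

#' Pearson correlation control test
#'
#' Screens a covariate (weight, age) against a facial parameter with
#' Pearson's correlation; reports rho with its exact t statistic
#' (t = rho * sqrt(df / (1 - rho^2)), df = n - 2) and two-sided p.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Data frame: `rho`, `t`, `df`, `p`.
#' @export
pearson_control <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(rho = unname(ct$estimate), t = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value)
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample comparison with Satterthwaite (fractional)
#' degrees of freedom, used for sex and similar two-group controls.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return Data frame: `t`, `df`, `p_raw`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
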