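#' Two-factor repeated-measures ANOVA
#'
#' Fits the two-factor design used for sweep-based photoinactivation
#' data: row factor (e.g. spontaneous vs. whisker-evoked activity) and
#' column factor (e.g. control vs. light), with subjects = units. With
#' `design = "both_within"` both factors are within-subject and each
#' effect is tested against its effect-by-subject interaction mean
#' square; with `design = "mixed"` the column factor is between-subjects
#' and is tested against the between-subject residual. No sphericity
#' correction is applied: with two levels per within factor sphericity
#' holds trivially.
#'
#' Post-hoc: for each row-factor level, column-level pairs are compared
#' with a pooled-error t statistic (difference of means over
#' `sqrt(2 * MS_error / n)`, using the error stratum in which the column
#' factor is tested), Bonferroni-multiplied by the number of row levels.
#'
#' @param data data.frame with columns `subject`, `row`, `col`, `value`
#' @param design `"both_within"` or `"mixed"`
#' @return an object of class `anova_rm`: `effects` (SS, df, F, p per
#'   effect), `posthoc`, `strata` (all SS components), `total_ss`
#' @export
two_way_rm_anova <- function(data, design = c("both_within", "mixed")) {
  design <- match.arg(design)
  stopifnot(all(c("subject", "row", "col", "value") %in% names(data)))
  data <- data.frame(subject = factor(data$subject),
                     row = factor(data$row),
                     col = factor(data$col),
                     value = as.numeric(data$value))
  if (any(is.na(data$value))) stop("input error: missing response values")
  n_subj <- nlevels(data$subject)
  if (n_subj < 2L) stop("input error: at least 2 subjects required")
  tab <- table(data$subject, data$row, data$col)
  if (design == "both_within" && any(tab != 1L))
    stop("input error: within design requires one observation per subject per cell")

  fit <- if (design == "both_within") {
    aov(value ~ row * col + Error(subject / (row * col)), data = data)
  } else {
    # column factor varies between subjects; subjects are crossed with row
    aov(value ~ row * col + Error(subject / row), data = data)
  }
  sm <- summary(fit)

  strata <- do.call(rbind, lapply(names(sm), function(nm) {
    s <- as.data.frame(sm[[nm]][[1]])
    data.frame(stratum = sub("^Error: ", "", nm),
               term = trimws(rownames(s)),
               ss = s[["Sum Sq"]], df = s[["Df"]],
               F = if ("F value" %in% names(s)) s[["F value"]] else NA_real_,
               p = if ("Pr(>F)" %in% names(s)) s[["Pr(>F)"]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  eff <- strata[strata$term %in% c("row", "col", "row:col"), , drop = FALSE]
  err <- strata[strata$term == "Residuals", , drop = FALSE]
  eff$df_error <- vapply(eff$stratum, function(st) {
    err$df[match(st, err$stratum)]
  }, numeric(1))
  effects <- data.frame(effect = eff$term, ss = eff$ss, df = eff$df,
                        df_error = eff$df_error, F = eff$F, p = eff$p,
                        stringsAsFactors = FALSE)
  gm <- mean(data$value)
  total_ss <- sum((data$value - gm)^2)

  # pooled-error post-hoc on the column factor within each row level
  col_stratum <- if (design == "both_within") "subject:col" else "subject"
  ms_e <- err$ss[match(col_stratum, err$stratum)] /
    err$df[match(col_stratum, err$stratum)]
  df_e <- err$df[match(col_stratum, err$stratum)]
  row_levels <- levels(data$row)
  col_levels <- levels(data$col)
  m <- length(row_levels)
  ph <- list()
  for (rl in row_levels) {
    sub <- data[data$row == rl, , drop = FALSE]
    for (i in seq_len(length(col_levels) - 1L)) {
      for (j in seq(i + 1L, length(col_levels))) {
        m1 <- mean(sub$value[sub$col == col_levels[i]])
        m2 <- mean(sub$value[sub$col == col_levels[j]])
        nn <- min(sum(sub$col == col_levels[i]), sum(sub$col == col_levels[j]))
        tt <- (m1 - m2) / sqrt(2 * ms_e / nn)
        p_raw <- 2 * pt(-abs(tt), df_e)
        ph[[length(ph) + 1L]] <- data.frame(
          row_level = rl,
          comparison = paste(col_levels[i], "vs", col_levels[j]),
          estimate = m1 - m2, t = tt, df = df_e, p = p_raw,
          p_adj = bonferroni_adjust(p_raw, m),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(effects = effects,
                 posthoc = do.call(rbind, ph),
                 strata = strata,
                 total_ss = total_ss,
                 design = design), class = "anova_rm")
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("two-way rmANOVA (%s)\n", x$design))
  print(x$effects, row.names = FALSE)
  cat("post-hoc (Bonferroni):\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Bonferroni adjustment by multiplication
#'
#' Each p-value is multiplied by the number of comparisons and capped at
#' one.
#'
#' @param p_values numeric p-values in `[0, 1]`
#' @param m number of comparisons (>= 1)
#' @return adjusted p-values
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("input error: p-values must lie in [0, 1]")
  if (m < 1) stop("input error: m must be >= 1")
  pmin(1, p_values * m)
}

#' Robust outlier detection (ROUT-style, location-only case)
#'
#' Identifies outliers from a single sample the way robust regression
#' followed by outlier removal does for the intercept-only model: the
#' location is the median; the robust scale is the 68.27th percentile of
#' the absolute residuals with an `n/(n-1)` small-sample correction (the
#' robust analogue of the standard deviation); each point gets a
#' two-sided p-value from the t distribution of residual/scale with
#' `n - 1` degrees of freedom; and the most extreme 30% of points are
#' tested with a step-up false-discovery-rate threshold at rate `Q`,
#' flagging the largest set whose k-th smallest p-value is at most
#' `(Q/100) * k / n`. Flags are invariant under affine rescaling of the
#' data.
#'
#' @param values numeric vector, length >= 3
#' @param Q false-discovery rate, percent (default 1)
#' @return logical mask, `TRUE` for outliers
#' @export
rout_outliers <- function(values, Q = 1) {
  n <- length(values)
  if (n < 3L) stop("input error: need at least 3 values")
  resid <- values - median(values)
  p68 <- quantile(abs(resid), 0.6827, names = FALSE, type = 7)
  rsdr <- p68 * n / (n - 1)
  mask <- rep(FALSE, n)
  if (rsdr <= 0) {
    # degenerate spread: anything off the median mass is an outlier
    mask[abs(resid) > 0] <- TRUE
    return(mask)
  }
  df <- n - 1
  pvals <- 2 * pt(-abs(resid) / rsdr, df)
  ord <- order(pvals)                      # most extreme first
  n_cand <- max(1L, floor(0.3 * n))
  alpha <- (Q / 100) * seq_len(n_cand) / n
  hits <- which(pvals[ord[seq_len(n_cand)]] <= alpha)
  if (length(hits)) mask[ord[seq_len(max(hits))]] <- TRUE
  mask
}

#' t tests with explicit degenerate-case conventions
#'
#' Paired, unpaired (Student, pooled variance) or one-sample t test.
#' When the relevant variance is zero the test is decided by the mean
#' difference: identical means give `t = 0, p = 1` (no evidence of a
#' difference); a nonzero difference with zero variance gives
#' `t = +/-Inf, p = 0`.
#'
#' @param x numeric sample
#' @param y second sample (paired/unpaired modes)
#' @param mode `"paired"`, `"unpaired"` or `"one_sample"`
#' @param mu null value for the one-sample mode (default 0)
#' @return `list(t, df, p, estimate)`
#' @export
t_tests <- function(x, y = NULL,
                    mode = c("paired", "unpaired", "one_sample"),
                    mu = 0) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    stopifnot(!is.null(y), length(x) == length(y))
    d <- x - y
    return(.one_sample_t(d, 0))
  }
  if (mode == "one_sample") return(.one_sample_t(x, mu))
  stopifnot(!is.null(y))
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  est <- mean(x) - mean(y)
  df <- nx + ny - 2
  if (sp2 == 0) {
    if (est == 0) return(list(t = 0, df = df, p = 1, estimate = 0))
    return(list(t = sign(est) * Inf, df = df, p = 0, estimate = est))
  }
  tt <- est / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), estimate = est)
}

.one_sample_t <- function(x, mu) {
  n <- length(x)
  est <- mean(x) - mu
  s <- sd(x)
  if (s == 0) {
    if (est == 0) return(list(t = 0, df = n - 1, p = 1, estimate = 0))
    return(list(t = sign(est) * Inf, df = n - 1, p = 0, estimate = est))
  }
  tt <- est / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), estimate = est)
}

#' Linear-trend contrast across ordered groups
#'
#' Tests a linear trend in the group means of a one-way layout using
#' evenly spaced, centered contrast coefficients against the pooled
#' within-group mean square.
#'
#' @param groups ordered list of numeric samples (>= 3 groups)
#' @return `list(t, F, df, p, estimate)`; `estimate` is the contrast
#'   value on the group means
#' @export
linear_trend_contrast <- function(groups) {
  k <- length(groups)
  if (k < 3L) stop("input error: need at least 3 ordered groups")
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  cc <- seq_len(k) - mean(seq_len(k))
  L <- sum(cc * means)
  N <- sum(ns)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- N - k
  msw <- ssw / df
  if (msw == 0) {
    if (L == 0) return(list(t = 0, F = 0, df = df, p = 1, estimate = 0))
    return(list(t = sign(L) * Inf, F = Inf, df = df, p = 0, estimate = L))
  }
  se <- sqrt(msw * sum(cc^2 / ns))
  tt <- L / se
  list(t = tt, F = tt^2, df = df, p = 2 * pt(-abs(tt), df), estimate = L)
}
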