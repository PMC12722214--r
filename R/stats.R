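#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation between paired measurements with the usual
#' t-distributed test of zero correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for constant input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Intraclass correlation coefficient (two-way random, absolute agreement,
#' single measure)
#'
#' Computes ICC(A,1) in the McGraw-Wong nomenclature from the two-way
#' ANOVA mean squares of an n-subjects-by-2-raters layout: with `MSR`,
#' `MSC` and `MSE` the row (subject), column (rater) and residual mean
#' squares, \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' Unlike the Pearson correlation, absolute agreement penalizes additive
#' and multiplicative bias between the two measurements. The p-value uses
#' the McGraw-Wong F test with Satterthwaite denominator degrees of
#' freedom.
#'
#' @param x,y Paired measurements (e.g. estimated and true values).
#' @param variant Fixed to `"ICC(A,1)"`; recorded in the output.
#' @return List with `icc`, `p`, `n`, and `variant`.
#' @export
icc <- function(x, y, variant = "ICC(A,1)") {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs are required")
  k <- 2
  M <- cbind(x, y)
  G <- mean(M)
  SSR <- k * sum((rowMeans(M) - G)^2)
  SSC <- n * sum((colMeans(M) - G)^2)
  SST <- sum((M - G)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  r <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  Fv <- MSR / (a * MSC + b * MSE)
  p <- pf(Fv, n - 1, v, lower.tail = FALSE)
  list(icc = r, p = p, n = n, variant = variant)
}

#' Paired two-tailed t-test
#'
#' @param before,after Paired numeric vectors.
#' @return List with `t`, `p`, `df`, and a `flag` marking degenerate
#'   inputs: `"zero_differences"` (identical vectors; t = 0, p = 1) or
#'   `"constant_difference"` (non-zero shift with zero variance).
#' @export
paired_ttest <- function(before, after) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length")
  d <- after - before
  if (length(d) < 2) stop("at least 2 pairs are required")
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1,
                  flag = "zero_differences"))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                flag = "constant_difference"))
  }
  tt <- t.test(after, before, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), flag = "ok")
}

#' One-way ANOVA with Tukey's multiple-comparison correction
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return List with the ANOVA `F` statistic, its `p` value, and `tukey`,
#'   a data frame of two-sided Tukey honest-significant-difference pairwise
#'   comparisons (difference, confidence bounds, adjusted p).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 0.95)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], tukey = tukey)
}

#' Per-parameter recovery statistics over vial means
#'
#' For each varied phantom parameter, correlates estimated against true
#' vial means (Pearson and ICC(A,1)) and reports bias and RMSE. Parameters
#' whose truth is constant across vials carry bias/RMSE only.
#'
#' @param quant A [run_pipeline()] result.
#' @param truth The [make_digital_phantom()] dataset the maps were
#'   estimated from.
#' @return An object of class `cest_recovery_report`: `table` (one row per
#'   parameter: r, r_p, icc, icc_p, bias, rmse, n), `per_background` (the
#'   same statistics per MT background for amide and glutamate), `vials`
#'   (the vial-mean table), and metadata (`seed`, `noise_sigma`,
#'   `icc_variant`, `dictionary_hash`).
#' @export
phantom_recovery_report <- function(quant, truth) {
  vt <- vial_means(quant, truth)
  params <- list(f_ss = c("truth_f_ss", "est_f_ss"),
                 f_amide = c("truth_f_amide", "est_f_amide"),
                 glu_mM = c("truth_glu_mM", "est_glu_mM"))
  stat_row <- function(tv, ev) {
    bias <- mean(ev - tv)
    rmse <- sqrt(mean((ev - tv)^2))
    if (sd(tv) > 0) {
      pr <- pearson(tv, ev); ic <- icc(tv, ev)
      data.frame(r = pr$r, r_p = pr$p, icc = ic$icc, icc_p = ic$p,
                 bias = bias, rmse = rmse, n = length(tv))
    } else data.frame(r = NA_real_, r_p = NA_real_, icc = NA_real_,
                      icc_p = NA_real_, bias = bias, rmse = rmse,
                      n = length(tv))
  }
  tab <- do.call(rbind, lapply(names(params), function(pn) {
    cols <- params[[pn]]
    cbind(parameter = pn, stat_row(vt[[cols[1]]], vt[[cols[2]]]))
  }))
  per_bg <- do.call(rbind, lapply(names(params), function(pn) {
    cols <- params[[pn]]
    do.call(rbind, lapply(sort(unique(vt$background)), function(b) {
      sub <- vt[vt$background == b, ]
      if (sd(sub[[cols[1]]]) == 0) return(NULL)
      cbind(parameter = pn, background = b,
            stat_row(sub[[cols[1]]], sub[[cols[2]]]))
    }))
  }))
  structure(list(table = tab, per_background = per_bg, vials = vt,
                 seed = truth$seed, noise_sigma = truth$noise_sigma,
                 icc_variant = "ICC(A,1)",
                 dictionary_hash = quant$schedule_hash),
            class = "cest_recovery_report")
}

#' @export
print.cest_recovery_report <- function(x, ...) {
  cat(sprintf("<cest_recovery_report> %d vials, noise sigma = %g, seed = %d, ICC variant %s\n",
              nrow(x$vials), x$noise_sigma, x$seed, x$icc_variant))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Vial-mean table for a quantified phantom
#'
#' Averages every estimated map over each truth-vial mask and pairs the
#' result with the ground-truth values.
#'
#' @inheritParams phantom_recovery_report
#' @return Data frame with one row per (background, vial).
#' @export
vial_means <- function(quant, truth) {
  stopifnot(inherits(truth, "cest_phantom"))
  nb <- length(truth$spec$mt_fractions)
  nv <- length(truth$vial_amide)
  if (all(truth$vial_id == 0)) stop("phantom mask contains no vials")
  rows <- list()
  for (ib in seq_len(nb)) {
    for (v in seq_len(nv)) {
      pix <- truth$vial_id == v
      rows[[length(rows) + 1L]] <- data.frame(
        background = ib, vial = v,
        truth_f_ss = truth$spec$mt_fractions[ib],
        est_f_ss = mean(quant$maps$f_ss[, , ib][pix]),
        est_k_ssw = mean(quant$maps$k_ssw[, , ib][pix]),
        truth_f_amide = truth$vial_amide[v],
        est_f_amide = mean(quant$maps$f_amide[, , ib][pix]),
        est_k_amide = mean(quant$maps$k_amide[, , ib][pix]),
        truth_glu_mM = truth$vial_glu[v],
        est_glu_mM = mean(quant$maps$glu_mM[, , ib][pix]),
        est_k_glu = mean(quant$maps$k_glu[, , ib][pix]),
        est_f_rnoe = mean(quant$maps$f_rnoe[, , ib][pix]),
        est_k_rnoe = mean(quant$maps$k_rnoe[, , ib][pix]))
    }
  }
  do.call(rbind, rows)
}
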