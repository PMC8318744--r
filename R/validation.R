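#' Relative error in percent
#'
#' Signed relative error of a measured concentration against its reference:
#' `(C - C0) * 100 / C0`. Vectorized over both arguments.
#'
#' @param C Measured concentration(s) (ug/mL).
#' @param C0 Reference concentration(s) (ug/mL), nonzero.
#' @return Signed percent.
#' @export
#' @examples
#' relative_error(1.002, 1.000)  # 0.2
relative_error <- function(C, C0) {
  if (any(C0 == 0)) stop("reference concentration C0 must be nonzero",
                         call. = FALSE)
  (C - C0) * 100 / C0
}

#' Relative standard deviation in percent
#'
#' Repeatability of a replicate set: sample standard deviation (n-1
#' denominator) times 100 over the mean. Compared in validation reports
#' against half the Horwitz value ([horwitz_half_rsd()]).
#'
#' @param values Numeric vector of replicate measurements, n >= 2, finite.
#' @return RSD in percent.
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (any(!is.finite(values))) stop("replicates must be finite", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero", call. = FALSE)
  stats::sd(values) * 100 / m
}

#' Half the Horwitz repeatability bound
#'
#' The Horwitz function `RSD_H = 2^(1 - 0.5 * log10(C))` predicts the
#' expected between-laboratory RSD at mass fraction `C`; within-laboratory
#' repeatability is acceptable below half of it. `C` is a dimensionless
#' mass fraction: 5 ug/mL corresponds to `C = 5e-6`.
#'
#' @param C Mass fraction(s), strictly between 0 and 1.
#' @return Half-Horwitz RSD bound in percent (unrounded; round only when
#'   rendering a report).
#' @export
#' @examples
#' horwitz_half_rsd(5e-6)  # ~6.28
horwitz_half_rsd <- function(C) {
  if (any(!is.finite(C)) || any(C <= 0) || any(C >= 1))
    stop("C must be a mass fraction in (0, 1)", call. = FALSE)
  0.5 * 2^(1 - 0.5 * log10(C))
}

#' Limit of detection and quantification
#'
#' From replicate measurements of a solution near the expected detection
#' limit: `LOD = 3.3 * SD`, `LOQ = 10 * SD` with the sample (n-1) SD.
#' Guidance asks for at least seven aliquots; fewer (down to 2) is allowed
#' with a warning.
#'
#' @param values Replicate measured concentrations (ug/mL), n >= 2.
#' @param min_n Replicate count below which a warning is raised (default 7).
#' @return List with `lod`, `loq`, `sd`, `n` (ug/mL).
#' @export
lod_loq <- function(values, min_n = 7) {
  if (length(values) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (any(!is.finite(values))) stop("replicates must be finite", call. = FALSE)
  if (length(values) < min_n)
    warning("only ", length(values), " replicates (", min_n,
            " recommended for LOD/LOQ)", call. = FALSE)
  s <- stats::sd(values)
  list(lod = 3.3 * s, loq = 10 * s, sd = s, n = length(values))
}

#' Spike recovery in percent
#'
#' `(C2 - C1) * 100 / Cs`, pairing replicate k of each spiked level with
#' replicate k of the unspiked set. Vectorized. The conventional acceptance
#' window is 85-110 percent; flagging happens at the report layer.
#'
#' @param C2 Measured concentration of the spiked sample (ug/mL).
#' @param C1 Measured concentration of the unspiked sample (ug/mL).
#' @param Cs Spiked concentration (ug/mL), > 0.
#' @return Recovery in percent.
#' @export
#' @examples
#' recovery(3.512, 3.003, 0.500)  # 101.8
recovery <- function(C2, C1, Cs) {
  if (any(Cs <= 0)) stop("spike concentration Cs must be > 0", call. = FALSE)
  (C2 - C1) * 100 / Cs
}

#' Tablet preparation design
#'
#' The fixed arithmetic of the sample preparation chain: `m` mg of ground
#' tablet powder dissolved to 250 mL, of which 10 mL is diluted to 100 mL,
#' collapses to a dilution product of 2.5 so that
#' `mg/tablet = 2.5 * Ci * M / m`.
#'
#' @param M Average tablet weight (mg), > 0.
#' @param m Powder weight taken (mg), > 0.
#' @param dilution_product Fixed factor of the preparation chain
#'   (default 2.5 = 100 * 250 / 10 / 1000).
#' @return A `kf_tablet_design` list.
#' @export
tablet_design <- function(M, m, dilution_product = 2.5) {
  stopifnot(is.numeric(M), is.numeric(m), is.numeric(dilution_product))
  if (M <= 0 || m <= 0 || dilution_product <= 0)
    stop("tablet design values must be > 0", call. = FALSE)
  structure(list(M = M, m = m, dilution_product = dilution_product),
            class = "kf_tablet_design")
}

#' Drug content per tablet
#'
#' Converts the concentration measured in the final diluted solution to
#' mg per tablet: `dilution_product * Ci * M / m`.
#'
#' @param Ci Final-solution concentration(s) (ug/mL), >= 0.
#' @param design A [tablet_design()].
#' @return Content in mg/tablet.
#' @export
#' @examples
#' tablet_content(4.978, tablet_design(M = 253.4, m = 253.4))  # 12.445
tablet_content <- function(Ci, design) {
  stopifnot(inherits(design, "kf_tablet_design"))
  if (any(Ci < 0)) stop("concentration must be >= 0", call. = FALSE)
  design$dilution_product * Ci * design$M / design$m
}

#' Two-tailed F critical value for a variance-ratio test
#'
#' With the larger variance in the numerator, the two-tailed variance-ratio
#' test at level `alpha` compares against the upper `alpha/2` quantile:
#' `f_critical(0.05, 2, 2)` is 39.00.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Numerator and denominator degrees of freedom, >= 1.
#' @return Critical F value.
#' @export
f_critical <- function(alpha, df1, df2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  stats::qf(1 - alpha / 2, df1, df2)
}

#' Two-sided t critical value
#'
#' Quantile at `1 - alpha/2`: `t_critical(0.05, 4)` is 2.776.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom, >= 1.
#' @return Critical t value.
#' @export
t_critical <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (df < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' Two-method equivalence comparison (F test then pooled t test)
#'
#' Compares replicate results of two analytical methods (e.g. the filter
#' method against a reference HPLC assay). The variance-ratio F test puts
#' the larger sample variance in the numerator and compares against the
#' two-tailed critical value; the pooled-variance t test compares the means
#' with `t = |mean_a - mean_b| / (SD_pool * sqrt(1/n_a + 1/n_b))` on
#' `n_a + n_b - 2` degrees of freedom. The comparison is symmetric in its
#' two arguments.
#'
#' @param a,b Numeric replicate vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param labels Length-2 character vector naming the methods.
#' @return A `kf_method_comparison` with means, SDs, `F_exp`, `F_crit`,
#'   `sd_pool`, `t_exp`, `t_crit`, `df`, `alpha`, and logical verdicts
#'   `variances_equivalent`, `means_equivalent`.
#' @export
#' @examples
#' compare_methods(c(12.4450, 12.4375, 12.3825), c(12.45, 12.38, 12.42))
compare_methods <- function(a, b, alpha = 0.05,
                            labels = c("method_a", "method_b")) {
  if (length(a) < 2 || length(b) < 2)
    stop("each method needs at least 2 replicates", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("replicates must be finite", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va >= vb) {
    F_exp <- if (vb > 0) va / vb else if (va == 0) 1 else Inf
    dfn <- na - 1; dfd <- nb - 1
  } else {
    F_exp <- vb / va
    dfn <- nb - 1; dfd <- na - 1
  }
  df <- na + nb - 2
  sd_pool <- sqrt(((na - 1) * va + (nb - 1) * vb) / df)
  if (sd_pool == 0 && mean(a) != mean(b))
    stop("degenerate data: zero pooled SD with unequal means", call. = FALSE)
  t_exp <- if (sd_pool > 0)
    abs(mean(a) - mean(b)) / (sd_pool * sqrt(1 / na + 1 / nb)) else 0
  F_crit <- f_critical(alpha, dfn, dfd)
  t_crit <- t_critical(alpha, df)
  structure(list(labels = labels,
                 mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = na, n_b = nb,
                 F_exp = F_exp, F_crit = F_crit,
                 df_num = dfn, df_den = dfd,
                 sd_pool = sd_pool, t_exp = t_exp, t_crit = t_crit,
                 df = df, alpha = alpha,
                 variances_equivalent = F_exp < F_crit,
                 means_equivalent = t_exp < t_crit),
            class = "kf_method_comparison")
}

#' @export
print.kf_method_comparison <- function(x, ...) {
  cat(sprintf("Two-method comparison: %s vs %s (alpha = %g)\n",
              x$labels[1], x$labels[2], x$alpha))
  cat(sprintf("  %s: mean %.4f +/- %.4f (n = %d)\n",
              x$labels[1], x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  %s: mean %.4f +/- %.4f (n = %d)\n",
              x$labels[2], x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  F_exp = %.3f vs F(%g; %d; %d) = %.2f\n",
              x$F_exp, x$alpha, x$df_num, x$df_den, x$F_crit))
  cat(sprintf("  SD_pool = %.4f, t_exp = %.3f vs t(%g, %d) = %.3f\n",
              x$sd_pool, x$t_exp, x$alpha, x$df, x$t_crit))
  cat(if (x$variances_equivalent)
        "  The two methods show the same repeatability (F_exp < F_crit).\n"
      else
        "  The two methods differ in repeatability (F_exp >= F_crit).\n")
  cat(if (x$means_equivalent)
        "  The mean results are not significantly different (t_exp < t_crit).\n"
      else
        "  The mean results differ significantly (t_exp >= t_crit).\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of
#' printed assay tables), unlike base `round()`'s round-half-even.
#' Used only at the report-rendering layer; the computation engine never
#' rounds.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
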