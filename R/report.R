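#' Assemble a method-validation report
#'
#' Collects the individual validation statistics into one object with a
#' rendered text summary. Every section is optional; empty sections are
#' omitted. All statistics are computed at full precision; rounding
#' (half away from zero, to the customary table precision) happens only
#' when printing.
#'
#' @param accuracy Optional data frame of standard-mixture results with
#'   columns `design`, `component`, `replicate`, `measured`, `reference`
#'   (ug/mL). Yields per-replicate RE%, per-design RSD% and the
#'   half-Horwitz bound at the reference mass fraction.
#' @param content Optional list with `values` (data frame `sample`,
#'   `component`, `concentration` in ug/mL) and `design` (a
#'   [tablet_design()]). Yields mg/tablet per sample and per-component RSD.
#' @param recovery Optional data frame with columns `component`, `level`
#'   (spike concentration Cs, ug/mL; 0 rows are the unspiked base),
#'   `replicate`, `measured` (ug/mL). Replicate k of each spiked level is
#'   paired with replicate k of the unspiked base; recoveries outside
#'   85-110% are flagged.
#' @param lod Optional named list of replicate vectors (ug/mL), one per
#'   component, measured near the expected detection limit.
#' @param comparison Optional named list of `kf_method_comparison` objects
#'   (see [compare_methods()]).
#' @param alpha Significance level recorded in the report.
#' @return A `kf_validation_report` with one element per non-empty section.
#' @export
build_validation_report <- function(accuracy = NULL, content = NULL,
                                    recovery = NULL, lod = NULL,
                                    comparison = NULL, alpha = 0.05) {
  rep_ <- list(alpha = alpha)

  if (!is.null(accuracy) && nrow(accuracy) > 0) {
    need <- c("design", "component", "measured", "reference")
    if (!all(need %in% names(accuracy)))
      stop("accuracy needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    accuracy$re_pct <- relative_error(accuracy$measured, accuracy$reference)
    key <- interaction(accuracy$design, accuracy$component, drop = TRUE)
    summ <- do.call(rbind, lapply(split(accuracy, key), function(g) {
      data.frame(design = g$design[1], component = g$component[1],
                 n = nrow(g),
                 mean_measured = mean(g$measured),
                 reference = g$reference[1],
                 mean_re_pct = relative_error(mean(g$measured),
                                              g$reference[1]),
                 rsd_pct = if (nrow(g) >= 2) rsd_percent(g$measured)
                           else NA_real_,
                 half_horwitz_pct = horwitz_half_rsd(g$reference[1] * 1e-6))
    }))
    summ$rsd_acceptable <- summ$rsd_pct < summ$half_horwitz_pct
    rownames(summ) <- NULL
    rep_$accuracy <- list(replicates = accuracy, summary = summ)
  }

  if (!is.null(content) && nrow(content$values) > 0) {
    v <- content$values
    if (!all(c("sample", "component", "concentration") %in% names(v)))
      stop("content$values needs sample, component, concentration",
           call. = FALSE)
    v$mg_per_tablet <- tablet_content(v$concentration, content$design)
    summ <- do.call(rbind, lapply(split(v, v$component), function(g) {
      data.frame(component = g$component[1], n = nrow(g),
                 mean_mg = mean(g$mg_per_tablet),
                 sd_mg = if (nrow(g) >= 2) stats::sd(g$mg_per_tablet)
                         else NA_real_,
                 rsd_pct = if (nrow(g) >= 2) rsd_percent(g$mg_per_tablet)
                           else NA_real_)
    }))
    rownames(summ) <- NULL
    rep_$content <- list(values = v, summary = summ,
                         design = content$design)
  }

  if (!is.null(recovery) && nrow(recovery) > 0) {
    need <- c("component", "level", "replicate", "measured")
    if (!all(need %in% names(recovery)))
      stop("recovery needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    out <- NULL
    for (comp in unique(recovery$component)) {
      rc <- recovery[recovery$component == comp, ]
      base <- rc[rc$level == 0, ]
      if (nrow(base) == 0)
        stop("recovery design for ", comp, " lacks the unspiked level 0",
             call. = FALSE)
      base <- base[order(base$replicate), ]
      spiked <- rc[rc$level > 0, ]
      if (nrow(spiked)) {
        c1 <- base$measured[match(spiked$replicate, base$replicate)]
        if (anyNA(c1))
          stop("unmatched replicate in recovery pairing for ", comp,
               call. = FALSE)
        spiked$unspiked <- c1
        spiked$recovery_pct <- recovery(spiked$measured, c1, spiked$level)
        spiked$within_85_110 <- spiked$recovery_pct >= 85 &
          spiked$recovery_pct <= 110
        out <- rbind(out, spiked)
      }
    }
    if (!is.null(out)) {
      rownames(out) <- NULL
      rep_$recovery <- out
    }
  }

  if (!is.null(lod) && length(lod) > 0) {
    rep_$lod <- do.call(rbind, lapply(names(lod), function(comp) {
      ll <- lod_loq(lod[[comp]])
      data.frame(component = comp, n = ll$n, sd = ll$sd,
                 lod_ug_mL = ll$lod, loq_ug_mL = ll$loq)
    }))
  }

  if (!is.null(comparison) && length(comparison) > 0) {
    stopifnot(all(vapply(comparison, inherits, logical(1),
                         "kf_method_comparison")))
    rep_$comparison <- comparison
  }

  structure(rep_, class = "kf_validation_report")
}

#' @export
print.kf_validation_report <- function(x, ...) {
  cat("=== Method validation report (alpha =", x$alpha, ") ===\n")
  if (!is.null(x$accuracy)) {
    cat("\n-- Accuracy and repeatability (standard mixtures) --\n")
    s <- x$accuracy$summary
    s$mean_re_pct <- round_half_up(s$mean_re_pct, 2)
    s$rsd_pct <- round_half_up(s$rsd_pct, 2)
    s$half_horwitz_pct <- round_half_up(s$half_horwitz_pct, 2)
    s$mean_measured <- round_half_up(s$mean_measured, 3)
    print(s, row.names = FALSE)
  }
  if (!is.null(x$content)) {
    cat("\n-- Tablet content --\n")
    s <- x$content$summary
    s$mean_mg <- round_half_up(s$mean_mg, 2)
    s$sd_mg <- round_half_up(s$sd_mg, 2)
    s$rsd_pct <- round_half_up(s$rsd_pct, 2)
    print(s, row.names = FALSE)
  }
  if (!is.null(x$recovery)) {
    cat("\n-- Spike recovery (acceptable 85-110%) --\n")
    s <- x$recovery
    s$recovery_pct <- round_half_up(s$recovery_pct, 2)
    print(s[, c("component", "level", "replicate", "measured",
                "recovery_pct", "within_85_110")], row.names = FALSE)
  }
  if (!is.null(x$lod)) {
    cat("\n-- Limits of detection and quantification --\n")
    s <- x$lod
    s$lod_ug_mL <- signif(s$lod_ug_mL, 3)
    s$loq_ug_mL <- signif(s$loq_ug_mL, 3)
    print(s, row.names = FALSE)
  }
  if (!is.null(x$comparison)) {
    cat("\n-- Two-method comparison --\n")
    for (nm in names(x$comparison)) {
      cat("[", nm, "]\n", sep = "")
      print(x$comparison[[nm]])
    }
  }
  invisible(x)
}
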