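#' Pair per-pesticide odds ratios from two scans
#'
#' Inner-joins the meta-analytic rows of two [run_pwas()] results (typically
#' duration-based vs intensity-based) on pesticide id and computes the ratio
#' of odds ratios (ROR = OR_a / OR_b), its log, and the geometric mean of the
#' two ORs (the x-axis of the Bland-Altman ratio plot).
#'
#' @param results_a,results_b `pwas_result` objects run on the same
#'   participants.
#' @param selection `"intersection"` (pesticides discovered at the nominal
#'   FDR in both scans), `"union"` (discovered in either), `"all"` (every
#'   pesticide present in both result sets), or an explicit character vector
#'   of pesticide ids.
#' @param fdr FDR level defining discovery for the set selections.
#' @return A `paired_or` `data.table` with `pesticide_id`, `or_a`, `or_b`,
#'   `ror`, `log_ror`, `geometric_mean`; attributes record the two metrics.
#' @export
paired_or_table <- function(results_a, results_b, selection = "intersection",
                            fdr = 0.05) {
  ma <- as.data.table(results_a)[loc_type == "meta"]
  mb <- as.data.table(results_b)[loc_type == "meta"]
  if (is.character(selection) && length(selection) == 1L &&
      selection %in% c("intersection", "union", "all")) {
    da <- ma[q < fdr, pesticide_id]
    db <- mb[q < fdr, pesticide_id]
    sel <- switch(selection,
                  intersection = intersect(da, db),
                  union = union(da, db),
                  all = union(ma$pesticide_id, mb$pesticide_id))
  } else sel <- selection
  pairs <- merge(ma[pesticide_id %in% sel, .(pesticide_id, beta_a = beta, or_a = or)],
                 mb[pesticide_id %in% sel, .(pesticide_id, beta_b = beta, or_b = or)],
                 by = "pesticide_id")
  if (nrow(pairs) == 0L) stop_config("no pesticides common to both result sets")
  pairs[, ror := or_a / or_b]
  pairs[, log_ror := log(ror)]
  pairs[, geometric_mean := sqrt(or_a * or_b)]
  setattr(pairs, "metric_a", attr(results_a, "metric"))
  setattr(pairs, "metric_b", attr(results_b, "metric"))
  setattr(pairs, "class", c("paired_or", class(pairs)))
  pairs[]
}

#' Bland-Altman agreement analysis of paired odds ratios
#'
#' Computed on the log scale, the standard convention when ratios are plotted
#' against geometric means: with `d_i = log ROR_i`, the bias is `exp(mean d)`
#' and the 95% limits of agreement are `exp(mean d +/- 1.96 sd d)`. Precision
#' intervals use the classical approximations `se_bias = sd/sqrt(n)` and
#' `se_loa = sd * sqrt(3/n)` with t(n-1) quantiles, exponentiated back to the
#' ratio scale.
#'
#' @param pairs A [paired_or_table()] result (>= 3 pairs).
#' @return List with `n`, `bias`, `loa_low`, `loa_high`, `ci_bias`,
#'   `ci_loa_low`, `ci_loa_high` (each a length-2 vector), and `sd_log_ror`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$log_ror
  n <- length(d)
  if (n < 3L) stop_config("Bland-Altman analysis needs at least 3 pairs")
  m <- mean(d); s <- sd(d)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  tq <- qt(0.975, n - 1)
  list(
    n = n,
    bias = exp(m),
    loa_low = exp(m - 1.96 * s), loa_high = exp(m + 1.96 * s),
    ci_bias = exp(m + c(-1, 1) * tq * se_bias),
    ci_loa_low = exp(m - 1.96 * s + c(-1, 1) * tq * se_loa),
    ci_loa_high = exp(m + 1.96 * s + c(-1, 1) * tq * se_loa),
    sd_log_ror = s
  )
}

#' Paired t-test on log odds ratios
#'
#' One-sample two-sided t-test of the log RORs against zero: do the two
#' exposure metrics yield systematically different effect estimates?
#'
#' @param pairs A [paired_or_table()] result (>= 2 pairs).
#' @return List with `t_stat`, `df`, `p`, `mean_ratio` (exp of the mean log
#'   ROR), `ci` (95% CI of the ratio), `flag` for degenerate inputs.
#' @export
paired_t_log_or <- function(pairs) {
  d <- pairs$log_ror
  if (length(d) < 2L) stop_config("paired t-test needs at least 2 pairs")
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t_stat = NA_real_, df = length(d) - 1, p = 1,
                  mean_ratio = 1, ci = c(1, 1), flag = "all_identical"))
    return(list(t_stat = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_ratio = exp(mean(d)), ci = exp(c(mean(d), mean(d))),
                flag = "zero_variance"))
  }
  tt <- t.test(d, mu = 0)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_ratio = exp(unname(tt$estimate)),
       ci = exp(as.numeric(tt$conf.int)), flag = NA_character_)
}

#' Pearson correlation of paired per-pesticide estimates
#'
#' Correlates the two scans' per-pesticide log-OR estimates (a measure of
#' cross-metric agreement in effect ranking, computed on the log scale).
#'
#' @param pairs A [paired_or_table()] result (>= 3 pairs).
#' @return List with `r`, `p`, `n`, `flag`.
#' @export
or_correlation <- function(pairs) {
  a <- log(pairs$or_a); b <- log(pairs$or_b)
  if (length(a) < 3L) stop_config("correlation needs at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(a), flag = "zero_variance"))
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
       flag = NA_character_)
}

#' Combined agreement summary of two scans
#'
#' @param pairs A [paired_or_table()] result.
#' @return List with components `bland_altman`, `paired_t`, `correlation`.
#' @export
agreement_summary <- function(pairs) {
  list(bland_altman = bland_altman(pairs),
       paired_t = paired_t_log_or(pairs),
       correlation = or_correlation(pairs))
}

#' Bland-Altman ratio plot
#'
#' Ratio of odds ratios against the geometric mean of the paired ORs, with
#' the bias line and shaded 95% limits of agreement. Requires ggplot2.
#'
#' @param pairs A [paired_or_table()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_config("ggplot2 is required for plotting")
  ba <- bland_altman(pairs)
  df <- as.data.frame(pairs)
  ggplot2::ggplot(df, ggplot2::aes(x = geometric_mean, y = ror)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = ba$loa_low, ymax = ba$loa_high,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, colour = "red") +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Geometric mean of paired ORs", y = "Ratio of ORs")
}
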