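# Per-substrate inference: Welch tests, BH adjustment, five-outcome
# classification, census statistics, and printed-precision consistency
# checks.

# Vectorised Welch machinery shared by welch_test() and
# summarize_substrates(). Degenerate rows (both SDs zero) yield NA.
welch_stats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- abs(mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t[se == 0] <- NA_real_
  df[se == 0] <- NA_real_
  p <- ifelse(is.na(t), NA_real_,
              ifelse(t == 0, 1, 2 * stats::pt(t, df, lower.tail = FALSE)))
  data.frame(t = t, df = df, p = p)
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Compares two group means given their means, standard deviations and
#' sample sizes: `t = |mean1 - mean2| / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The df
#' never exceed `n1 + n2 - 2`, with equality exactly when the two standard
#' errors coincide.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @return List with elements `t`, `df`, `p`.
#' @examples
#' welch_test(1.0, 0.1, 5, 0.5, 0.1, 5) # t ~ 7.906, df = 8
#' @export
welch_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  for (v in c("mean1", "sd1", "n1", "mean2", "sd2", "n2")) {
    stop_if_not_scalar_number(get(v), v)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    stop("degenerate comparison: both standard deviations are zero")
  }
  res <- welch_stats(mean1, sd1, n1, mean2, sd2, n2)
  list(t = res$t, df = res$df, p = res$p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment of a vector of p-values, capped at 1 and
#' monotone-enforced, returned in input order. `NA` entries (untested
#' hypotheses) are excluded from the family before adjustment and stay
#' `NA`, so absent values never inflate the family size.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Classify a substrate comparison into the five outcomes
#'
#' Applies the endpoint classification used for each substrate, based on
#' the two strain means (day-7 replicate-mean A750), the BH-adjusted
#' p-value, and the measurable-growth thresholds:
#'
#' 1. negligible growth by both strains (both means <= `lower`);
#' 2. measurable growth by both but no significant difference
#'    (`p_adj` absent or >= `alpha`);
#' 3. measurable growth by the EHB+ strain only;
#' 4. measurable growth by both with the EHB- strain denser (also returned,
#'    with the `mirror` attribute set, for the mirror case of measurable
#'    EHB- growth and negligible EHB+ growth, which the five-outcome scheme
#'    does not name);
#' 5. measurable growth by both with the EHB+ strain denser.
#'
#' A significant difference with exactly equal means has no direction and
#' is an error (it cannot arise from real data at printed precision).
#'
#' @param mean_plus,mean_minus endpoint means for the EHB+ and EHB- strain.
#' @param p_adj BH-adjusted p-value, or `NA` when untested.
#' @param thresholds a [growth_thresholds()] object.
#' @return Integer outcome code in 1..5 with logical attribute `mirror`.
#' @examples
#' classify_outcome(1.49, 1.16, 1e-6)  # 5
#' classify_outcome(0.25, 0.15, NA)    # 1
#' @export
classify_outcome <- function(mean_plus, mean_minus, p_adj = NA_real_,
                             thresholds = growth_thresholds()) {
  stop_if_not_scalar_number(mean_plus, "mean_plus")
  stop_if_not_scalar_number(mean_minus, "mean_minus")
  meas_p <- is_measurable(mean_plus, thresholds)
  meas_m <- is_measurable(mean_minus, thresholds)
  if ((!meas_p && mean_plus > thresholds$lower) ||
      (!meas_m && mean_minus > thresholds$lower)) {
    stop("endpoint mean above the measurable range (> ", thresholds$upper,
         "); outcome undefined")
  }
  mirror <- FALSE
  code <- if (!meas_p && !meas_m) {
    1L
  } else if (meas_p && !meas_m) {
    3L
  } else if (!meas_p && meas_m) {
    mirror <- TRUE
    4L
  } else if (is.na(p_adj) || p_adj >= thresholds$alpha) {
    2L
  } else if (mean_plus == mean_minus) {
    stop("significant difference with exactly equal means: ",
         "direction undefined")
  } else if (mean_plus > mean_minus) {
    5L
  } else {
    4L
  }
  structure(code, mirror = mirror)
}

#' Per-substrate endpoint comparison of two strains
#'
#' Builds the per-substrate summary table from a kinetic dataset: for every
#' non-control substrate, the endpoint (day-7, 750 nm by default) per-plate
#' values give each strain's mean and SD; strains are compared with Welch
#' t-tests; BH adjustment is applied across exactly the substrates where at
#' least one strain shows measurable growth (substrates negligible for both
#' strains are not part of the testing family and keep an absent adjusted
#' p, mirroring the published table's `NA` convention); and each substrate
#' receives its outcome code via [classify_outcome()].
#'
#' @param dataset a [kinetic_dataset()] with exactly two strains.
#' @param layout plate layout.
#' @param thresholds a [growth_thresholds()] object.
#' @param strains character of length 2 naming the (plus, minus) strains;
#'   defaults to the dataset's strains in stored order.
#' @return A `substrate_summary` data frame with 95 rows and columns
#'   `substrate`, `class`, `mean_plus`, `sd_plus`, `mean_minus`,
#'   `sd_minus`, `t`, `df`, `p_raw`, `p_adj`, `outcome`, `mirror`.
#' @export
summarize_substrates <- function(dataset, layout = ff_plate_layout(),
                                 thresholds = growth_thresholds(),
                                 strains = NULL) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (is.null(strains)) strains <- dataset$strains
  if (length(strains) != 2L || !all(strains %in% dataset$strains)) {
    stop("`strains` must name the (plus, minus) pair present in the dataset")
  }
  em <- endpoint_matrix(dataset, layout, wavelength = 750,
                        time = thresholds$endpoint_day,
                        include_control = FALSE)
  sample_strain <- sub("_[^_]*$", "", rownames(em))
  xp <- em[sample_strain == strains[1], , drop = FALSE]
  xm <- em[sample_strain == strains[2], , drop = FALSE]
  n1 <- nrow(xp)
  n2 <- nrow(xm)
  mean_plus <- colMeans(xp)
  mean_minus <- colMeans(xm)
  sd_plus <- apply(xp, 2, sd)
  sd_minus <- apply(xm, 2, sd)
  w <- welch_stats(mean_plus, sd_plus, n1, mean_minus, sd_minus, n2)

  tested <- is_measurable(mean_plus, thresholds) |
    is_measurable(mean_minus, thresholds)
  p_adj <- rep(NA_real_, ncol(em))
  p_adj[tested] <- bh_adjust(w$p[tested])

  outcome <- integer(ncol(em))
  mirror <- logical(ncol(em))
  for (j in seq_len(ncol(em))) {
    oc <- classify_outcome(mean_plus[j], mean_minus[j], p_adj[j], thresholds)
    outcome[j] <- as.integer(oc)
    mirror[j] <- attr(oc, "mirror")
  }

  keep <- layout[!layout$is_control, ]
  out <- data.frame(
    substrate = colnames(em),
    class = keep$class[match(colnames(em), keep$substrate)],
    mean_plus = unname(mean_plus), sd_plus = unname(sd_plus),
    mean_minus = unname(mean_minus), sd_minus = unname(sd_minus),
    t = w$t, df = w$df, p_raw = w$p, p_adj = p_adj,
    outcome = outcome, mirror = mirror,
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("substrate_summary", "data.frame")
  out
}

#' Census of substrate-use outcomes
#'
#' Aggregate statistics over the 95-substrate panel, recomputed from the
#' rule primitives (endpoint means, the measurable-growth thresholds,
#' adjusted p-values and the direction of the difference) rather than from
#' any stored outcome labels, so the census is reproducible from printed
#' means and p-values alone. Substrates with measurable growth by the EHB+
#' strain only ("plus-only") count toward `n_plus_higher` when significant,
#' which is how the published prose counts them. Percentages are of the
#' panel size, rounded to the nearest whole percent.
#'
#' @param rows a `substrate_summary` data frame covering the 95 substrates;
#'   the water-control row must have been excluded (its presence is an
#'   error).
#' @param thresholds a [growth_thresholds()] object.
#' @return A `census_report` list with counts `n_substrates`, `used_plus`,
#'   `used_minus`, `n_significant`, `n_plus_higher`, `n_minus_higher`,
#'   `n_no_difference`, `n_plus_only`, `n_negligible_both`, percentage
#'   fields, and `per_class_fractions` (per substrate class, the fraction
#'   significant with the EHB+ strain denser).
#' @export
census <- function(rows, thresholds = growth_thresholds()) {
  stopifnot(is.data.frame(rows))
  if (any(rows$substrate == "water") ||
      (!is.null(rows$is_control) && any(rows$is_control))) {
    stop("the water control row must be excluded from the census")
  }
  need <- c("substrate", "class", "mean_plus", "mean_minus", "p_adj")
  if (!all(need %in% names(rows))) {
    stop("census rows need columns ", paste(need, collapse = ", "))
  }
  n <- nrow(rows)
  meas_p <- is_measurable(rows$mean_plus, thresholds)
  meas_m <- is_measurable(rows$mean_minus, thresholds)
  negl_p <- rows$mean_plus <= thresholds$lower
  negl_m <- rows$mean_minus <= thresholds$lower
  sig <- !is.na(rows$p_adj) & rows$p_adj < thresholds$alpha
  plus_higher <- sig & rows$mean_plus > rows$mean_minus
  minus_higher <- sig & rows$mean_minus > rows$mean_plus
  pct <- function(k) as.integer(round(100 * k / n))
  frac <- tapply(plus_higher, rows$class, mean)
  structure(list(
    n_substrates = n,
    used_plus = sum(meas_p),
    used_minus = sum(meas_m),
    n_significant = sum(sig),
    n_plus_higher = sum(plus_higher),
    n_minus_higher = sum(minus_higher),
    n_no_difference = sum(meas_p & meas_m & !sig),
    n_plus_only = sum(meas_p & negl_m),
    n_negligible_both = sum(negl_p & negl_m),
    pct_plus_higher = pct(sum(plus_higher)),
    pct_minus_higher = pct(sum(minus_higher)),
    pct_significant = pct(sum(sig)),
    per_class_fractions = setNames(as.numeric(frac), names(frac)),
    alpha = thresholds$alpha
  ), class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat("Substrate-use census (", x$n_substrates, " substrates, alpha = ",
      x$alpha, ")\n", sep = "")
  cat(sprintf("  used by EHB+ strain:        %d\n", x$used_plus))
  cat(sprintf("  used by EHB- strain:        %d\n", x$used_minus))
  cat(sprintf("  significantly different:    %d (%d%%)\n",
              x$n_significant, x$pct_significant))
  cat(sprintf("    EHB+ denser:              %d (%d%%)\n",
              x$n_plus_higher, x$pct_plus_higher))
  cat(sprintf("    EHB- denser:              %d (%d%%)\n",
              x$n_minus_higher, x$pct_minus_higher))
  cat(sprintf("  measurable EHB+ only:       %d\n", x$n_plus_only))
  cat(sprintf("  no difference:              %d\n", x$n_no_difference))
  cat(sprintf("  negligible growth by both:  %d\n", x$n_negligible_both))
  invisible(x)
}

# f(u) = Welch-Satterthwaite df as a function of the variance ratio
# u = (s1/s2)^2 at equal n; maximal (2(n-1)) at u = 1, tending to n-1 as
# u -> 0 or Inf.
ws_df_ratio <- function(u, n) {
  ifelse(is.infinite(u), n - 1, (n - 1) * (1 + u)^2 / (1 + u^2))
}

#' Attainable Welch t and df intervals under printed rounding
#'
#' Summary tables print means and SDs rounded to a fixed number of
#' decimals, so a t statistic recomputed from the printed values need not
#' match the printed t. This computes the exact interval of (t, df)
#' attainable from any true means within +/- half a printed unit of the
#' printed means and any true SDs within the same band (floored at 0),
#' using monotonicity: t grows with the mean gap and shrinks with either
#' SD; df depends only on the variance ratio and peaks when the two
#' standard errors are equal.
#'
#' @param mean_plus,sd_plus,mean_minus,sd_minus printed summary values.
#' @param n replicates per group (default 5).
#' @param digits printed decimal places (default 2).
#' @return List with `t_lower`, `t_upper`, `df_lower`, `df_upper`.
#' @export
welch_interval <- function(mean_plus, sd_plus, mean_minus, sd_minus,
                           n = 5, digits = 2) {
  half <- 0.5 * 10^(-digits)
  dm <- abs(mean_plus - mean_minus)
  dm_lo <- max(0, dm - 2 * half)
  dm_hi <- dm + 2 * half
  s1 <- c(max(0, sd_plus - half), sd_plus + half)
  s2 <- c(max(0, sd_minus - half), sd_minus + half)
  se <- function(a, b) sqrt((a^2 + b^2) / n)
  t_upper <- if (se(s1[1], s2[1]) == 0) Inf else dm_hi / se(s1[1], s2[1])
  t_lower <- dm_lo / se(s1[2], s2[2])
  u_lo <- (s1[1] / s2[2])^2
  u_hi <- if (s2[1] == 0) Inf else (s1[2] / s2[1])^2
  df_at <- ws_df_ratio(c(u_lo, u_hi), n)
  df_upper <- if (u_lo <= 1 && u_hi >= 1) 2 * (n - 1) else max(df_at)
  df_lower <- min(df_at)
  list(t_lower = t_lower, t_upper = t_upper,
       df_lower = df_lower, df_upper = df_upper)
}

#' Printed-precision consistency of an endpoint table
#'
#' Checks, for every row of a summary table with a printed t and df,
#' whether the printed values are consistent with the printed means and
#' SDs once rounding is taken into account: the printed t (itself rounded)
#' must intersect the attainable [welch_interval()] for t, and likewise for
#' df.
#'
#' @param rows a `substrate_summary` data frame (default: the packaged
#'   endpoint table).
#' @param n replicates per group (default 5).
#' @param digits printed decimal places (default 2).
#' @return Data frame with one row per checked input row: the attainable
#'   bounds, `t_ok`, `df_ok` and `consistent`.
#' @export
table1_consistency <- function(rows = load_table1(), n = 5, digits = 2) {
  half <- 0.5 * 10^(-digits)
  keep <- is.finite(rows$t) & is.finite(rows$df)
  rows <- rows[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    iv <- welch_interval(rows$mean_plus[i], rows$sd_plus[i],
                         rows$mean_minus[i], rows$sd_minus[i],
                         n = n, digits = digits)
    t_ok <- rows$t[i] >= iv$t_lower - half & rows$t[i] <= iv$t_upper + half
    df_ok <- rows$df[i] >= iv$df_lower - half &
      rows$df[i] <= iv$df_upper + half
    data.frame(substrate = rows$substrate[i],
               t_printed = rows$t[i], t_lower = iv$t_lower,
               t_upper = iv$t_upper, df_printed = rows$df[i],
               df_lower = iv$df_lower, df_upper = iv$df_upper,
               t_ok = t_ok, df_ok = df_ok, consistent = t_ok && df_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
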