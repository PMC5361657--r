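# Channel arithmetic, replicate aggregation, growth thresholding and
# endpoint extraction.

#' Measurable-growth thresholds and endpoint settings
#'
#' Bundles the analysis constants: measurable growth is defined as
#' `lower < A750 <= upper` on the day-`endpoint_day` replicate mean, with
#' defaults 0.3 (strict lower bound, separating lag-phase noise from
#' log-phase growth) and 3.0 (inclusive upper bound, 99.9% light
#' absorbance). `alpha` is the significance level applied to
#' BH-adjusted p-values.
#'
#' @param lower strict lower absorbance bound (default 0.3).
#' @param upper inclusive upper absorbance bound (default 3.0).
#' @param endpoint_day endpoint used for all inferential comparisons, in
#'   days (default 7).
#' @param alpha significance level (default 0.05).
#' @return A `growth_thresholds` object.
#' @export
growth_thresholds <- function(lower = 0.3, upper = 3.0, endpoint_day = 7.0,
                              alpha = 0.05) {
  stop_if_not_scalar_number(lower, "lower")
  stop_if_not_scalar_number(upper, "upper")
  stop_if_not_scalar_number(endpoint_day, "endpoint_day")
  stop_if_not_scalar_number(alpha, "alpha")
  if (lower < 0 || lower >= upper) stop("need 0 <= lower < upper")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(lower = lower, upper = upper, endpoint_day = endpoint_day,
                 alpha = alpha),
            class = "growth_thresholds")
}

#' Corrected redox absorbance
#'
#' The redox (formazan) signal at 490 nm also picks up light scattered by
#' hyphae; since mycelium absorbs evenly from 490 to 750 nm, subtracting the
#' turbidity channel isolates respiration: `Ac490 = A490 - A750`. Values are
#' not clamped; negative corrected values (blank-level noise) are preserved.
#'
#' @param a490,a750 absorbance values (vectorised).
#' @return `a490 - a750`, possibly negative.
#' @examples
#' corrected_absorbance(1.0, 0.4) # 0.6
#' @export
corrected_absorbance <- function(a490, a750) {
  if (length(a490) != length(a750)) stop("inputs must have equal length")
  if (!all(is.finite(a490)) || !all(is.finite(a750))) {
    stop("absorbance values must be finite")
  }
  a490 - a750
}

#' Mean absorbance over replicate plates
#'
#' The per-condition summary absorbance is the arithmetic mean over
#' replicate plates at a given strain, well, wavelength and time.
#'
#' @param dataset a [kinetic_dataset()].
#' @param strain,well,wavelength,time coordinate of the reading.
#' @return The mean absorbance (scalar).
#' @export
replicate_mean <- function(dataset, strain, well, wavelength, time) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  r <- dataset$readings
  sel <- r$strain == strain & r$well == well &
    r$wavelength == wavelength & abs(r$time_d - time) < 1e-9
  vals <- r$absorbance[sel]
  if (length(vals) != dataset$n_rep) {
    stop("expected ", dataset$n_rep, " replicates at ", strain, "/", well,
         "/", wavelength, " nm/day ", time, ", found ", length(vals))
  }
  mean(vals)
}

#' Is growth measurable?
#'
#' Measurable growth is `lower < a <= upper`: the lower bound is strict
#' (endpoint absorbance exactly at the bound is lag-phase, negligible
#' growth) and the upper bound inclusive.
#'
#' @param a absorbance value(s).
#' @param thresholds a [growth_thresholds()] object.
#' @return Logical vector.
#' @examples
#' is_measurable(c(0.3, 0.66, 3.0, 3.01)) # FALSE TRUE TRUE FALSE
#' @export
is_measurable <- function(a, thresholds = growth_thresholds()) {
  if (!all(is.finite(a))) stop("absorbance values must be finite")
  a > thresholds$lower & a <= thresholds$upper
}

#' Per-plate endpoint matrix
#'
#' Extracts the sample-by-substrate table used by the distance-based global
#' comparisons: one row per replicate plate (strain x replicate), one column
#' per substrate, holding the raw per-plate absorbance at the requested
#' wavelength and time. The water control column is dropped unless
#' `include_control = TRUE`.
#'
#' @param dataset a [kinetic_dataset()].
#' @param layout plate layout mapping wells to substrates.
#' @param wavelength 490 or 750 (default 750, the turbidity channel).
#' @param time time point in days; must lie on the dataset's grid.
#' @param include_control keep the water-control column (default `FALSE`).
#' @return Numeric matrix with rownames `"<strain>_<replicate>"` and
#'   substrate colnames.
#' @export
endpoint_matrix <- function(dataset, layout = ff_plate_layout(),
                            wavelength = 750, time,
                            include_control = FALSE) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  validate_plate_layout(layout)
  if (!any(abs(dataset$time_grid - time) < 1e-9)) {
    stop("time ", time, " d is not on the dataset's time grid")
  }
  keep <- if (include_control) layout else layout[!layout$is_control, ]
  r <- dataset$readings
  r <- r[r$wavelength == wavelength & abs(r$time_d - time) < 1e-9 &
           r$well %in% keep$well, , drop = FALSE]
  sample_levels <- as.vector(t(outer(dataset$strains, dataset$replicates,
                                     paste, sep = "_")))
  sid <- factor(paste(r$strain, r$replicate, sep = "_"),
                levels = sample_levels)
  sub <- factor(keep$substrate[match(r$well, keep$well)],
                levels = keep$substrate)
  m <- matrix(NA_real_, nrow = length(sample_levels), ncol = nrow(keep),
              dimnames = list(sample_levels, keep$substrate))
  m[cbind(as.integer(sid), as.integer(sub))] <- r$absorbance
  if (anyNA(m)) stop("endpoint matrix has missing cells")
  m
}

#' Rank correlation between the redox and turbidity channels
#'
#' Computes Kendall's tau-b (mid-ranks for ties) between the corrected
#' redox channel (mean Ac490 over replicates) and the turbidity channel
#' (mean A750) across strain-by-substrate means. By default every time
#' point on the grid contributes a pair; pass `time` to restrict to one
#' time point. Because tau is a rank statistic it is invariant under the
#' strictly monotone log transform often applied before plotting the two
#' channels, so `log = TRUE` (which requires strictly positive values)
#' changes nothing but is provided for parity.
#'
#' @param dataset a [kinetic_dataset()].
#' @param layout plate layout; control well included (it is a row of the
#'   endpoint table like any other).
#' @param time optional single time point in days (default: all).
#' @param log log-transform both channels first (requires positive values).
#' @return Kendall's tau-b (scalar).
#' @export
channel_correlation <- function(dataset, layout = ff_plate_layout(),
                                time = NULL, log = FALSE) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  r <- dataset$readings
  if (!is.null(time)) {
    if (!any(abs(dataset$time_grid - time) < 1e-9)) {
      stop("time ", time, " d is not on the dataset's time grid")
    }
    r <- r[abs(r$time_d - time) < 1e-9, , drop = FALSE]
  }
  agg <- stats::aggregate(absorbance ~ strain + well + time_d + wavelength,
                          data = r, FUN = mean)
  a490 <- agg[agg$wavelength == 490, ]
  a750 <- agg[agg$wavelength == 750, ]
  key <- function(d) paste(d$strain, d$well, format(d$time_d), sep = "\r")
  idx <- match(key(a490), key(a750))
  x <- corrected_absorbance(a490$absorbance, a750$absorbance[idx])
  y <- a750$absorbance[idx]
  if (length(x) < 2L) stop("need at least 2 channel pairs")
  if (isTRUE(log)) {
    if (any(x <= 0) || any(y <= 0)) {
      stop("log transform requires strictly positive channel values")
    }
    x <- base::log(x)
    y <- base::log(y)
  }
  stats::cor(x, y, method = "kendall")
}
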