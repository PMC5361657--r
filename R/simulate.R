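# Seeded generator of two-strain phenotype-array kinetic datasets with
# planted per-substrate outcomes.

#' Logistic growth curve
#'
#' `b + K / (1 + exp(-r (t - t_mid)))`: a baseline optical density `b`
#' (well plus medium), a carrying capacity `K` reached at stationary
#' phase, a growth rate `r` (per day) and a midpoint `t_mid` (days) at
#' which half the capacity is reached. `K = 0` gives the flat no-growth
#' control well.
#'
#' @param t time in days (vectorised).
#' @param K carrying capacity (absorbance, >= 0).
#' @param r growth rate (per day, > 0).
#' @param t_mid inflection time (days).
#' @param b baseline absorbance.
#' @return Absorbance values.
#' @examples
#' logistic_curve(2.5, K = 1, r = 2, t_mid = 2.5, b = 0.1) # b + K/2
#' @export
logistic_curve <- function(t, K, r, t_mid, b) {
  if (any(K < 0)) stop("K must be >= 0")
  if (any(r <= 0)) stop("r must be > 0")
  b + K / (1 + exp(-r * (t - t_mid)))
}

# Draw per-substrate growth archetypes with planted outcome codes.
# Runs inside the config's seeded RNG scope.
make_archetypes <- function(layout, effect_size, proportions) {
  subs <- layout[!layout$is_control, ]
  codes <- sample(rep(as.integer(names(proportions)), proportions))
  n <- length(codes)
  r <- runif(n, 1.5, 3)
  t_mid <- runif(n, 2, 3.5)
  K_plus <- numeric(n)
  K_minus <- numeric(n)
  for (i in seq_len(n)) {
    switch(codes[i],
      { K_plus[i] <- runif(1, 0.01, 0.10)           # 1: negligible both
        K_minus[i] <- runif(1, 0.01, 0.10) },
      { K_plus[i] <- K_minus[i] <- runif(1, 0.5, 1.6) }, # 2: equal
      { K_plus[i] <- runif(1, 0.4, 0.8)             # 3: EHB+ only
        K_minus[i] <- runif(1, 0.01, 0.05) },
      { K_minus[i] <- runif(1, 0.5, 1.6) + effect_size  # 4: EHB- higher
        K_plus[i] <- K_minus[i] - effect_size },
      { K_minus[i] <- runif(1, 0.5, 1.6)            # 5: EHB+ higher
        K_plus[i] <- K_minus[i] + effect_size }
    )
  }
  out <- data.frame(
    well = c(subs$well, layout$well[layout$is_control]),
    substrate = c(subs$substrate, layout$substrate[layout$is_control]),
    code = c(codes, NA_integer_),
    K_plus = c(K_plus, 0), K_minus = c(K_minus, 0),
    r = c(r, 1), t_mid = c(t_mid, 3),
    stringsAsFactors = FALSE
  )
  out[match(layout$well, out$well), , drop = FALSE]
}

#' Configure a synthetic phenotype-array experiment
#'
#' Describes a two-strain, 96-well kinetic experiment with planted
#' per-substrate outcomes. Each substrate receives a growth archetype: an
#' outcome code (1 negligible both, 2 equal measurable growth, 3
#' measurable EHB+ only, 4/5 a planted capacity gap of `effect_size` in
#' favour of EHB- or EHB+) plus logistic parameters drawn once,
#' deterministically from `seed`. The default outcome composition (17
#' negligible, 15 equal, 2 plus-only, 5 minus-higher, 56 plus-higher)
#' mirrors the rule-based census of the packaged endpoint table, and the
#' default effect size 0.3 matches its typical significant endpoint gap;
#' noise is Gaussian with SD 0.03 per reading, truncated at zero (plate
#' readers report nonnegative optical density).
#'
#' @param seed integer seed; the planted truth and the noise stream are
#'   both deterministic functions of it.
#' @param n_rep replicate plates per strain (default 5).
#' @param time_grid reading times in days (default 0.5 to 7 by 0.5).
#' @param noise_sd per-reading Gaussian noise SD (default 0.03).
#' @param redox_gain dimensionless gain coupling cumulative growth to the
#'   redox channel (default 0.6, >= 0): the 490 nm signal is turbidity
#'   plus `redox_gain` times noiseless cumulative growth, so the noiseless
#'   corrected channel is nondecreasing, emulating irreversible formazan
#'   accumulation.
#' @param baseline well baseline absorbance (default 0.1).
#' @param effect_size planted capacity gap for outcome 4/5 substrates
#'   (default 0.3).
#' @param proportions named integer vector giving the number of substrates
#'   planted with each outcome code; must sum to 95.
#' @param layout plate layout (default [ff_plate_layout()]).
#' @param archetypes optional pre-built archetype table overriding the
#'   seeded draw.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed = 1, n_rep = 5,
                              time_grid = seq(0.5, 7, by = 0.5),
                              noise_sd = 0.03, redox_gain = 0.6,
                              baseline = 0.1, effect_size = 0.3,
                              proportions = c(`1` = 17, `2` = 15, `3` = 2,
                                              `4` = 5, `5` = 56),
                              layout = NULL, archetypes = NULL) {
  stop_if_not_scalar_number(seed, "seed")
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  stop_if_not_scalar_number(redox_gain, "redox_gain")
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (redox_gain < 0) stop("redox_gain must be >= 0")
  if (length(time_grid) < 2L || is.unsorted(time_grid)) {
    stop("time_grid must be an increasing vector of times")
  }
  if (is.null(layout)) layout <- ff_plate_layout()
  validate_plate_layout(layout)
  if (is.null(archetypes)) {
    if (!all(names(proportions) %in% as.character(1:5))) {
      stop("proportions must be named by outcome codes 1..5")
    }
    if (sum(proportions) != 95L) stop("proportions must sum to 95")
    archetypes <- with_seed(seed,
                            make_archetypes(layout, effect_size, proportions))
  }
  if (nrow(archetypes) != 96L ||
      any(archetypes$K_plus[is.na(archetypes$code)] != 0)) {
    stop("archetypes must cover 96 wells with a zero-capacity control")
  }
  structure(list(seed = seed, n_rep = as.integer(n_rep),
                 time_grid = time_grid, noise_sd = noise_sd,
                 redox_gain = redox_gain, baseline = baseline,
                 effect_size = effect_size, layout = layout,
                 archetypes = archetypes),
            class = "simulation_config")
}

#' Generate a synthetic two-strain kinetic dataset
#'
#' Simulates the full study design (two strains, `n_rep` replicate plates,
#' 96 wells, the 14-point twice-daily reading schedule, two wavelengths)
#' from a [simulation_config()]. For every reading, turbidity is the
#' archetype's logistic curve plus truncated Gaussian noise; the 490 nm
#' channel is the same turbidity plus `redox_gain` times the noiseless
#' cumulative growth plus its own noise, so the noiseless corrected redox
#' channel never decreases. Identical configurations (hence identical
#' seeds) yield bit-identical datasets.
#'
#' @param config a [simulation_config()].
#' @return A `pm_simulation` list: `dataset` (a [kinetic_dataset()]),
#'   `truth` (planted outcome code and growth parameters per substrate)
#'   and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  arch <- config$archetypes
  strains <- c("EHB+", "EHB-")
  grid <- expand.grid(time_d = config$time_grid, well = arch$well,
                      replicate = seq_len(config$n_rep), strain = strains,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ai <- match(grid$well, arch$well)
  K <- ifelse(grid$strain == "EHB+", arch$K_plus[ai], arch$K_minus[ai])
  mu <- logistic_curve(grid$time_d, K, arch$r[ai], arch$t_mid[ai],
                       config$baseline)
  n <- nrow(grid)
  # noise stream offset well away from the archetype/permutation seeds
  readings <- with_seed(config$seed + 1000003L, {
    a750 <- pmax(0, mu + rnorm(n, 0, config$noise_sd))
    a490 <- pmax(0, a750 + config$redox_gain * (mu - config$baseline) +
                   rnorm(n, 0, config$noise_sd))
    rbind(
      data.frame(strain = grid$strain, replicate = grid$replicate,
                 well = grid$well, wavelength = 490, time_d = grid$time_d,
                 absorbance = a490, stringsAsFactors = FALSE),
      data.frame(strain = grid$strain, replicate = grid$replicate,
                 well = grid$well, wavelength = 750, time_d = grid$time_d,
                 absorbance = a750, stringsAsFactors = FALSE)
    )
  })
  dataset <- kinetic_dataset(readings, layout = config$layout,
                             time_grid = config$time_grid)
  truth <- arch[!is.na(arch$code),
                c("well", "substrate", "code", "K_plus", "K_minus",
                  "r", "t_mid")]
  rownames(truth) <- NULL
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "pm_simulation")
}

#' Write the planted truth of a simulation as TSV
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
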