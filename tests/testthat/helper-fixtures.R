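# Shared fixtures, built in code at test time.

# The FF layout is deterministic; cache it once per test run.
.layout <- NULL
test_layout <- function() {
  if (is.null(.layout)) .layout <<- ff_plate_layout()
  .layout
}

# A complete long-format readings table with constant absorbance, the
# smallest dataset that satisfies the completeness contract.
flat_readings <- function(strains = c("EHB+", "EHB-"), n_rep = 1,
                          times = seq(0.5, 7, by = 0.5), value = 0.2) {
  layout <- test_layout()
  grid <- expand.grid(strain = strains, replicate = seq_len(n_rep),
                      well = layout$well, wavelength = c(490, 750),
                      time_d = times, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$absorbance <- value
  grid
}

# Distance matrix for n samples of multivariate Gaussian noise.
random_profile_matrix <- function(n_samples, n_vars, seed) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_samples * n_vars, mean = 1, sd = 0.3)),
              nrow = n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)), NULL))
  m
}

# Independent brute-force enumeration of two-group labelings via combn,
# deliberately different machinery from the package's recursive
# enumeration. `stat_fun` maps a label vector to a statistic.
brute_force_two_group <- function(n, n1, labels = c("A", "B"), stat_fun) {
  picks <- utils::combn(n, n1)
  apply(picks, 2, function(idx) {
    g <- rep(labels[2], n)
    g[idx] <- labels[1]
    stat_fun(g)
  })
}

# Direct double-loop PERMANOVA pseudo-F, written independently of the
# package implementation.
oracle_permanova_F <- function(m, g) {
  n <- nrow(m)
  a <- length(unique(g))
  sst <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    sst <- sst + m[i, j]^2
  }
  sst <- sst / n
  ssw <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    s <- 0
    if (length(idx) > 1) {
      pairs <- utils::combn(idx, 2)
      for (k in seq_len(ncol(pairs))) {
        s <- s + m[pairs[1, k], pairs[2, k]]^2
      }
    }
    ssw <- ssw + s / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

oracle_anosim_R <- function(m, g) {
  n <- nrow(m)
  dvals <- c()
  between <- c()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    dvals <- c(dvals, m[i, j])
    between <- c(between, g[i] != g[j])
  }
  rk <- rank(dvals)
  (mean(rk[between]) - mean(rk[!between])) / (length(dvals) / 2)
}

oracle_mrpp_delta <- function(m, g) {
  n <- nrow(m)
  out <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    pairs <- utils::combn(idx, 2)
    dsum <- 0
    for (k in seq_len(ncol(pairs))) dsum <- dsum + m[pairs[1, k], pairs[2, k]]
    out <- out + (length(idx) / n) * dsum / ncol(pairs)
  }
  out
}
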