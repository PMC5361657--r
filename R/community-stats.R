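# From-scratch distance-based multivariate statistics: Bray-Curtis,
# PERMANOVA, ANOSIM, MRPP (Monte-Carlo or exact enumeration), UPGMA
# dendrograms, and the per-time-point global scan.

#' Bray-Curtis dissimilarity
#'
#' `bray_curtis()` computes `sum(|x - y|) / sum(x + y)` between two
#' nonnegative profiles; `bray_curtis_matrix()` computes all pairwise
#' dissimilarities among the rows of a sample-by-substrate matrix.
#' Negative entries (blank-corrected turbidity noise) are clamped to zero
#' with a warning reporting how many cells were affected; a pair of
#' all-zero profiles has no defined dissimilarity and is an error.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @param m sample-by-variable numeric matrix with rownames.
#' @param warn_clamp warn when negative entries are clamped (default
#'   `TRUE`); the clamp count is always recorded.
#' @return `bray_curtis()` a scalar in \[0, 1\]; `bray_curtis_matrix()` a
#'   [stats::dist] object with a `clamped` attribute counting clamped
#'   cells.
#' @examples
#' bray_curtis(c(2, 1), c(1, 1)) # 0.2
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("profiles must be finite")
  }
  neg <- sum(x < 0) + sum(y < 0)
  if (neg > 0) {
    warning("clamped ", neg, " negative value(s) to 0 for Bray-Curtis")
    x <- pmax(x, 0)
    y <- pmax(y, 0)
  }
  tot <- sum(x + y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero profiles")
  sum(abs(x - y)) / tot
}

#' @rdname bray_curtis
#' @export
bray_curtis_matrix <- function(m, warn_clamp = TRUE) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (!all(is.finite(m))) stop("matrix entries must be finite")
  clamped <- sum(m < 0)
  if (clamped > 0) {
    if (warn_clamp) {
      warning("clamped ", clamped, " negative value(s) to 0 for Bray-Curtis")
    }
    m <- pmax(m, 0)
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least two samples")
  rs <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (rs[i] + rs[j] == 0) {
        stop("Bray-Curtis undefined for all-zero samples ", i, " and ", j)
      }
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / (rs[i] + rs[j])
    }
  }
  structure(as.dist(d), clamped = clamped)
}

#' Permutation-test settings
#'
#' @param n_perm number of random permutations (default 1000).
#' @param seed RNG seed for the permutation stream, or `NULL` to use the
#'   current stream.
#' @param exact_enumeration enumerate all distinct relabelings instead of
#'   sampling (feasible for small designs; the observed labeling is part of
#'   the enumeration).
#' @return A `permutation_settings` object.
#' @export
permutation_settings <- function(n_perm = 1000, seed = NULL,
                                 exact_enumeration = FALSE) {
  stop_if_not_scalar_number(n_perm, "n_perm")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 exact_enumeration = isTRUE(exact_enumeration)),
            class = "permutation_settings")
}

check_grouping <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n) stop("`groups` must label every sample")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  groups
}

# All distinct permutations of a label vector (multiset permutations),
# returned as a matrix with one labeling per row. Guarded against
# combinatorial explosion; enumeration is meant for small designs.
all_relabelings <- function(groups) {
  g <- as.integer(as.factor(groups))
  counts <- tabulate(g)
  total <- round(exp(lgamma(length(g) + 1) - sum(lgamma(counts + 1))))
  if (total > 1e5) {
    stop("exact enumeration over ", total,
         " labelings is infeasible; use Monte-Carlo permutations")
  }
  recurse <- function(counts, prefix) {
    if (sum(counts) == 0L) return(list(prefix))
    out <- list()
    for (lev in which(counts > 0L)) {
      counts2 <- counts
      counts2[lev] <- counts2[lev] - 1L
      out <- c(out, recurse(counts2, c(prefix, lev)))
    }
    out
  }
  mat <- do.call(rbind, recurse(counts, integer(0)))
  levs <- levels(as.factor(groups))
  matrix(levs[mat], nrow = nrow(mat))
}

# Shared permutation driver: given a statistic function of a grouping and
# the direction in which large values are extreme ("ge") or small ("le"),
# return the permutation p-value and the permuted statistics.
perm_pvalue <- function(stat_fun, groups, settings, obs, direction = "ge",
                        tol = 1e-12) {
  extreme <- switch(direction,
                    ge = function(v) v >= obs - tol,
                    le = function(v) v <= obs + tol)
  if (settings$exact_enumeration) {
    labs <- all_relabelings(groups)
    stats <- apply(labs, 1L, stat_fun)
    list(p = mean(extreme(stats)), n = nrow(labs), stats = stats,
         exact = TRUE)
  } else {
    stats <- with_seed(settings$seed, {
      vapply(seq_len(settings$n_perm),
             function(i) stat_fun(sample(groups)), numeric(1))
    })
    list(p = (1 + sum(extreme(stats))) / (1 + settings$n_perm),
         n = settings$n_perm, stats = stats, exact = FALSE)
  }
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix. With `N` samples in `a` groups,
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` sums the within-group
#' pair terms scaled by group size, `SS_between` is their difference,
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))` and `R2 =
#' SS_between/SS_total`. The p-value counts permuted pseudo-F values at
#' least as large as the observed one; under Monte-Carlo sampling the
#' `(1 + count)/(1 + n_perm)` convention is used (the observed labeling
#' counts as one permutation, so p is never 0), while exact enumeration
#' averages over all distinct labelings, the observed one included. A
#' perfectly separated design has `SS_within = 0` and reports `F = Inf`.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @param groups group labels, one per sample.
#' @param settings a [permutation_settings()] object.
#' @return A `perm_test` list with `statistic` (pseudo-F), `R2`,
#'   `p_value`, `ss` (total/within/between), `df`, `n_perm`, `exact`.
#' @export
permanova <- function(d, groups, settings = permutation_settings()) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- check_grouping(groups, n)
  a <- nlevels(groups)
  m2 <- m^2
  ss_total <- sum(m2) / (2 * n)
  ss_within_of <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      s <- s + sum(m2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ssw <- ss_within_of(groups)
  ssb <- ss_total - ssw
  f_obs <- ((ssb) / (a - 1)) / (ssw / (n - a))
  perm <- perm_pvalue(f_of, groups, settings, f_obs, direction = "ge")
  structure(list(method = "PERMANOVA",
                 statistic = c(F = f_obs),
                 R2 = ssb / ss_total,
                 p_value = perm$p,
                 ss = c(total = ss_total, within = ssw, between = ssb),
                 df = c(between = a - 1L, within = n - a),
                 n_perm = perm$n, exact = perm$exact),
            class = "perm_test")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a distance matrix: all
#' `M = N(N-1)/2` pairwise distances are ranked (mid-ranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M/2)`.
#' `R` lies in \[-1, 1\] and equals 1 exactly when every between-group
#' distance exceeds every within-group distance. The permutation p-value
#' follows the same conventions as [permanova()].
#'
#' @inheritParams permanova
#' @return A `perm_test` list with `statistic` (R), `p_value`, `n_perm`,
#'   `exact`.
#' @export
anosim <- function(d, groups, settings = permutation_settings()) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- check_grouping(groups, n)
  lower <- lower.tri(m)
  ranks <- rank(m[lower])
  M <- n * (n - 1) / 2
  r_of <- function(g) {
    within <- outer(g, g, "==")[lower]
    (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
  }
  r_obs <- r_of(groups)
  perm <- perm_pvalue(r_of, groups, settings, r_obs, direction = "ge")
  structure(list(method = "ANOSIM",
                 statistic = c(R = r_obs),
                 p_value = perm$p,
                 n_perm = perm$n, exact = perm$exact),
            class = "perm_test")
}

#' Multi-response permutation procedure (MRPP)
#'
#' Computes the observed weighted mean within-group distance
#' `delta_obs = sum_g w_g * mean(d within g)` with group weights
#' `w_g = n_g / N` by default (`weight_type = 1`; types 2 and 3 use
#' `n_g - 1` and `n_g (n_g - 1) / 2`, normalised), the chance-corrected
#' within-group agreement `A = 1 - delta_obs / delta_exp` where
#' `delta_exp` is the mean of delta over permuted labelings (all distinct
#' labelings under exact enumeration), and a p-value counting permuted
#' deltas at most as large as the observed one (small delta = tight
#' groups), with the same conventions as [permanova()].
#'
#' @inheritParams permanova
#' @param weight_type group weighting: 1 (`n_g`, the default community-
#'   ecology convention), 2 (`n_g - 1`) or 3 (`n_g (n_g - 1) / 2`).
#' @return A `perm_test` list with `statistic` (A), `delta`, `delta_exp`,
#'   `p_value`, `n_perm`, `exact`.
#' @export
mrpp <- function(d, groups, settings = permutation_settings(),
                 weight_type = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- check_grouping(groups, n)
  if (!weight_type %in% 1:3) stop("weight_type must be 1, 2 or 3")
  delta_of <- function(g) {
    levs <- unique(g)
    w <- numeric(length(levs))
    dbar <- numeric(length(levs))
    for (k in seq_along(levs)) {
      idx <- which(g == levs[k])
      ng <- length(idx)
      dbar[k] <- mean(m[idx, idx][lower.tri(m[idx, idx])])
      w[k] <- switch(weight_type, ng, ng - 1, ng * (ng - 1) / 2)
    }
    sum(w / sum(w) * dbar)
  }
  delta_obs <- delta_of(groups)
  perm <- perm_pvalue(delta_of, groups, settings, delta_obs,
                      direction = "le")
  delta_exp <- mean(perm$stats)
  structure(list(method = "MRPP",
                 statistic = c(A = 1 - delta_obs / delta_exp),
                 delta = delta_obs, delta_exp = delta_exp,
                 p_value = perm$p,
                 n_perm = perm$n, exact = perm$exact),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  ", names(x$statistic), " = ", format(x$statistic, digits = 4),
      sep = "")
  if (!is.null(x$R2)) cat(", R2 = ", format(x$R2, digits = 4), sep = "")
  cat("\n  p = ", format(x$p_value, digits = 4), " (",
      if (x$exact) "exact enumeration, " else "",
      x$n_perm, if (x$exact) " labelings)" else " permutations)",
      "\n", sep = "")
  invisible(x)
}

#' Agglomerative cluster dendrogram in Newick form
#'
#' Builds an average-linkage (UPGMA, the default), single- or
#' complete-linkage dendrogram from a distance matrix and returns it as a
#' Newick string with branch lengths derived from merge heights (an
#' ultrametric tree: two samples at distance 0.4 sit at height 0.2 below
#' their join). Ties are broken deterministically by input order.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @param linkage `"average"` (UPGMA), `"single"`, or `"complete"`.
#' @param file optional path; when given the Newick string is also written
#'   there.
#' @return The Newick string (invisibly returns the same when writing).
#' @export
upgma_dendrogram <- function(d, linkage = c("average", "single", "complete"),
                             file = NULL) {
  linkage <- match.arg(linkage)
  d <- as.dist(as.matrix(d))
  if (attr(d, "Size") < 2L) stop("need at least two samples")
  hc <- hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(file)) {
    writeLines(nwk, file, useBytes = TRUE)
    return(invisible(nwk))
  }
  nwk
}

#' Global substrate-use comparison at every time point
#'
#' For each time point on the dataset's grid, extracts the per-plate
#' turbidity profile across all substrates ([endpoint_matrix()]), computes
#' Bray-Curtis dissimilarities among the replicate plates (negative values
#' clamped to zero, with a total clamp count recorded), and tests the
#' strain grouping with [permanova()], [anosim()] and [mrpp()] under
#' shared settings. When a seed is supplied, each time point uses a
#' deterministic offset of it so the whole scan is reproducible.
#'
#' @param dataset a [kinetic_dataset()].
#' @param layout plate layout.
#' @param settings a [permutation_settings()] object.
#' @param wavelength channel for the profiles (default 750 nm, turbidity).
#' @param include_control include the water-control column (default
#'   `FALSE`: dissimilarity considers growth across all substrates).
#' @return A `global_scan` data frame with one row per time point and
#'   columns `time`, `permanova_F`, `permanova_R2`, `permanova_p`,
#'   `anosim_R`, `anosim_p`, `mrpp_A`, `mrpp_p`, `n_perm`, plus a
#'   `clamped` attribute with the total number of clamped cells.
#' @export
global_scan <- function(dataset, layout = ff_plate_layout(),
                        settings = permutation_settings(),
                        wavelength = 750, include_control = FALSE) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  clamped <- 0L
  rows <- lapply(seq_along(dataset$time_grid), function(i) {
    t <- dataset$time_grid[i]
    em <- endpoint_matrix(dataset, layout, wavelength = wavelength,
                          time = t, include_control = include_control)
    d <- bray_curtis_matrix(em, warn_clamp = FALSE)
    clamped <<- clamped + attr(d, "clamped")
    groups <- sub("_[^_]*$", "", labels(d))
    st <- settings
    if (!is.null(st$seed)) st$seed <- st$seed + i
    pm <- permanova(d, groups, st)
    an <- anosim(d, groups, st)
    mr <- mrpp(d, groups, st)
    data.frame(time = t,
               permanova_F = unname(pm$statistic),
               permanova_R2 = pm$R2,
               permanova_p = pm$p_value,
               anosim_R = unname(an$statistic),
               anosim_p = an$p_value,
               mrpp_A = unname(mr$statistic),
               mrpp_p = mr$p_value,
               n_perm = pm$n_perm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clamped") <- clamped
  class(out) <- c("global_scan", "data.frame")
  out
}

#' Write a global scan as TSV
#'
#' Writes the per-time-point comparison in the conventional column order
#' (day, then PERMANOVA F/R2/p, ANOSIM R/p, MRPP A/p).
#'
#' @param scan a [global_scan()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_global_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "global_scan"))
  out <- data.frame(
    day = scan$time,
    F = scan$permanova_F, R2 = scan$permanova_R2,
    p_permanova = scan$permanova_p,
    R = scan$anosim_R, p_anosim = scan$anosim_p,
    A = scan$mrpp_A, p_mrpp = scan$mrpp_p,
    n_perm = scan$n_perm,
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
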