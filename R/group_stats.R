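#' Two-sided Mann-Whitney U test
#'
#' Wraps \code{\link[stats]{wilcox.test}} with an explicit rule for the exact
#' path: the exact null distribution is used when both samples have at most 8
#' observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b numeric samples (missing values dropped; each group needs at
#'   least 2 non-missing values).
#' @param exact override the automatic exact/approximate choice.
#' @return list with \code{U} (the Mann-Whitney U statistic for \code{a}),
#'   \code{p} (two-sided p-value) and \code{exact} (logical path taken).
#' @examples
#' mwuTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mwuTest <- function(a, b, exact = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two non-missing values")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (length(a) <= 8L && length(b) <= 8L && !ties)
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  # degenerate pooled sample (every value tied): no evidence either way
  if (is.na(p)) p <- 1
  list(U = unname(ht$statistic), p = p, exact = exact)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via \eqn{\chi^2 = -2 \sum \ln p_i} on
#' \eqn{2k} degrees of freedom.
#'
#' @param p numeric vector of p-values, each in (0, 1].
#' @return list with \code{chi2}, \code{df} and the combined \code{p}.
#' @examples
#' fisherCombine(c(0.05, 0.05))  # chi2 ~ 11.98, df 4, p ~ 0.0175
#' @export
fisherCombine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values to combine")
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

## Normal-approximation two-sided MWU p from a rank sum, matching
## wilcox.test(correct = TRUE)'s approximate path (tie + continuity
## correction). Used for observed AND permuted statistics inside the
## permutation test so the two are compared on the same scale.
.mwu_p_approx <- function(R1, n1, n2, tiecorr, N) {
  U <- R1 - n1 * (n1 + 1) / 2
  z <- U - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) * ((N + 1) - tiecorr / (N * (N - 1))))
  if (sigma == 0) return(rep(1, length(U)))
  zc <- (z - sign(z) * 0.5) / sigma
  p <- 2 * pmin(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE))
  pmin(1, p)
}

## Reduce one feature over the window to per-well observations.
## Returns list(values, well) where `well` labels each observation.
.window_values <- function(features, feature, window, reducer) {
  stopifnot(feature %in% names(features))
  sel <- features$div %in% window & !is.na(features[[feature]])
  if (!any(sel)) stop("no data for feature '", feature, "' in window DIV ",
                      min(window), "-", max(window))
  f <- features[sel, , drop = FALSE]
  if (reducer == "mean") {
    v <- tapply(f[[feature]], f$well, mean)
    list(values = as.numeric(v), well = names(v))
  } else {
    list(values = f[[feature]], well = f$well)
  }
}

#' Pooled-window permutation test on well labels
#'
#' The two-group comparison of one activity feature over a DIV window
#' (default DIV8-DIV16): each well's values over the window are reduced to
#' one observation (default: the mean over available days), a two-sided
#' Mann-Whitney U test compares the two well sets, and the condition labels
#' of the wells are then permuted \code{nPerm} times (group sizes preserved)
#' to build the null distribution of the MWU p-value. The empirical p-value
#' is \code{(1 + #\{p_perm <= p_obs\}) / (nPerm + 1)} — ties count
#' inclusively, and a zero-exceedance result reports the attainable minimum
#' \code{1/(nPerm + 1)} (i.e. p < 0.0001 at 10,000 permutations).
#'
#' With \code{reducer = "concat"} every well-day value in the window enters
#' the MWU as its own observation, but labels are still permuted at the well
#' level, preserving the exchangeability unit.
#'
#' @param features feature table (\code{\link{computeWellFeatures}} rows).
#' @param groups group assignment (\code{well}, \code{condition}) with
#'   exactly two conditions; defaults to the table's own \code{condition}
#'   column.
#' @param feature feature column name.
#' @param window integer DIVs to pool (default \code{8:16}).
#' @param nPerm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param reducer \code{"mean"} or \code{"concat"}.
#' @return list with \code{observed_mwu_p}, \code{U}, \code{perm_p},
#'   \code{n_perm}, \code{n_per_group} (named), \code{seed},
#'   \code{reducer}.
#' @export
permutationTest <- function(features, groups = NULL, feature,
                            window = 8:16, nPerm = 10000L, seed = NULL,
                            reducer = c("mean", "concat")) {
  reducer <- match.arg(reducer)
  if (is.null(groups))
    groups <- unique(features[!is.na(features$condition),
                              c("well", "condition")])
  conds <- sort(unique(groups$condition))
  if (length(conds) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(conds, collapse = ", "))
  wv <- .window_values(features, feature, window, reducer)
  keep <- wv$well %in% groups$well
  vals <- wv$values[keep]
  obswell <- wv$well[keep]
  wells <- unique(obswell)
  lab <- groups$condition[match(wells, groups$well)]
  n_g <- table(factor(lab, levels = conds))
  if (any(n_g < 2L))
    stop("fewer than two wells per group after QC: ",
         paste(names(n_g), n_g, collapse = ", "))

  N <- length(vals)
  r <- rank(vals)
  tt <- table(vals)
  tiecorr <- sum(tt^3 - tt)
  # per-well rank sums and observation counts: a permutation's rank sum is a
  # sum over its group-1 wells
  s_w <- as.numeric(tapply(r, factor(obswell, levels = wells), sum))
  c_w <- as.numeric(tapply(rep(1, N), factor(obswell, levels = wells), sum))

  is_g1 <- lab == conds[1L]
  obs_R1 <- sum(s_w[is_g1])
  obs_n1 <- sum(c_w[is_g1])
  observed_p <- .mwu_p_approx(obs_R1, obs_n1, N - obs_n1, tiecorr, N)
  obs_U <- obs_R1 - obs_n1 * (obs_n1 + 1) / 2

  if (!is.null(seed)) set.seed(seed)
  k <- sum(is_g1)
  perm_p_vals <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(length(wells), k)
    R1 <- sum(s_w[idx]); n1 <- sum(c_w[idx])
    .mwu_p_approx(R1, n1, N - n1, tiecorr, N)
  }, numeric(1))
  perm_p <- (1 + sum(perm_p_vals <= observed_p)) / (nPerm + 1)

  list(observed_mwu_p = observed_p, U = obs_U, perm_p = perm_p,
       n_perm = as.integer(nPerm),
       n_per_group = stats::setNames(as.integer(n_g), conds),
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
       reducer = reducer)
}

#' Per-DIV Mann-Whitney series with Fisher combination
#'
#' Runs a two-sided MWU test on the well-level values of one feature for each
#' DIV of the window separately, then combines the per-DIV p-values by
#' Fisher's method. Days with fewer than two non-missing wells per group are
#' skipped and reported.
#'
#' @inheritParams permutationTest
#' @return list with \code{per_div_p} (named numeric), \code{skipped_divs},
#'   \code{fisher_chi2}, \code{fisher_df}, \code{fisher_p}.
#' @export
perDivSeries <- function(features, groups = NULL, feature, window = 8:16) {
  if (is.null(groups))
    groups <- unique(features[!is.na(features$condition),
                              c("well", "condition")])
  conds <- sort(unique(groups$condition))
  stopifnot(length(conds) == 2L)
  per_div <- numeric(0)
  skipped <- integer(0)
  for (d in sort(unique(window))) {
    f <- features[features$div == d & !is.na(features[[feature]]), ,
                  drop = FALSE]
    cond <- groups$condition[match(f$well, groups$well)]
    a <- f[[feature]][cond == conds[1L] & !is.na(cond)]
    b <- f[[feature]][cond == conds[2L] & !is.na(cond)]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <- c(skipped, d)
      next
    }
    per_div[as.character(d)] <- mwuTest(a, b)$p
  }
  if (!length(per_div))
    stop("no eligible days in window for feature '", feature, "'")
  fc <- fisherCombine(per_div)
  list(per_div_p = per_div, skipped_divs = skipped,
       fisher_chi2 = fc$chi2, fisher_df = fc$df, fisher_p = fc$p)
}

#' Full two-tier comparison of one feature
#'
#' Combines \code{\link{perDivSeries}} (per-DIV MWU + Fisher combination) and
#' \code{\link{permutationTest}} (pooled-window MWU calibrated by label
#' permutation) into one \linkS4class{GroupComparison}.
#'
#' @inheritParams permutationTest
#' @return A \linkS4class{GroupComparison}.
#' @export
compareFeature <- function(features, groups = NULL, feature, window = 8:16,
                           nPerm = 10000L, seed = NULL,
                           reducer = c("mean", "concat")) {
  reducer <- match.arg(reducer)
  pd <- perDivSeries(features, groups, feature, window)
  pt <- permutationTest(features, groups, feature, window, nPerm, seed,
                        reducer)
  new("GroupComparison",
      feature = feature, window = as.integer(window),
      perDivP = pd$per_div_p, fisherChi2 = pd$fisher_chi2,
      fisherDf = as.integer(pd$fisher_df), fisherP = pd$fisher_p,
      observedMwuP = pt$observed_mwu_p, permP = pt$perm_p,
      nPerm = pt$n_perm, nPerGroup = pt$n_per_group,
      seed = pt$seed, reducer = reducer)
}

#' Tidy data.frame of GroupComparison results
#'
#' @param x a list of \linkS4class{GroupComparison} objects (or a single
#'   one).
#' @return One row per feature with the Fisher and permutation results.
#' @export
comparisonTable <- function(x) {
  if (is(x, "GroupComparison")) x <- list(x)
  do.call(rbind, lapply(x, function(g)
    data.frame(feature = g@feature,
               window_start = min(g@window), window_end = max(g@window),
               n_divs = length(g@perDivP),
               fisher_chi2 = g@fisherChi2, fisher_df = g@fisherDf,
               fisher_p = g@fisherP, observed_mwu_p = g@observedMwuP,
               perm_p = g@permP, n_perm = g@nPerm,
               n_group1 = g@nPerGroup[[1L]], n_group2 = g@nPerGroup[[2L]],
               seed = g@seed, reducer = g@reducer,
               stringsAsFactors = FALSE)))
}
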