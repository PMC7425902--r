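#' Pooled kernel bandwidth for RT densities
#'
#' The Gaussian kernel SD is set equal to the standard deviation of the RT
#' data collapsed across all conditions, so every condition of a
#' participant is smoothed identically — a requirement for the crossing
#' points of smoothed mixtures to coincide (convolution with a common
#' kernel preserves the fixed-point property exactly).
#'
#' @param rts Numeric vector of RTs pooled over conditions (>= 2 values).
#' @return Bandwidth in ms.
#' @export
pooled_bandwidth <- function(rts) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < 2) stop("need at least 2 RTs", call. = FALSE)
  s <- stats::sd(rts)
  if (s == 0) stop("constant RT sample: bandwidth undefined", call. = FALSE)
  s
}

#' Common evaluation grid for a set of RT samples
#'
#' 512 equally spaced points spanning the pooled range extended by three
#' bandwidths on each side.
#'
#' @param rts Pooled RTs.
#' @param bandwidth Kernel SD (ms).
#' @param n Grid size (default 512).
#' @return Strictly increasing numeric vector.
#' @export
density_grid <- function(rts, bandwidth, n = 512) {
  seq(min(rts) - 3 * bandwidth, max(rts) + 3 * bandwidth, length.out = n)
}

#' Gaussian kernel density estimate on a fixed grid
#'
#' Plain kernel sum: `f(g) = mean(dnorm(g, rts, bandwidth))`, evaluated at
#' every grid point. No binning or FFT approximation, so the estimate at a
#' point is exactly the average kernel contribution of the sample.
#'
#' @param rts RT sample (>= 5 values).
#' @param bandwidth Kernel SD (ms), > 0.
#' @param grid Evaluation grid (strictly increasing).
#' @return Object of class `density_estimate`: list with `grid`, `density`,
#'   `bandwidth`, `n`.
#' @export
estimate_density <- function(rts, bandwidth, grid) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < 5)
    stop("need at least 5 RTs for a density estimate (got ",
         length(rts), ")", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = rts, sd = bandwidth)), numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 n = length(rts), median = stats::median(rts),
                 range = range(rts)),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> n = %d, bandwidth = %.1f ms, grid [%.0f, %.0f]\n",
              x$n, x$bandwidth, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Crossing point of two density estimates
#'
#' Locates sign changes of `d1 - d2` on the common grid, refines each by
#' linear interpolation, and — when kernel noise produces several candidate
#' crossings — selects the one at which the integrated density difference
#' (the CDF difference `D(x) = F1(x) - F2(x)`) is largest in magnitude.
#' For two mixtures of common base distributions `D` is extremal exactly at
#' the base-density intersection, whatever the mixture proportions, so this
#' selector targets the structural crossing; because `D` integrates the
#' noisy density difference it is far more stable than any pointwise
#' criterion, and it uses only the pair's own data (no information about
#' the other pairs leaks in, which would bias the downstream test toward a
#' common crossing). Candidates outside the overlap of the two samples'
#' observed RT ranges are discarded.
#'
#' @param d1,d2 `density_estimate` objects on the same grid.
#' @return List with `crossing` (RT in ms, or `NA`), `reason` (`NA` on
#'   success, otherwise why the crossing is missing), `n_candidates`.
#' @export
crossing_point <- function(d1, d2) {
  if (!isTRUE(all.equal(d1$grid, d2$grid)))
    stop("density estimates must share a grid", call. = FALSE)
  g <- d1$grid
  diffd <- d1$density - d2$density
  s <- sign(diffd)
  idx <- which(s[-1] * s[-length(s)] < 0)
  # exact zeros on the grid count as crossings
  idx <- sort(unique(c(idx, which(s == 0))))
  if (!length(idx))
    return(list(crossing = NA_real_, reason = "no crossing", n_candidates = 0L))
  cross <- vapply(idx, function(i) {
    if (s[i] == 0) return(g[i])
    g[i] + (g[i + 1] - g[i]) * diffd[i] / (diffd[i] - diffd[i + 1])
  }, numeric(1))
  # trapezoid CDF difference, evaluated at each candidate
  D <- c(0, cumsum((diffd[-1] + diffd[-length(diffd)]) / 2 * diff(g)))
  D_at <- vapply(cross, function(x) {
    i <- findInterval(x, g, all.inside = TRUE)
    w <- (x - g[i]) / (g[i + 1] - g[i])
    (1 - w) * D[i] + w * D[i + 1]
  }, numeric(1))
  in_overlap <- cross >= max(d1$range[1], d2$range[1]) &
    cross <= min(d1$range[2], d2$range[2])
  if (!any(in_overlap))
    return(list(crossing = NA_real_, reason = "no crossing in overlap",
                n_candidates = length(cross)))
  pick <- which(in_overlap)[which.max(abs(D_at[in_overlap]))]
  list(crossing = cross[pick], reason = NA_character_,
       n_candidates = length(cross))
}

#' Per-participant pairwise crossing points across conditions
#'
#' Step 1 and 2 of the fixed-point analysis: for each participant, a
#' Gaussian KDE of the RT distribution of each condition (bandwidth = the
#' participant's pooled RT standard deviation, one common grid), then the
#' crossing point of every condition pair. Participants with fewer than
#' `min_n` RTs in any condition are excluded with a logged reason.
#'
#' @param trials A trial table.
#' @param factor `"TP"` or `"ToT"`: which manipulation defines the
#'   conditions (levels -1/0/+1 of `tp_code` / `tot_code`).
#' @param min_n Minimum RTs per condition per participant (default 5).
#' @return Object of class `crossing_set`: data frame `crossings` (subject,
#'   pair, crossing, reason), character vector `excluded` (subject:
#'   reason), the factor, and `n_participants` actually used.
#' @export
crossing_set <- function(trials, factor = c("TP", "ToT"), min_n = 5) {
  factor <- match.arg(factor)
  code <- if (factor == "TP") "tp_code" else "tot_code"
  d <- trials[trials$session == "experimental" & !is.na(trials[[code]]) &
                is.finite(trials$rt_ms), ]
  levels <- sort(unique(d[[code]]))
  if (length(levels) < 2)
    stop("need at least 2 ", factor, " levels with RTs", call. = FALSE)
  pairs <- utils::combn(levels, 2)
  rows <- list()
  excluded <- character(0)
  for (s in unique(d$subject)) {
    ds <- d[d$subject == s, ]
    ns <- table(factor(ds[[code]], levels = levels))
    if (any(ns < min_n)) {
      excluded <- c(excluded, sprintf(
        "subject %s: fewer than %d RTs in condition %s",
        s, min_n, names(ns)[which.min(ns)]))
      next
    }
    bw <- pooled_bandwidth(ds$rt_ms)
    grid <- density_grid(ds$rt_ms, bw)
    dens <- lapply(levels, function(l)
      estimate_density(ds$rt_ms[ds[[code]] == l], bw, grid))
    names(dens) <- as.character(levels)
    for (j in seq_len(ncol(pairs))) {
      l1 <- as.character(pairs[1, j]); l2 <- as.character(pairs[2, j])
      cp <- crossing_point(dens[[l1]], dens[[l2]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, pair = paste(l1, l2, sep = ":"),
        crossing = cp$crossing, reason = cp$reason)
    }
  }
  if (!length(rows)) stop("no participant met the inclusion criteria",
                          call. = FALSE)
  cr <- do.call(rbind, rows)
  structure(list(crossings = cr, excluded = excluded, factor = factor,
                 n_pairs = ncol(pairs),
                 n_participants = length(unique(cr$subject))),
            class = "crossing_set")
}

#' @export
print.crossing_set <- function(x, ...) {
  cat(sprintf("<crossing_set> factor %s: %d participants x %d pairs (%d excluded)\n",
              x$factor, x$n_participants, x$n_pairs, length(x$excluded)))
  invisible(x)
}

#' Bayes-factor test for a common crossing point
#'
#' Step 3 of the fixed-point analysis: a one-way repeated-measures ANOVA of
#' the crossing RTs on the condition pair (participant as a blocking
#' factor), summarized by the BIC approximation to the Bayes factor,
#' `BF01 = exp((BIC_effect - BIC_null) / 2)`. `BF01 > 1` favors a single
#' crossing population — the fixed-point property, hence a binary-mixture
#' (dual-process) account; `BF01 < 1` favors pair-dependent crossings.
#' Participants with any missing crossing are excluded (logged).
#'
#' @param cs A `crossing_set`.
#' @return Object of class `fixedpoint_result`: `BF01`, `BF10`, per-pair
#'   crossing means and SEs, `n_participants`, `excluded`, and the two
#'   models' BICs.
#' @export
fixed_point_bayes_test <- function(cs) {
  stopifnot(inherits(cs, "crossing_set"))
  cr <- cs$crossings
  complete <- tapply(is.na(cr$crossing), cr$subject, sum) == 0
  keep <- names(complete)[complete]
  dropped <- setdiff(unique(cr$subject), keep)
  if (length(keep) < 2)
    stop("fewer than 2 participants with complete crossing sets", call. = FALSE)
  cr <- cr[cr$subject %in% keep, ]
  d <- data.frame(crossing = cr$crossing,
                  pair = factor(cr$pair),
                  subject = factor(cr$subject))
  null_fit <- stats::lm(crossing ~ subject, data = d)
  eff_fit <- stats::lm(crossing ~ subject + pair, data = d)
  bic_null <- stats::BIC(null_fit)
  bic_eff <- stats::BIC(eff_fit)
  bf01 <- exp((bic_eff - bic_null) / 2)
  means <- tapply(d$crossing, d$pair, mean)
  ses <- tapply(d$crossing, d$pair, function(x) stats::sd(x) / sqrt(length(x)))
  structure(list(BF01 = bf01, BF10 = 1 / bf01,
                 pair_means = means, pair_ses = ses,
                 n_participants = length(keep),
                 excluded = c(cs$excluded,
                              if (length(dropped))
                                paste0("subject ", dropped,
                                       ": incomplete crossing set")),
                 bic_null = bic_null, bic_effect = bic_eff,
                 factor = cs$factor),
            class = "fixedpoint_result")
}

#' @export
print.fixedpoint_result <- function(x, ...) {
  cat(sprintf("<fixedpoint_result> factor %s: BF01 = %.3g (%s), n = %d\n",
              x$factor, x$BF01,
              if (x$BF01 > 1) "common crossing favored"
              else "pair-dependent crossings favored",
              x$n_participants))
  invisible(x)
}

#' Run the full fixed-point test on a trial table
#'
#' Convenience wrapper: crossing extraction followed by the Bayes-factor
#' test.
#'
#' @inheritParams crossing_set
#' @return A `fixedpoint_result`.
#' @export
fixed_point_test <- function(trials, factor = c("TP", "ToT"), min_n = 5) {
  fixed_point_bayes_test(crossing_set(trials, factor, min_n))
}
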