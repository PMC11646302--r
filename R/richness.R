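#' Read-based rarefaction of a single sample
#'
#' Draws reads without replacement (multivariate hypergeometric) at depths
#' spaced in increments of `step_fraction` of the total read count and
#' records the mean and standard deviation of observed OTU richness over
#' `iterations` random draws per depth. Each iteration reuses one random
#' permutation of the reads for all depths, which yields the exact
#' without-replacement distribution at every depth.
#'
#' @param counts per-OTU read counts of the sample (named or not).
#' @param step_fraction depth increment as a fraction of the total, default
#'   0.001 (0.1%).
#' @param iterations random draws per depth, default 50.
#' @param seed optional integer seed.
#' @return a `richness_curve` data.frame with columns `effort`, `mean`, `sd`,
#'   `n_iter`. The final level is the full depth, where the mean equals
#'   observed richness exactly and the sd is zero.
#' @export
rarefy_reads <- function(counts, step_fraction = 0.001, iterations = 50,
                         seed = NULL) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 0), sum(counts) >= 1, step_fraction > 0,
            step_fraction <= 1, iterations >= 1)
  N <- sum(counts)
  depths <- unique(pmin(N, floor(N * seq(step_fraction, 1, by = step_fraction))))
  depths <- depths[depths >= 1L]          # levels yielding <1 read are skipped
  if (!N %in% depths) depths <- c(depths, N)
  reads <- rep.int(seq_along(counts), counts)
  rich <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      perm <- reads[sample.int(N)]
      first <- which(!duplicated(perm))    # ascending first-occurrence positions
      findInterval(depths, first)
    }, numeric(length(depths)))
  })
  rich <- matrix(rich, nrow = length(depths))
  out <- data.frame(effort = depths,
                    mean = rowMeans(rich),
                    sd = apply(rich, 1L, stats::sd),
                    n_iter = iterations)
  out$sd[is.na(out$sd)] <- 0
  attr(out, "seed") <- seed
  class(out) <- c("richness_curve", "data.frame")
  out
}

#' Exact expected rarefied richness
#'
#' Closed-form expectation of the number of distinct OTUs seen when drawing
#' `depth` reads without replacement:
#' \eqn{E[S] = \sum_i (1 - C(N - n_i, d)/C(N, d))}.
#'
#' @param counts per-OTU read counts.
#' @param depth number of reads drawn (vectorised).
#' @return numeric vector of expectations.
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  vapply(depth, function(d) {
    stopifnot(d >= 0, d <= N)
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, numeric(1))
}

#' Fit a Michaelis-Menten saturation curve to a rarefaction curve
#'
#' Unweighted least squares of \eqn{R(d) = R_{max} d / (K + d)} against the
#' mean richness track. Initialisation: \eqn{R_{max,0}} = 1.05 x maximum
#' observed richness, \eqn{K_0} = the effort at which the curve first reaches
#' half of \eqn{R_{max,0}}.
#'
#' @param curve a [rarefy_reads()] result or data.frame with `effort` and
#'   `mean` columns (>= 3 distinct effort levels).
#' @return an `mm_fit` list with `Rmax`, `K`, `resid_norm`.
#' @export
fit_mm <- function(curve) {
  d <- curve$effort; r <- curve$mean
  if (length(unique(d)) < 3L) stop("need >= 3 distinct effort levels")
  Rmax0 <- 1.05 * max(r)
  K0 <- d[which(r >= Rmax0 / 2)[1]]
  if (is.na(K0)) K0 <- max(d)
  K0 <- max(K0, min(d[d > 0]) / 10)
  fit <- tryCatch(
    stats::nls(r ~ Rmax * d / (K + d),
               start = list(Rmax = Rmax0, K = K0),
               algorithm = "port", lower = c(Rmax = 1e-9, K = 1e-9),
               control = stats::nls.control(maxiter = 10000, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out <- list(Rmax = unname(cf["Rmax"]), K = unname(cf["K"]),
                resid_norm = sqrt(sum(stats::resid(fit)^2)))
  } else {
    # profile fallback for near-saturated curves where nls stalls: for fixed
    # K the optimal Rmax is closed-form, so optimise over log K only
    rmax_given <- function(K) {
      w <- d / (K + d)
      sum(w * r) / sum(w * w)
    }
    sse <- function(logK) {
      K <- exp(logK)
      sum((r - rmax_given(K) * d / (K + d))^2)
    }
    lo <- log(min(d[d > 0])) - 25; hi <- log(max(d)) + 12
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
    K <- exp(opt$minimum)
    out <- list(Rmax = rmax_given(K), K = K, resid_norm = sqrt(opt$objective))
    if (!is.finite(out$Rmax) || !is.finite(out$K) || out$Rmax <= 0)
      stop("Michaelis-Menten fit did not converge (last iterate Rmax=",
           signif(out$Rmax, 6), ", K=", signif(out$K, 6), ")", call. = FALSE)
  }
  structure(out, class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("mm_fit: Rmax = %.4g, K = %.4g, residual norm = %.3g\n",
              x$Rmax, x$K, x$resid_norm))
  invisible(x)
}

#' Predicted richness from a Michaelis-Menten fit
#' @param object an `mm_fit`.
#' @param effort sequencing depths at which to evaluate the curve.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.mm_fit <- function(object, effort, ...) {
  object$Rmax * effort / (object$K + effort)
}

#' Relative richness gain from doubling sequencing depth
#'
#' Under the fitted curve, \eqn{R(2D)/R(D) - 1 = K/(K + 2D)}. Sequencing
#' depth is deemed sufficient when the gain is below 5%.
#'
#' @param fit an `mm_fit`.
#' @param total_depth the sample's achieved depth D (> 0).
#' @param threshold sufficiency cutoff on the gain, default 0.05 (strict `<`).
#' @return list with `gain` (fraction) and `sufficient` (logical).
#' @export
doubling_gain <- function(fit, total_depth, threshold = 0.05) {
  stopifnot(total_depth > 0)
  gain <- fit$K / (fit$K + 2 * total_depth)
  list(gain = gain, sufficient = gain < threshold)
}

#' Build a species-by-sampling-unit incidence matrix
#'
#' @param counts species/OTU x unit count (or logical) matrix, or a
#'   `species_table` / `otu_table`.
#' @return logical matrix of class `incidence_matrix` with attribute `T` (the
#'   number of sampling units).
#' @export
incidence_matrix <- function(counts) {
  if (inherits(counts, "species_table")) counts <- counts$counts
  if (inherits(counts, "otu_table")) counts <- counts$counts
  m <- as.matrix(counts) > 0
  if (ncol(m) < 1L) stop("need at least one sampling unit")
  structure(m, class = c("incidence_matrix", class(m)), T = ncol(m))
}

incidence_freqs <- function(inc) {
  ni <- rowSums(inc)
  list(S_obs = sum(ni > 0),
       Q = vapply(1:4, function(k) sum(ni == k), numeric(1)),
       T = ncol(inc))
}

#' Chao2 and iChao2 incidence-based richness estimates
#'
#' Classic nonparametric lower bounds from incidence frequency counts.
#' With \eqn{Q_k} = number of species found in exactly k sampling units and T
#' units in total:
#' \deqn{Chao2 = S_{obs} + \frac{T-1}{T}\frac{Q_1^2}{2 Q_2}}
#' (bias-corrected form \eqn{S_{obs} + \frac{T-1}{T} Q_1(Q_1-1)/2} when
#' \eqn{Q_2 = 0}), and the improved estimator adds the Q3/Q4 term
#' \deqn{iChao2 = Chao2 + \frac{T-3}{4T}\frac{Q_3}{Q_4}
#'   \max\!\left(Q_1 - \frac{T-3}{2(T-1)}\frac{Q_2 Q_3}{Q_4},\, 0\right)}
#' with \eqn{Q_4} replaced by 1 when zero (continuity correction).
#'
#' @param inc an [incidence_matrix()] (or logical matrix).
#' @param q2_correction,q4_correction apply the standard corner-case
#'   corrections (defaults `TRUE`); with `q4_correction = FALSE` the added
#'   term is zero when `Q4 == 0`.
#' @return list of class `ichao2_estimate`: `S_obs`, `Q1`..`Q4`, `T`,
#'   `chao2`, `ichao2` (`NA` when `T < 4`).
#' @export
ichao2 <- function(inc, q2_correction = TRUE, q4_correction = TRUE) {
  f <- incidence_freqs(inc)
  S <- f$S_obs; Q1 <- f$Q[1]; Q2 <- f$Q[2]; Q3 <- f$Q[3]; Q4 <- f$Q[4]
  T <- f$T
  A <- (T - 1) / T
  chao2 <- if (Q2 > 0) S + A * Q1^2 / (2 * Q2)
           else if (q2_correction) S + A * Q1 * (Q1 - 1) / 2
           else S
  ich <- NA_real_
  if (T >= 4) {
    Q4c <- if (Q4 > 0) Q4 else if (q4_correction) 1 else NA
    add <- if (Q3 == 0 || is.na(Q4c)) 0 else
      (T - 3) / (4 * T) * (Q3 / Q4c) *
      max(Q1 - (T - 3) / (2 * (T - 1)) * Q2 * Q3 / Q4c, 0)
    ich <- chao2 + add
  }
  structure(list(S_obs = S, Q1 = Q1, Q2 = Q2, Q3 = Q3, Q4 = Q4, T = T,
                 chao2 = chao2, ichao2 = ich),
            class = "ichao2_estimate")
}

#' @export
print.ichao2_estimate <- function(x, ...) {
  cat(sprintf("iChao2: S_obs = %d, T = %d, Q1-4 = (%g, %g, %g, %g), chao2 = %.2f, ichao2 = %s\n",
              x$S_obs, x$T, x$Q1, x$Q2, x$Q3, x$Q4, x$chao2,
              ifelse(is.na(x$ichao2), "unavailable (T < 4)",
                     sprintf("%.2f", x$ichao2))))
  invisible(x)
}

#' Sample-based rarefaction with an incidence richness estimator
#'
#' Draws random subsets of sampling units without replacement at sizes
#' `step`, `2*step`, ... and records mean/sd observed richness per size plus,
#' optionally, the mean iChao2 estimate over the same draws (falling back to
#' Chao2 for subset sizes below 4 units).
#'
#' @param inc an [incidence_matrix()].
#' @param step subset-size increment, default 5.
#' @param iterations draws per size, default 50.
#' @param seed optional integer seed.
#' @param estimator `"ichao2"` (default) or `"none"`.
#' @return data.frame of class `richness_curve` with columns `effort`,
#'   `mean`, `sd`, `n_iter` and, when the estimator is enabled, `mean_est`,
#'   `sd_est`.
#' @export
rarefy_samples <- function(inc, step = 5, iterations = 50, seed = NULL,
                           estimator = c("ichao2", "none")) {
  estimator <- match.arg(estimator)
  T <- ncol(inc)
  stopifnot(step >= 1, step <= T)
  sizes <- unique(c(seq(step, T, by = step), T))
  res <- with_seed(seed, {
    lapply(sizes, function(k) {
      draws <- vapply(seq_len(iterations), function(it) {
        u <- sample.int(T, k)
        sub <- inc[, u, drop = FALSE]
        s_obs <- sum(rowSums(sub) > 0)
        est <- NA_real_
        if (estimator == "ichao2") {
          e <- ichao2(sub)
          est <- if (is.na(e$ichao2)) e$chao2 else e$ichao2
        }
        c(s_obs, est)
      }, numeric(2))
      c(mean(draws[1, ]), stats::sd(draws[1, ]),
        mean(draws[2, ]), stats::sd(draws[2, ]))
    })
  })
  res <- do.call(rbind, res)
  out <- data.frame(effort = sizes, mean = res[, 1],
                    sd = ifelse(is.na(res[, 2]), 0, res[, 2]),
                    n_iter = iterations)
  if (estimator == "ichao2") {
    out$mean_est <- res[, 3]
    out$sd_est <- ifelse(is.na(res[, 4]), 0, res[, 4])
  }
  attr(out, "seed") <- seed
  class(out) <- c("richness_curve", "data.frame")
  out
}
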