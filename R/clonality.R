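#' Fit the limit-of-detection / linear count-calibration model
#'
#' Pooled deep sequencing overestimates the copy number of recurrent
#' mutations, and copy numbers below a limit of detection (LOD) cannot be
#' quantified at all. Given calibration mixtures with known copy numbers, this
#' fits a piecewise model: observed counts at or below the LOD collapse to a
#' single copy; above it, observed and expected counts are related linearly.
#' The LOD is found by scanning candidate values over `[0, max(expected)]`
#' with a decreasing-step (step-halving) search using a fixed budget of
#' objective evaluations. Each candidate `L` defines a changepoint: points
#' with `expected > L` get an ordinary least-squares fit
#' `observed ~ expected`; points at or below `L` — the unquantifiable regime —
#' are fit flat (their mean). The candidate minimising the total squared error
#' wins; ties go to the smallest LOD, and the fitted LOD is reported as the
#' integer count it implies. Note the fit's flat segment estimates where
#' quantification breaks down, while the *application* of the model
#' ([adjust_count()]) collapses at-or-below-LOD counts to a single copy.
#'
#' @param points Data frame of calibration points with columns `expected`
#'   (known copies in a constructed mixture) and `observed` (pipeline raw
#'   count). At least 4 points.
#' @param n_eval Total objective-evaluation budget for the scan (default
#'   1000).
#' @return A `clonality_model`: list with `lod` (integer), `slope`,
#'   `intercept`, `sse`, `lack_of_fit_p` (linearity check on above-LOD
#'   points; informational), `n_points`.
#' @seealso [adjust_count()], [clonality()]
#' @export
fit_lod_linear <- function(points, n_eval = 1000) {
  assert_event_cols(points, c("expected", "observed"))
  points <- as_tibble(points)
  if (nrow(points) < 4) stop("need >= 4 calibration points", call. = FALSE)
  expected <- as.numeric(points$expected)
  observed <- as.numeric(points$observed)

  objective <- function(L) {
    above <- expected > L
    if (sum(above) < 2 || length(unique(expected[above])) < 2) return(Inf)
    fit <- stats::lm.fit(cbind(1, expected[above]), observed[above])
    sse_above <- sum(fit$residuals^2)
    below <- observed[!above]
    sse_below <- if (length(below) > 0) sum((below - mean(below))^2) else 0
    sse_above + sse_below
  }

  max_exp <- max(expected)
  # coarse grid, then step-halving refinement around the incumbent
  grid <- seq(0, max_exp, length.out = 21)
  vals <- vapply(grid, objective, numeric(1))
  used <- length(grid)
  best_sse <- min(vals)
  best_L <- min(grid[vals <= best_sse + 1e-12])
  step <- (max_exp) / 2
  while (used + 2 <= n_eval && step > .Machine$double.eps * max(1, max_exp)) {
    cand <- c(best_L - step, best_L + step)
    cand <- cand[cand >= 0 & cand <= max_exp]
    if (length(cand) > 0) {
      cv <- vapply(cand, objective, numeric(1))
      used <- used + length(cand)
      all_L <- c(best_L, cand); all_v <- c(best_sse, cv)
      best_sse <- min(all_v)
      best_L <- min(all_L[all_v <= best_sse + 1e-12])
    }
    step <- step / 2
  }
  if (!is.finite(best_sse)) {
    stop("degenerate calibration: all points at or below every candidate LOD",
         call. = FALSE)
  }
  above <- expected > best_L
  fit <- stats::lm(observed ~ expected,
                   data = tibble(expected = expected[above],
                                 observed = observed[above]))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate calibration: non-positive slope above the LOD",
         call. = FALSE)
  }
  # lack-of-fit vs saturated group means, when expected values replicate
  lof_p <- NA_real_
  ta <- tibble(expected = expected[above], observed = observed[above])
  if (dplyr::n_distinct(ta$expected) < nrow(ta) &&
      dplyr::n_distinct(ta$expected) > 2) {
    full <- stats::lm(observed ~ factor(expected), data = ta)
    lof_p <- stats::anova(fit, full)[2, "Pr(>F)"]
  }
  structure(
    list(lod = as.integer(floor(best_L + 1e-9)), slope = slope,
         intercept = intercept, sse = best_sse, lack_of_fit_p = lof_p,
         n_points = nrow(points)),
    class = "clonality_model"
  )
}

#' Construct a clonality model from known parameters
#'
#' @param lod Limit of detection (copies).
#' @param slope,intercept Linear calibration parameters.
#' @return A `clonality_model`.
#' @export
clonality_model <- function(lod = 4, slope = 1.1363, intercept = 0.3123) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (lod < 0) stop("lod must be >= 0", call. = FALSE)
  structure(list(lod = as.integer(lod), slope = slope, intercept = intercept,
                 sse = NA_real_, lack_of_fit_p = NA_real_, n_points = 0L),
            class = "clonality_model")
}

#' @export
print.clonality_model <- function(x, ...) {
  cat("<clonality_model> LOD ", x$lod, ", observed = ",
      format(x$intercept, digits = 4), " + ", format(x$slope, digits = 4),
      " x expected\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.clonality_model <- function(x, ...) {
  tibble(term = c("lod", "slope", "intercept"),
         estimate = c(x$lod, x$slope, x$intercept))
}

#' @export
#' @importFrom generics glance
glance.clonality_model <- function(x, ...) {
  tibble(lod = x$lod, slope = x$slope, intercept = x$intercept, sse = x$sse,
         lack_of_fit_p = x$lack_of_fit_p, n_points = x$n_points)
}

#' Adjust an observed mutation count for quantification bias
#'
#' Counts at or below the model's LOD collapse to 1 copy; above it the linear
#' calibration is inverted: `(observed - intercept) / slope`, rounded half-up
#' with floor 1.
#'
#' @param observed Observed (raw) count(s), >= 1. Vectorised.
#' @param model A `clonality_model`.
#' @return Integer adjusted count(s).
#' @examples
#' m <- clonality_model()          # LOD 4, slope 1.1363, intercept 0.3123
#' adjust_count(3, m)              # 1
#' adjust_count(50, m)             # 44
#' @export
adjust_count <- function(observed, model) {
  stopifnot(inherits(model, "clonality_model"))
  if (any(observed < 1)) stop("observed counts must be >= 1", call. = FALSE)
  as.integer(ifelse(observed <= model$lod, 1,
                    pmax(1, round_half_up(
                      (observed - model$intercept) / model$slope))))
}

#' Clonality of a sample or group
#'
#' Fraction of mutation copies attributable to clonal expansion:
#' `(total - independent) / total`, 0 when `total` is 0.
#'
#' @param total Total (typically LOD/linear-adjusted) mutation count.
#' @param independent Number of independent mutations. Vectorised.
#' @return Clonality fraction in `[0, 1]`.
#' @export
clonality <- function(total, independent) {
  if (any(independent > total)) {
    stop("independent count exceeds total count", call. = FALSE)
  }
  if (any(independent < 0)) stop("counts must be non-negative", call. = FALSE)
  ifelse(total == 0, 0, (total - independent) / total)
}

#' Clonality-corrected mutation frequency
#'
#' The assay's raw mutant frequency (mutant pfu / total pfu) counts every
#' clonal copy; multiplying by `1 - clonality` counts each independent
#' mutation once, yielding the mutation frequency.
#'
#' @param mutant_pfu,total_pfu Plaque-forming unit counts per animal.
#'   Vectorised.
#' @param clonality_fraction Per-animal clonality in `[0, 1]`.
#' @return Corrected mutation frequency (per pfu).
#' @export
corrected_mutation_frequency <- function(mutant_pfu, total_pfu,
                                         clonality_fraction) {
  if (any(total_pfu <= 0)) stop("total_pfu must be positive", call. = FALSE)
  if (any(clonality_fraction < 0 | clonality_fraction > 1)) {
    stop("clonality must be in [0, 1]", call. = FALSE)
  }
  (mutant_pfu / total_pfu) * (1 - clonality_fraction)
}
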