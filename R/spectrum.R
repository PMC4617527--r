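MUTATION_CLASSES <- c("GC>AT", "GC>TA", "GC>CG", "AT>GC", "AT>TA", "AT>CG",
                      "insertion", "deletion")
TRANSITION_CLASSES <- c("GC>AT", "AT>GC")
TRANSVERSION_CLASSES <- c("GC>TA", "GC>CG", "AT>TA", "AT>CG")

#' Collapsed mutation class of an event
#'
#' The 12 directed base substitutions collapse into six classes over
#' complementary strands (e.g. G>T and C>A are both `GC>TA`); indels map to
#' `insertion` / `deletion`. Substitution classes carry a
#' transition/transversion label.
#'
#' @param ref_base Reference base(s) at the event position.
#' @param kind Event kind(s): `"sub"`, `"ins"`, `"del"`.
#' @param detail Alternative base for substitutions; ignored for indels.
#' @return Character vector of classes (see `MUTATION_CLASSES`). Vectorised.
#' @examples
#' classify_mutation_class("G", "sub", "T")  # "GC>TA"
#' classify_mutation_class("C", "sub", "A")  # "GC>TA"
#' @export
classify_mutation_class <- function(ref_base, kind, detail) {
  n <- max(length(ref_base), length(kind), length(detail))
  ref_base <- rep_len(toupper(ref_base), n)
  kind <- rep_len(kind, n)
  detail <- rep_len(as.character(detail), n)
  out <- character(n)
  out[kind == "ins"] <- "insertion"
  out[kind == "del"] <- "deletion"
  is_sub <- kind == "sub"
  if (any(is_sub)) {
    r <- ref_base[is_sub]; a <- toupper(detail[is_sub])
    if (any(!r %in% DNA_BASES) || any(!a %in% DNA_BASES)) {
      stop("substitution bases must be A/C/G/T", call. = FALSE)
    }
    if (any(r == a)) stop("alternative base equals reference base", call. = FALSE)
    # collapse onto the purine-reference strand: name the pair by the purine
    flip <- r %in% c("C", "T")
    r[flip] <- complement_base(r[flip])
    a[flip] <- complement_base(a[flip])
    pair_from <- ifelse(r == "G", "GC", "AT")
    out[is_sub] <- paste0(pair_from, ">", a, complement_base(a))
  }
  out
}

#' Transition / transversion / indel grouping of a mutation class
#'
#' @param class Mutation class string(s) from [classify_mutation_class()].
#' @return `"transition"`, `"transversion"` or `"indel"`.
#' @export
class_group <- function(class) {
  ifelse(class %in% TRANSITION_CLASSES, "transition",
         ifelse(class %in% TRANSVERSION_CLASSES, "transversion", "indel"))
}

#' Build a mutation spectrum
#'
#' Counts calls per collapsed mutation class. With `independent_only = TRUE`
#' (the convention for spectra) each distinct event per sample contributes 1;
#' otherwise events are weighted by a count column (clonal copies included),
#' the convention for positional mutation-load plots.
#'
#' @param calls Annotated call tibble with a `class` column (see
#'   [annotate_calls()]).
#' @param independent_only Weight each call once (default) or by `count_col`.
#' @param count_col Count column used when `independent_only = FALSE`.
#' @return A `mut_spectrum` tibble: `class`, `count`, `proportion`, with all
#'   eight classes present (zero-filled) and an `n_mutations` attribute.
#' @export
build_spectrum <- function(calls, independent_only = TRUE,
                           count_col = "adjusted_count") {
  assert_event_cols(calls, "class")
  w <- if (independent_only) rep(1L, nrow(calls)) else calls[[count_col]]
  counts <- tibble(class = factor(calls$class, levels = MUTATION_CLASSES),
                   w = as.integer(w)) |>
    group_by(.data$class, .drop = FALSE) |>
    summarise(count = as.integer(sum(.data$w)), .groups = "drop") |>
    mutate(class = as.character(.data$class))
  n <- sum(counts$count)
  counts <- mutate(counts,
                   proportion = if (n > 0) .data$count / n else 0,
                   group = class_group(.data$class))
  structure(counts, n_mutations = n,
            class = c("mut_spectrum", class(counts)))
}

#' Compare two mutation spectra by Pearson chi-squared
#'
#' Pearson's chi-squared test of independence on the class-by-group
#' contingency table built from two spectra's counts. When any expected cell
#' is below 5 the p-value is computed by Monte-Carlo simulation (fixed seed,
#' `B` draws) instead of the asymptotic reference distribution; the statistic
#' and degrees of freedom are always the Pearson ones.
#'
#' @param spectrum_a,spectrum_b `mut_spectrum` objects (counts required).
#' @param B Monte-Carlo draws (default 1e5).
#' @param mc_seed Seed for the Monte-Carlo p-value.
#' @return Tibble: `chi2`, `df`, `p`, `monte_carlo`.
#' @export
compare_spectra <- function(spectrum_a, spectrum_b, B = 1e5, mc_seed = 20151019) {
  ca <- spectrum_a$count; cb <- spectrum_b$count
  if (sum(ca) == 0 || sum(cb) == 0) {
    stop("cannot compare an empty spectrum", call. = FALSE)
  }
  keep <- ca + cb > 0
  tab <- rbind(ca[keep], cb[keep])
  asym <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  mc <- any(asym$expected < 5)
  p <- if (mc) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(mc_seed)
    stats::chisq.test(tab, simulate.p.value = TRUE, B = B)$p.value
  } else {
    asym$p.value
  }
  tibble(chi2 = unname(asym$statistic), df = unname(asym$parameter), p = p,
         monte_carlo = mc)
}

#' Per-class spectrum differences with multiplicity correction
#'
#' For each mutation class, a 2x2 chi-squared test (class vs all other
#' classes, group A vs group B), with p-values adjusted across the eight
#' classes (Holm by default). The correction method is configurable because
#' no single convention dominates for reporter-gene spectra.
#'
#' @inheritParams compare_spectra
#' @param method Multiple-testing correction passed to [stats::p.adjust()].
#' @return Tibble per class: counts, proportions, `chi2`, `p`, `p_adj`.
#' @export
compare_spectra_by_class <- function(spectrum_a, spectrum_b, method = "holm",
                                     B = 1e5, mc_seed = 20151019) {
  na <- sum(spectrum_a$count); nb <- sum(spectrum_b$count)
  res <- purrr::map(seq_len(nrow(spectrum_a)), function(i) {
    tab <- rbind(c(spectrum_a$count[i], na - spectrum_a$count[i]),
                 c(spectrum_b$count[i], nb - spectrum_b$count[i]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble(chi2 = NA_real_, p = NA_real_))
    }
    t0 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p <- if (any(t0$expected < 5)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(mc_seed)
      stats::chisq.test(tab, simulate.p.value = TRUE, B = B)$p.value
    } else t0$p.value
    tibble(chi2 = unname(t0$statistic), p = p)
  }) |> list_rbind()
  tibble(class = spectrum_a$class,
         count_a = spectrum_a$count, count_b = spectrum_b$count,
         prop_a = spectrum_a$proportion, prop_b = spectrum_b$proportion,
         chi2 = res$chi2, p = res$p,
         p_adj = stats::p.adjust(res$p, method = method))
}

#' Compare group mutant frequencies by Poisson regression
#'
#' Log-linear Poisson model of per-animal mutant plaque counts with
#' `log(total pfu)` offset and a group indicator; the exponentiated group
#' coefficient is the mutant-frequency rate ratio. If either group has no
#' mutant plaques at all, an exact rate-ratio test on the pooled counts
#' ([stats::poisson.test()]) is used instead and flagged.
#'
#' @param pools Data frame with columns `group` (two levels; the first level
#'   of `factor(group)` is the reference), `mutant_pfu`, `total_pfu`.
#' @return Tibble: `rate_ratio`, `p`, `conf_low`, `conf_high`, `method`,
#'   `flag` (non-empty for single-animal groups or the exact-test fallback).
#' @export
compare_mutant_frequency <- function(pools) {
  assert_event_cols(pools, c("group", "mutant_pfu", "total_pfu"))
  if (any(pools$total_pfu <= 0)) stop("total_pfu must be positive", call. = FALSE)
  g <- factor(pools$group)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  flag <- if (any(table(g) < 2)) "single-animal group: CI unstable" else ""
  zero_group <- tapply(pools$mutant_pfu, g, sum) == 0
  if (any(zero_group)) {
    tot <- tapply(pools$total_pfu, g, sum)
    mut <- tapply(pools$mutant_pfu, g, sum)
    et <- stats::poisson.test(c(mut[2], mut[1]), c(tot[2], tot[1]))
    return(tibble(rate_ratio = unname(et$estimate), p = et$p.value,
                  conf_low = et$conf.int[1], conf_high = et$conf.int[2],
                  method = "exact", flag = "all-zero group: exact test fallback"))
  }
  fit <- stats::glm(mutant_pfu ~ g + offset(log(total_pfu)),
                    family = stats::poisson(), data = pools)
  sm <- summary(fit)$coefficients
  est <- sm[2, "Estimate"]; se <- sm[2, "Std. Error"]
  tibble(rate_ratio = exp(est), p = sm[2, "Pr(>|z|)"],
         conf_low = exp(est - 1.96 * se), conf_high = exp(est + 1.96 * se),
         method = "poisson-regression", flag = flag)
}

#' Mutation hotspots across samples
#'
#' A position's independent-mutation load is the number of distinct
#' (sample, event) pairs at that position — per-sample distinct, summed over
#' samples. Positions with a load strictly greater than `min_independent` are
#' hotspots.
#'
#' @param calls Call tibble across samples.
#' @param min_independent Threshold; a hotspot needs **more than** this many
#'   independent mutations (default 4).
#' @param count_col Count column used for the total-load column.
#' @return Tibble: `position`, `n_independent`, `n_total`, sorted by
#'   decreasing `n_independent`.
#' @export
find_hotspots <- function(calls, min_independent = 4, count_col = "raw_count") {
  if (nrow(calls) == 0) {
    return(tibble(position = integer(), n_independent = integer(),
                  n_total = integer()))
  }
  calls |>
    distinct(.data$sample_id, .data$position, .data$kind, .data$detail,
             .keep_all = TRUE) |>
    group_by(.data$position) |>
    summarise(n_independent = dplyr::n(),
              n_total = as.integer(sum(.data[[count_col]])),
              .groups = "drop") |>
    filter(.data$n_independent > min_independent) |>
    arrange(dplyr::desc(.data$n_independent), .data$position)
}

#' Indel association with homopolymer runs
#'
#' Counts, per indel kind, how many called indels fall inside a homopolymer
#' run of length `>= min_run_len` or within `adjacency_bp` of its ends.
#' Substitution calls are ignored.
#'
#' @param calls Call tibble.
#' @param runs Homopolymer tibble from [find_homopolymers()].
#' @param min_run_len Minimum run length considered (default 3).
#' @param adjacency_bp Flanking distance counted as "next to" a run
#'   (default 1).
#' @return Tibble per kind (`ins`, `del`): `n_inside_or_adjacent`, `n_total`,
#'   `fraction`.
#' @export
homopolymer_association <- function(calls, runs, min_run_len = 3,
                                    adjacency_bp = 1) {
  runs <- filter(runs, .data$length >= min_run_len)
  indels <- filter(calls, .data$kind %in% c("ins", "del"))
  in_run <- function(p) {
    any(p >= runs$start - adjacency_bp &
          p <= runs$start + runs$length - 1 + adjacency_bp)
  }
  indels |>
    mutate(hit = purrr::map_lgl(.data$position, in_run)) |>
    group_by(.data$kind) |>
    summarise(n_inside_or_adjacent = sum(.data$hit), n_total = dplyr::n(),
              fraction = mean(.data$hit), .groups = "drop")
}

#' Power of spectrum estimation from k sampled mutants
#'
#' How many mutants must be sequenced per animal to recover its mutation
#' spectrum? Subsamples of size `k` are drawn without replacement from the
#' animal's full mutation list; each subsample's class spectrum is compared
#' with the full-list spectrum and power is the fraction of draws that are
#' *not* significantly different at `alpha`. The default comparison is a
#' chi-squared goodness-of-fit of subsample counts against the full-list
#' class proportions with a Monte-Carlo p-value; `metric` accepts any
#' function `(sub_counts, full_probs) -> p-value` as an alternative strategy.
#'
#' @param classes Character vector: the class of every mutation in the full
#'   list (one entry per independent mutation).
#' @param k Subsample size (<= `length(classes)`).
#' @param n_iter Number of subsampling iterations (>= 100).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @param metric Optional p-value function; default goodness-of-fit.
#' @param B Monte-Carlo draws inside the default metric.
#' @return Tibble: `k`, `power`, `n_iter`.
#' @export
power_simulation <- function(classes, k, n_iter = 1000, alpha = 0.05,
                             seed = 1, metric = NULL, B = 2000) {
  n <- length(classes)
  if (k > n) stop("k exceeds the size of the mutation list", call. = FALSE)
  if (n_iter < 100) stop("n_iter must be >= 100", call. = FALSE)
  lv <- unique(classes)
  full_counts <- table(factor(classes, levels = lv))
  full_probs <- as.numeric(full_counts) / n
  if (is.null(metric)) {
    metric <- function(sub_counts, probs) {
      suppressWarnings(stats::chisq.test(sub_counts, p = probs,
                                         simulate.p.value = TRUE,
                                         B = B)$p.value)
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hits <- vapply(seq_len(n_iter), function(i) {
    sub <- sample(classes, k, replace = FALSE)
    sc <- as.numeric(table(factor(sub, levels = lv)))
    metric(sc, full_probs) >= alpha
  }, logical(1))
  tibble(k = k, power = mean(hits), n_iter = n_iter)
}
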