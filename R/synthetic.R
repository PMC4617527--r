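#' Default mutation-class probabilities
#'
#' Class mixes for the two exposure conditions the generator emulates. The
#' grouped totals follow the reported bone-marrow spectra — control:
#' transitions 0.35, transversions 0.49, indels 0.16; mutagen-exposed (bulky
#' guanine-adduct profile): transitions 0.14, transversions 0.61, indels 0.25
#' — with the within-group allocation dominated by `GC>TA` for the exposed
#' condition and insertion:deletion split ~1:4.
#'
#' @return Named probability vector over the eight mutation classes.
#' @export
class_probs_control <- function() {
  c("GC>AT" = 0.30, "GC>TA" = 0.25, "GC>CG" = 0.12,
    "AT>GC" = 0.05, "AT>TA" = 0.08, "AT>CG" = 0.04,
    insertion = 0.02, deletion = 0.14)
}

#' @rdname class_probs_control
#' @export
class_probs_bap <- function() {
  c("GC>AT" = 0.12, "GC>TA" = 0.45, "GC>CG" = 0.10,
    "AT>GC" = 0.02, "AT>TA" = 0.04, "AT>CG" = 0.02,
    insertion = 0.047, deletion = 0.203)
}

#' Generate a seeded toy reference gene
#'
#' A random gene (length a multiple of 3) for fast tests; the bundled lacZ
#' sequence is used where realism matters.
#'
#' @param length Gene length in bp (rounded up to a multiple of 3).
#' @param seed RNG seed.
#' @return A [ref_gene].
#' @export
random_toy_gene <- function(length = 450, seed = 1) {
  length <- 3L * ceiling(length / 3)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ref_gene(paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""),
           name = "toygene")
}

#' Configuration for the pooled-plaque generator
#'
#' The defaults emulate the assay conditions of a deep-sequenced Muta(TM)Mouse
#' lacZ experiment: pools of mutant plaques amplified in two technical
#' replicates, per-library coverage ~9e4x, a positional background-error field
#' shared by every library (substitution rates log-uniform on
#' `[1.7e-5, 2.15e-2]`), indel error elevated at homopolymers, and
#' replicate-specific PCR artefacts.
#'
#' @param gene A [ref_gene] (default: seeded 450-bp toy gene).
#' @param n_samples Pools per group to simulate.
#' @param n_plaques Mutant plaques pooled per sample.
#' @param clonal_fraction Probability that a plaque duplicates an earlier
#'   plaque's mutation within the same animal (clonal expansion).
#' @param class_probs Named probability vector over the eight mutation
#'   classes.
#' @param n_hotspots,hotspot_weight Number of hotspot positions and their
#'   sampling-weight multiplier.
#' @param depth Read depth per position per library.
#' @param sub_noise_range Log-uniform range of per-event background rates.
#' @param indel_noise_multiplier Multiplier applied to indel background at
#'   positions inside/adjacent to homopolymers of length
#'   `>= homopolymer_min_len` (capped at `indel_noise_max`).
#' @param homopolymer_min_len,adjacency_bp Homopolymer definition for the
#'   elevated-indel-error region.
#' @param indel_noise_max Cap on any indel background rate.
#' @param pcr_n_events Replicate-specific PCR artefact events per library.
#' @param pcr_prop_range Log-uniform range of PCR artefact proportions.
#' @param hitchhiker_rate Probability a plaque carries an extra silent
#'   substitution alongside its driving mutation.
#' @param plaque_weight_cv Coefficient of variation of per-plaque read
#'   weights (0 = equal-sized plaques).
#' @param seed RNG seed; every stochastic element derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(gene = random_toy_gene(),
                       n_samples = 6,
                       n_plaques = 500,
                       clonal_fraction = 0.3,
                       class_probs = class_probs_bap(),
                       n_hotspots = 20,
                       hotspot_weight = 10,
                       depth = 9e4,
                       sub_noise_range = c(1.7e-5, 2.15e-2),
                       indel_noise_multiplier = 50,
                       homopolymer_min_len = 4,
                       adjacency_bp = 1,
                       indel_noise_max = 0.464,
                       pcr_n_events = 10,
                       pcr_prop_range = c(1e-3, 2e-2),
                       hitchhiker_rate = 0,
                       plaque_weight_cv = 0,
                       seed = 1) {
  if (abs(sum(class_probs) - 1) > 1e-8) {
    stop("class_probs must sum to 1", call. = FALSE)
  }
  if (!all(names(class_probs) %in% MUTATION_CLASSES) ||
      is.null(names(class_probs))) {
    stop("class_probs must be named by mutation class", call. = FALSE)
  }
  if (clonal_fraction < 0 || clonal_fraction >= 1) {
    stop("clonal_fraction must be in [0, 1)", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# shared positional background-error field over the full event grid
build_noise_field <- function(config) {
  gene <- config$gene
  L <- gene$length
  chars <- strsplit(gene$sequence, "")[[1]]
  subs <- tidyr::expand_grid(position = seq_len(L), detail = DNA_BASES) |>
    mutate(kind = "sub") |>
    filter(chars[.data$position] != .data$detail)
  indels <- bind_rows(
    tibble(position = seq_len(L), kind = "ins", detail = chars),
    tibble(position = seq_len(L), kind = "del", detail = "1")
  )
  grid <- bind_rows(subs, indels) |>
    select("position", "kind", "detail")
  if (all(config$sub_noise_range == 0)) {
    grid$rate <- 0
  } else {
    lo <- log10(config$sub_noise_range[1])
    hi <- log10(config$sub_noise_range[2])
    grid$rate <- 10^stats::runif(nrow(grid), lo, hi)
  }
  runs <- find_homopolymers(gene, min_len = config$homopolymer_min_len)
  if (nrow(runs) > 0) {
    hp <- unique(unlist(purrr::map2(
      runs$start - config$adjacency_bp,
      runs$start + runs$length - 1 + config$adjacency_bp,
      seq
    )))
    hot <- grid$kind %in% c("ins", "del") & grid$position %in% hp
    grid$rate[hot] <- pmin(grid$rate[hot] * config$indel_noise_multiplier,
                           config$indel_noise_max)
  }
  grid
}

# draw one new driving mutation given class and positional weights; the
# class may be fixed by the caller so site-collision retries cannot tilt the
# class mix
draw_mutation <- function(config, chars, weights, cls = NULL) {
  if (is.null(cls)) {
    cls <- sample(names(config$class_probs), 1, prob = config$class_probs)
  }
  L <- length(chars)
  if (cls == "insertion") {
    p <- sample.int(L, 1, prob = weights)
    len <- if (stats::runif(1) < 0.95) 1L else 2L
    detail <- strrep(chars[p], len)
    return(list(position = p, kind = "ins", detail = detail, class = cls))
  }
  if (cls == "deletion") {
    p <- sample.int(L, 1, prob = weights)
    len <- if (stats::runif(1) < 0.86) 1L else 2L
    if (p + len - 1L > L) len <- 1L
    return(list(position = p, kind = "del", detail = as.character(len),
                class = cls))
  }
  pair <- substr(cls, 1, 2)           # "GC" or "AT"
  target_to <- substr(cls, 4, 4)      # alt on the purine strand
  ok <- if (pair == "GC") chars %in% c("G", "C") else chars %in% c("A", "T")
  w <- weights * ok
  p <- sample.int(L, 1, prob = w)
  alt <- if (chars[p] %in% c("G", "A")) target_to else complement_base(target_to)
  list(position = p, kind = "sub", detail = alt, class = cls)
}

# rejection-sample a silent (synonymous) substitution
draw_silent <- function(config, chars, weights) {
  gene <- config$gene
  for (i in 1:50) {
    p <- sample.int(length(chars), 1, prob = weights)
    alts <- setdiff(DNA_BASES, chars[p])
    a <- sample(alts, 1)
    imp <- tryCatch(classify_impact(gene, p, "sub", a), error = function(e) NA)
    if (identical(imp, "silent")) {
      return(list(position = p, kind = "sub", detail = a,
                  class = classify_mutation_class(chars[p], "sub", a)))
    }
  }
  NULL
}

#' Simulate pooled-plaque sequencing libraries with known truth
#'
#' For each sample, `n_plaques` plaques each receive one phenotype-driving
#' mutation (position hotspot-weighted, type from `class_probs`); with
#' probability `clonal_fraction` a plaque instead duplicates an earlier
#' plaque's mutation (clonal expansion). Each of the two technical replicates
#' then draws, for every event, a binomial read count at the configured depth
#' with success probability `copies / n_plaques` (weighted by plaque size if
#' `plaque_weight_cv > 0`) plus the shared positional background rate plus any
#' replicate-specific PCR artefact proportion.
#'
#' @param config A [sim_config].
#' @param group Group label stored in the sample sheet.
#' @param wild_type If `TRUE`, pools carry no true mutations (negative-control
#'   plaques): libraries contain background and PCR error only, while the
#'   sample sheet keeps `n_plaques` for thresholding.
#' @param noise_field Optional background field (the `noise_truth` tibble of a
#'   previous call) so that several simulated groups share one positional
#'   error field, as libraries sequenced on one platform and chip do. Default
#'   `NULL` draws a fresh field from `config`.
#' @return List with `samples` (per sample: list of two [position_counts]),
#'   `truth` (tibble: `sample_id`, `position`, `kind`, `detail`, `copies`,
#'   `class`, `driver`), `noise_truth` (generating background field),
#'   `sample_sheet` (tibble, pfu columns left `NA` for the caller to fill).
#' @export
simulate_pools <- function(config, group = "treated", wild_type = FALSE,
                           noise_field = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  gene <- config$gene
  L <- gene$length
  chars <- strsplit(gene$sequence, "")[[1]]

  weights <- rep(1, L)
  hotspots <- sample.int(L, min(config$n_hotspots, L))
  weights[hotspots] <- config$hotspot_weight

  noise <- if (is.null(noise_field)) build_noise_field(config) else noise_field
  if (max(noise$position) > L) {
    stop("noise_field positions exceed the reference length", call. = FALSE)
  }
  noise_key <- paste(noise$position, noise$kind, noise$detail)

  samples <- list()
  truth_all <- list()
  for (s in seq_len(config$n_samples)) {
    sample_id <- sprintf("%s%02d", group, s)
    muts <- vector("list", if (wild_type) 0 else config$n_plaques)
    extras <- list()
    seen <- character(0)
    for (i in seq_len(length(muts))) {
      if (i > 1 && stats::runif(1) < config$clonal_fraction) {
        muts[[i]] <- muts[[sample.int(i - 1, 1)]]
      } else {
        # recurrence within a sample is attributed to clonal expansion, so a
        # fresh plaque must carry a mutation not drawn before in this sample;
        # the mutation class is drawn once and only the site is retried, so
        # collisions cannot tilt the class mix
        cls <- sample(names(config$class_probs), 1, prob = config$class_probs)
        for (try in 1:100) {
          m <- draw_mutation(config, chars, weights, cls = cls)
          k <- paste(m$position, m$kind, m$detail)
          if (!k %in% seen) break
        }
        seen <- c(seen, k)
        muts[[i]] <- m
      }
      if (config$hitchhiker_rate > 0 &&
          stats::runif(1) < config$hitchhiker_rate) {
        hh <- draw_silent(config, chars, weights)
        if (!is.null(hh)) extras[[length(extras) + 1]] <- hh
      }
    }
    plaque_w <- if (config$plaque_weight_cv > 0) {
      stats::rgamma(length(muts), shape = 1 / config$plaque_weight_cv^2,
                    rate = 1 / config$plaque_weight_cv^2)
    } else {
      rep(1, length(muts))
    }
    drv <- tibble(
      position = purrr::map_int(muts, ~ as.integer(.x$position)),
      kind = purrr::map_chr(muts, "kind"),
      detail = purrr::map_chr(muts, "detail"),
      class = purrr::map_chr(muts, "class"),
      w = plaque_w
    ) |>
      group_by(.data$position, .data$kind, .data$detail, .data$class) |>
      summarise(copies = dplyr::n(), weight = sum(.data$w), .groups = "drop") |>
      mutate(driver = TRUE)
    if (length(extras) > 0) {
      hh <- tibble(
        position = purrr::map_int(extras, ~ as.integer(.x$position)),
        kind = purrr::map_chr(extras, "kind"),
        detail = purrr::map_chr(extras, "detail"),
        class = purrr::map_chr(extras, "class")
      ) |>
        group_by(.data$position, .data$kind, .data$detail, .data$class) |>
        summarise(copies = dplyr::n(), .groups = "drop") |>
        mutate(weight = .data$copies, driver = FALSE)
      drv <- bind_rows(drv, hh)
    }
    total_weight <- sum(plaque_w)
    truth <- mutate(drv, sample_id = sample_id,
                    true_prop = .data$weight / total_weight)

    reps <- purrr::map(c("A", "B"), function(rep_tag) {
      prop <- noise$rate
      hit <- match(paste(truth$position, truth$kind, truth$detail), noise_key)
      on_grid <- !is.na(hit)
      prop[hit[on_grid]] <- prop[hit[on_grid]] + truth$true_prop[on_grid]
      grid <- noise
      grid$prop <- prop
      if (any(!on_grid)) {
        grid <- bind_rows(grid,
                          tibble(position = truth$position[!on_grid],
                                 kind = truth$kind[!on_grid],
                                 detail = truth$detail[!on_grid],
                                 rate = 0,
                                 prop = truth$true_prop[!on_grid]))
      }
      if (config$pcr_n_events > 0) {
        idx <- sample.int(nrow(grid), config$pcr_n_events)
        grid$prop[idx] <- grid$prop[idx] +
          10^stats::runif(config$pcr_n_events,
                          log10(config$pcr_prop_range[1]),
                          log10(config$pcr_prop_range[2]))
      }
      cnt <- stats::rbinom(nrow(grid), config$depth, pmin(grid$prop, 1))
      ev <- grid[cnt > 0, c("position", "kind", "detail")]
      ev$count <- cnt[cnt > 0]
      position_counts(ev, rep(as.integer(config$depth), L),
                      library_id = paste0(sample_id, "_", rep_tag),
                      sample_id = sample_id)
    })
    samples[[sample_id]] <- reps
    truth_all[[sample_id]] <- select(truth, "sample_id", "position", "kind",
                                     "detail", "copies", "class", "driver",
                                     "true_prop")
  }
  list(
    samples = samples,
    truth = list_rbind(truth_all),
    noise_truth = noise,
    sample_sheet = tibble(sample_id = names(samples), group = group,
                          n_plaques = config$n_plaques,
                          mutant_pfu = NA_integer_, total_pfu = NA_integer_)
  )
}

#' Simulate a calibration mixture with known copy numbers
#'
#' Emulates control libraries built by mixing subcloned mutant plaques in
#' known proportions: mutation `i` is carried by `copies[i]` plaques of a pool
#' of `sum(copies)`, sequenced in two technical replicates. Used to exercise
#' [fit_lod_linear()].
#'
#' @param copies Integer vector of known per-mutation copy numbers.
#' @param gene A [ref_gene].
#' @param depth Read depth per position.
#' @param noise_range Background range (`c(0, 0)` for noiseless mixtures).
#' @param plaque_weight_cv Per-plaque size variation (0 = equal).
#' @param seed RNG seed.
#' @return List: `samples`, `truth`, `noise_truth`, `sample_sheet` as in
#'   [simulate_pools()].
#' @export
simulate_calibration_mixture <- function(copies, gene = random_toy_gene(),
                                         depth = 9e4,
                                         noise_range = c(1.7e-5, 2.15e-2),
                                         plaque_weight_cv = 0, seed = 1) {
  n <- sum(copies)
  noiseless <- all(noise_range == 0)
  config <- sim_config(
    gene = gene, n_samples = 1, n_plaques = n, clonal_fraction = 0,
    depth = depth,
    sub_noise_range = if (noiseless) c(1e-12, 1e-12) else noise_range,
    indel_noise_multiplier = 1, pcr_n_events = 0,
    plaque_weight_cv = plaque_weight_cv, seed = seed
  )
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  chars <- strsplit(gene$sequence, "")[[1]]
  # distinct substitution events, one per calibration mutant
  pos <- sample.int(gene$length, length(copies))
  alt <- purrr::map_chr(pos, ~ sample(setdiff(DNA_BASES, chars[.x]), 1))
  plaque_w <- if (plaque_weight_cv > 0) {
    stats::rgamma(n, shape = 1 / plaque_weight_cv^2, rate = 1 / plaque_weight_cv^2)
  } else {
    rep(1, n)
  }
  owner <- rep(seq_along(copies), copies)
  weight <- tapply(plaque_w, owner, sum)
  truth <- tibble(sample_id = "calibration01", position = as.integer(pos),
                  kind = "sub", detail = alt, copies = as.integer(copies),
                  class = classify_mutation_class(chars[pos], "sub", alt),
                  driver = TRUE,
                  true_prop = as.numeric(weight) / sum(plaque_w))
  noise <- build_noise_field(config)
  if (noiseless) noise$rate <- 0
  noise_key <- paste(noise$position, noise$kind, noise$detail)
  reps <- purrr::map(c("A", "B"), function(rep_tag) {
    prop <- noise$rate
    hit <- match(paste(truth$position, truth$kind, truth$detail), noise_key)
    prop[hit] <- prop[hit] + truth$true_prop
    cnt <- stats::rbinom(nrow(noise), as.integer(depth), pmin(prop, 1))
    ev <- noise[cnt > 0, c("position", "kind", "detail")]
    ev$count <- cnt[cnt > 0]
    position_counts(ev, rep(as.integer(depth), gene$length),
                    library_id = paste0("calibration01_", rep_tag),
                    sample_id = "calibration01")
  })
  list(samples = list(calibration01 = reps), truth = truth, noise_truth = noise,
       sample_sheet = tibble(sample_id = "calibration01", group = "calibration",
                             n_plaques = n, mutant_pfu = NA_integer_,
                             total_pfu = NA_integer_))
}

#' Simulate a complete two-group study with a shared error field
#'
#' Composes the full assay design: treated and control pooled samples plus a
#' wild-type negative-control pool, all sequenced in technical duplicate on
#' one platform, i.e. sharing a single positional background-error field.
#' Mutant and total plaque-forming units are drawn per animal around the
#' group mutant-frequency means so the report's frequency statistics can run.
#'
#' @param gene A [ref_gene].
#' @param seed RNG seed; group-level seeds derive from it.
#' @param n_treated,n_control Animals per group.
#' @param plaques_treated,plaques_control Pooled mutant plaques per animal.
#' @param class_probs_treated,class_probs_control Mutation-class mixes.
#' @param mf_treated,mf_control Group mean mutant frequencies (mutant pfu per
#'   total pfu) used to draw per-animal pfu counts.
#' @param total_pfu Total plaque-forming units assayed per animal.
#' @param depth Read depth per position per library.
#' @param ... Further arguments passed to [sim_config()].
#' @return List: `sample_sheet`, `counts` (named list of replicate pairs),
#'   `wild_type` (replicate pair for background estimation), `truth`
#'   (both groups), `noise_truth`.
#' @export
simulate_study <- function(gene, seed = 1, n_treated = 6, n_control = 6,
                           plaques_treated = 500, plaques_control = 145,
                           class_probs_treated = class_probs_bap(),
                           class_probs_control_ = class_probs_control(),
                           mf_treated = 701.7e-5, mf_control = 8.6e-5,
                           total_pfu = 3e5, depth = 9e4, ...) {
  cfg_t <- sim_config(gene = gene, n_samples = n_treated,
                      n_plaques = plaques_treated,
                      class_probs = class_probs_treated, depth = depth,
                      seed = seed, ...)
  sim_t <- simulate_pools(cfg_t, group = "treated")
  cfg_c <- sim_config(gene = gene, n_samples = n_control,
                      n_plaques = plaques_control,
                      class_probs = class_probs_control_, depth = depth,
                      seed = seed + 1, ...)
  sim_c <- simulate_pools(cfg_c, group = "control",
                          noise_field = sim_t$noise_truth)
  cfg_w <- sim_config(gene = gene, n_samples = 1, n_plaques = 100,
                      depth = depth, seed = seed + 2, ...)
  sim_w <- simulate_pools(cfg_w, group = "wildtype", wild_type = TRUE,
                          noise_field = sim_t$noise_truth)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 3)
  ss <- bind_rows(sim_c$sample_sheet, sim_t$sample_sheet)
  mf <- ifelse(ss$group == "treated", mf_treated, mf_control)
  ss$total_pfu <- as.integer(total_pfu)
  ss$mutant_pfu <- stats::rpois(nrow(ss), total_pfu * mf)
  list(sample_sheet = ss,
       counts = c(sim_c$samples, sim_t$samples),
       wild_type = sim_w$samples[[1]],
       truth = bind_rows(sim_c$truth, sim_t$truth),
       noise_truth = sim_t$noise_truth)
}
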