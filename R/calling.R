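#' Plaque-count-derived calling threshold
#'
#' In a pool of `n_plaques` mutant plaques amplified and sequenced together, a
#' mutation carried by a single plaque is expected in `1 / n_plaques` of the
#' reads. The calling threshold is that expected proportion scaled by a
#' stringency multiplier: 1.0 (exact expected proportion), 0.75, or 0.5.
#'
#' @param n_plaques Number of pooled mutant plaques (>= 1).
#' @param stringency Multiplier, one of 1.0, 0.75, 0.5.
#' @return Threshold proportion.
#' @examples
#' calling_threshold(100, 1.0)   # 0.01
#' calling_threshold(100, 0.5)   # 0.005
#' @export
calling_threshold <- function(n_plaques, stringency = 1.0) {
  if (length(n_plaques) != 1 || is.na(n_plaques) || n_plaques < 1) {
    stop("n_plaques must be a positive integer", call. = FALSE)
  }
  if (!stringency %in% c(1.0, 0.75, 0.5)) {
    stop("stringency must be 1.0, 0.75 or 0.5", call. = FALSE)
  }
  stringency * (1 / n_plaques)
}

#' Call mutations from a replicate pair of true-proportion tables
#'
#' An event is called when its noise-subtracted (true) proportion reaches the
#' threshold in **both** technical replicates — the replicate concordance
#' filter that removes PCR artefacts arising in a single amplification — and,
#' for indels, when the event is not masked by the indel noise cap. The
#' estimated copy number (`raw_count`) is the replicate-averaged true
#' proportion divided by the expected single-copy proportion `1 / n_plaques`
#' (the stringency-1.0 threshold), rounded half-up with floor 1, regardless of
#' the calling stringency.
#'
#' @param rep1,rep2 True-proportion tibbles for the two technical replicates
#'   of one pool (from [subtract_noise()]).
#' @param n_plaques Number of pooled mutant plaques.
#' @param stringency Calling stringency multiplier (1.0, 0.75 or 0.5).
#' @param mask Optional tibble of masked indel events from [indel_mask()].
#' @return Tibble of calls: `sample_id`, `position`, `kind`, `detail`,
#'   `true_prop_rep1`, `true_prop_rep2`, `threshold_used`, `raw_count`.
#' @export
call_mutations <- function(rep1, rep2, n_plaques, stringency = 1.0,
                           mask = NULL) {
  assert_event_cols(rep1, c("position", "kind", "detail", "true_prop"))
  assert_event_cols(rep2, c("position", "kind", "detail", "true_prop"))
  l1 <- attr(rep1, "gene_length"); l2 <- attr(rep2, "gene_length")
  if (!is.null(l1) && !is.null(l2) && l1 != l2) {
    stop("replicate position ranges differ", call. = FALSE)
  }
  threshold <- calling_threshold(n_plaques, stringency)
  expected_single <- calling_threshold(n_plaques, 1.0)
  sample_id <- unique(c(rep1$sample_id, rep2$sample_id))
  if (length(sample_id) != 1) {
    stop("replicates must come from the same pool", call. = FALSE)
  }
  key <- c("position", "kind", "detail")
  joined <- full_join(
    select(rep1, dplyr::all_of(key), true_prop_rep1 = "true_prop"),
    select(rep2, dplyr::all_of(key), true_prop_rep2 = "true_prop"),
    by = key
  ) |>
    mutate(true_prop_rep1 = dplyr::coalesce(.data$true_prop_rep1, 0),
           true_prop_rep2 = dplyr::coalesce(.data$true_prop_rep2, 0)) |>
    filter(.data$true_prop_rep1 >= threshold, .data$true_prop_rep2 >= threshold)
  if (!is.null(mask) && nrow(mask) > 0) {
    joined <- anti_join(joined, mask, by = key)
  }
  joined |>
    mutate(
      sample_id = sample_id,
      threshold_used = threshold,
      raw_count = pmax(
        1L,
        as.integer(round_half_up(
          ((.data$true_prop_rep1 + .data$true_prop_rep2) / 2) / expected_single
        ))
      )
    ) |>
    select("sample_id", "position", "kind", "detail", "true_prop_rep1",
           "true_prop_rep2", "threshold_used", "raw_count") |>
    arrange(.data$position, .data$kind, .data$detail)
}

#' Events failing replicate concordance
#'
#' Companion diagnostic to [call_mutations()]: events that pass the threshold
#' in exactly one technical replicate (removed from calling as presumptive
#' PCR artefacts), mirroring per-threshold "mutants removed" accounting.
#'
#' @inheritParams call_mutations
#' @return Tibble of discordant events.
#' @export
discordant_events <- function(rep1, rep2, n_plaques, stringency = 1.0) {
  threshold <- calling_threshold(n_plaques, stringency)
  key <- c("position", "kind", "detail")
  joined <- full_join(
    select(rep1, dplyr::all_of(key), true_prop_rep1 = "true_prop"),
    select(rep2, dplyr::all_of(key), true_prop_rep2 = "true_prop"),
    by = key
  ) |>
    mutate(true_prop_rep1 = dplyr::coalesce(.data$true_prop_rep1, 0),
           true_prop_rep2 = dplyr::coalesce(.data$true_prop_rep2, 0))
  filter(joined, xor(.data$true_prop_rep1 >= threshold,
                     .data$true_prop_rep2 >= threshold))
}

#' Per-sample tabulation of independent, total and recurrent mutations
#'
#' Within one animal, each distinct event is a single **independent**
#' mutation regardless of how many plaques carried it; its copies beyond the
#' first are **recurrent** mutations attributed to clonal expansion.
#'
#' @param calls Call tibble (one or more samples) with `sample_id` and a count
#'   column.
#' @param count_col Which count to total: `"raw_count"` (default) or
#'   `"adjusted_count"`.
#' @return Tibble per sample: `independent`, `total`, `recurrent`.
#' @export
tabulate_mutations <- function(calls, count_col = "raw_count") {
  if (nrow(calls) == 0) {
    return(tibble(sample_id = character(), independent = integer(),
                  total = integer(), recurrent = integer()))
  }
  calls |>
    group_by(.data$sample_id) |>
    summarise(independent = dplyr::n_distinct(.data$position, .data$kind,
                                              .data$detail),
              total = as.integer(sum(.data[[count_col]])),
              .groups = "drop") |>
    mutate(recurrent = .data$total - .data$independent)
}
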