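#' Estimate the per-position, per-event false mutation proportion
#'
#' PCR and sequencing artefacts recur at characteristic positions and rates
#' that are consistent across barcoded libraries, so the background ("false
#' mutation proportion") of every event is estimated as the median of that
#' event's read proportion across all libraries; libraries in which the event
#' was never seen contribute 0. The median keeps a genuine mutation present in
#' a minority of libraries (at most two libraries per pooled sample) from
#' inflating its own background estimate.
#'
#' The profile also records the **indel cap**: the largest false mutation
#' proportion observed for any base substitution. Indel events whose
#' background exceeds this cap (typically homopolymer slippage artefacts) are
#' masked from calling; see [indel_mask()].
#'
#' @param props List of proportion tibbles from [to_proportions()], or a list
#'   of [position_counts] objects (converted internally). At least 3
#'   libraries with identical position ranges.
#' @param exclude Optional character vector of `library_id`s to drop before
#'   taking the median (leave-one-out mode: exclude the libraries of the
#'   sample under test). Default `NULL` follows the all-samples convention.
#' @return A `noise_profile`: tibble (`position`, `kind`, `detail`,
#'   `false_prop`) with attributes `n_libraries`, `indel_cap`.
#' @export
estimate_noise <- function(props, exclude = NULL) {
  if (all(purrr::map_lgl(props, inherits, "position_counts"))) {
    props <- purrr::map(props, to_proportions)
  }
  if (!is.null(exclude)) {
    props <- purrr::discard(props, ~ any(unique(.x$library_id) %in% exclude))
  }
  n_lib <- length(props)
  if (n_lib < 3) stop("need >= 3 libraries for a meaningful median", call. = FALSE)
  ranges <- unique(purrr::map_int(props, function(x) {
    gl <- attr(x, "gene_length")
    if (is.null(gl)) NA_integer_ else as.integer(gl)
  }))
  ranges <- ranges[!is.na(ranges)]
  if (length(ranges) > 1) {
    stop("libraries have mismatched position ranges", call. = FALSE)
  }
  if (any(purrr::map_int(props, ~ length(unique(.x$library_id))) > 1)) {
    stop("each element of `props` must hold exactly one library", call. = FALSE)
  }
  all_props <- bind_rows(props)
  profile <- all_props |>
    filter(.data$prop > 0) |>
    group_by(.data$position, .data$kind, .data$detail) |>
    summarise(false_prop = median_zero_padded(.data$prop, n_lib),
              .groups = "drop")
  sub_rows <- filter(profile, .data$kind == "sub")
  indel_cap <- if (nrow(sub_rows) > 0) max(sub_rows$false_prop) else 0
  structure(profile, n_libraries = n_lib, indel_cap = indel_cap,
            class = c("noise_profile", class(profile)))
}

#' @rdname estimate_noise
#' @param profile A `noise_profile`.
#' @export
indel_cap <- function(profile) attr(profile, "indel_cap")

#' Indel events masked by the indel noise cap
#'
#' Returns the indel events whose false mutation proportion strictly exceeds
#' the largest substitution false mutation proportion. These sites — almost
#' always inside or adjacent to homopolymers on semiconductor platforms — are
#' too error-prone for reliable indel calling and are excluded.
#'
#' @param profile A `noise_profile` from [estimate_noise()].
#' @return Tibble of masked events (`position`, `kind`, `detail`,
#'   `false_prop`).
#' @export
indel_mask <- function(profile) {
  cap <- indel_cap(profile)
  profile |>
    as_tibble() |>
    filter(.data$kind %in% c("ins", "del"), .data$false_prop > cap)
}

#' Subtract background to obtain true mutation proportions
#'
#' `true_prop = max(0, prop - false_prop)` per event; events with no profile
#' entry subtract 0.
#'
#' @param props Proportion tibble from [to_proportions()] (one library).
#' @param profile A `noise_profile`.
#' @return The input tibble with `false_prop` and `true_prop` columns.
#' @export
subtract_noise <- function(props, profile) {
  assert_event_cols(props)
  props |>
    left_join(as_tibble(profile)[c("position", "kind", "detail", "false_prop")],
              by = c("position", "kind", "detail")) |>
    mutate(false_prop = dplyr::coalesce(.data$false_prop, 0),
           true_prop = pmax(0, .data$prop - .data$false_prop))
}

#' Serialize / read a noise profile as TSV
#'
#' @param profile A `noise_profile`.
#' @param path File path.
#' @return `path` invisibly; `read_noise_tsv()` returns the profile.
#' @export
write_noise_tsv <- function(profile, path) {
  writeLines(c(paste0("# poolmut noise profile v1 n_libraries=",
                      attr(profile, "n_libraries"),
                      " indel_cap=", format(indel_cap(profile), digits = 17))),
             path)
  readr::write_tsv(as_tibble(profile), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_noise_tsv
#' @export
read_noise_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  n_lib <- as.integer(sub(".*n_libraries=(\\d+).*", "\\1", hdr))
  cap <- as.numeric(sub(".*indel_cap=([^ ]+)$", "\\1", hdr))
  tbl <- readr::read_tsv(path, skip = 1, show_col_types = FALSE,
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           kind = readr::col_character(),
                           detail = readr::col_character(),
                           false_prop = readr::col_double()))
  structure(tbl, n_libraries = n_lib, indel_cap = cap,
            class = c("noise_profile", class(tbl)))
}
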