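#' @importFrom rlang .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join full_join inner_join anti_join bind_rows n distinct rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map2 imap list_rbind
NULL

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

#' Canonical event kinds
#'
#' Events are keyed by 1-based `position`, `kind` (`"sub"`, `"ins"`, `"del"`)
#' and `detail`: the alternative base for substitutions, the inserted sequence
#' for insertions (anchored to the base immediately 5' of the insertion), and
#' the deleted length in bp for deletions (anchored at the first deleted base).
#' @name event-keys
NULL

EVENT_KINDS <- c("sub", "ins", "del")

assert_event_cols <- function(tbl, cols = c("position", "kind", "detail")) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

# median of `x` padded with zeros up to length n (events absent from a library
# contribute proportion 0)
median_zero_padded <- function(x, n) {
  k <- n - length(x)
  if (k < 0) stop("more observations than libraries", call. = FALSE)
  if (k == 0) return(stats::median(x))
  # median of sorted c(rep(0, k), sort(x)) without materialising the zeros
  xs <- sort(x)
  pick <- function(i) if (i <= k) 0 else xs[i - k]
  if (n %% 2 == 1) pick((n + 1) / 2) else (pick(n / 2) + pick(n / 2 + 1)) / 2
}
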