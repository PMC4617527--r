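#' Per-library position-by-event count container
#'
#' A `position_counts` object holds, for one sequencing library (one PCR
#' replicate of one pooled sample), the read depth at every reference position
#' and the read counts of every non-reference event observed. Events follow
#' the keying described in [event-keys].
#'
#' @param events Tibble with columns `position`, `kind`, `detail`, `count`.
#' @param depth Integer vector of read depths, one per reference position.
#' @param library_id Library identifier (conventionally `<animal>_<A|B>`).
#' @param sample_id Pool/animal identifier.
#' @return A `position_counts` object.
#' @export
position_counts <- function(events, depth, library_id,
                            sample_id = sub("_[AB]$", "", library_id)) {
  assert_event_cols(events, c("position", "kind", "detail", "count"))
  events <- as_tibble(events) |>
    mutate(position = as.integer(.data$position),
           kind = as.character(.data$kind),
           detail = as.character(.data$detail),
           count = as.integer(.data$count)) |>
    arrange(.data$position, .data$kind, .data$detail)
  if (any(events$count < 0)) stop("negative event count", call. = FALSE)
  if (!all(events$kind %in% EVENT_KINDS)) {
    stop("event kind must be one of: ", paste(EVENT_KINDS, collapse = ", "),
         call. = FALSE)
  }
  L <- length(depth)
  if (nrow(events) > 0 && (min(events$position) < 1 || max(events$position) > L)) {
    stop("event position outside 1..", L, call. = FALSE)
  }
  structure(
    list(events = events, depth = as.integer(depth), length = L,
         library_id = library_id, sample_id = sample_id),
    class = "position_counts"
  )
}

#' @export
print.position_counts <- function(x, ...) {
  cat("<position_counts> library ", x$library_id, ": ", x$length,
      " positions, ", nrow(x$events), " events, median depth ",
      stats::median(x$depth), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.position_counts <- function(x, ...) {
  mutate(x$events, library_id = x$library_id, sample_id = x$sample_id,
         depth = x$depth[.data$position], .before = 1)
}

#' Parse a samtools text pileup into position-by-event counts
#'
#' Consumes the classic 6-column samtools pileup (chrom, 1-based pos, ref
#' base, depth, read bases, base qualities). Strand is collapsed: `.`/`,`
#' both count as reference and upper/lower-case alternative bases are merged,
#' because the reporter transgene has a fixed orientation and substitution
#' classes are reported collapsed over complementary strands. Insertions are
#' anchored at the preceding base (`+n<seq>` after that base's call);
#' deletions at their first deleted base, counted once from the `-n<seq>`
#' tag on the anchoring read base. `*` placeholders and `^`/`$` read
#' boundary marks are skipped.
#'
#' @param path Pileup file path.
#' @param gene A `ref_gene`; lines must reference `gene$name` and positions
#'   must not exceed its length.
#' @param library_id Library identifier.
#' @param sample_id Pool identifier (defaults to `library_id` minus a
#'   trailing replicate letter).
#' @return A [position_counts] object spanning positions `1..gene$length`.
#' @export
read_pileup <- function(path, gene, library_id,
                        sample_id = sub("_[AB]$", "", library_id)) {
  stopifnot(inherits(gene, "ref_gene"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  depth <- integer(gene$length)
  if (length(lines) == 0) {
    warning("empty pileup file: ", path, call. = FALSE)
    return(position_counts(
      tibble(position = integer(), kind = character(), detail = character(),
             count = integer()),
      depth, library_id, sample_id))
  }
  ev_pos <- integer(0); ev_kind <- character(0); ev_detail <- character(0)
  ev_count <- integer(0)
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) {
      f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    }
    if (length(f) < 5) stop("malformed pileup line ", ln, call. = FALSE)
    if (f[1] != gene$name) {
      stop("pileup line ", ln, " references '", f[1], "', expected '",
           gene$name, "'", call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1) stop("malformed position on line ", ln, call. = FALSE)
    if (pos > gene$length) {
      stop("position ", pos, " beyond reference length ", gene$length,
           " (line ", ln, ")", call. = FALSE)
    }
    d <- suppressWarnings(as.integer(f[4]))
    if (is.na(d) || d < 0) stop("malformed depth on line ", ln, call. = FALSE)
    depth[pos] <- d
    parsed <- parse_pileup_bases(f[5], ln)
    if (nrow(parsed) > 0) {
      ev_pos <- c(ev_pos, rep(pos, nrow(parsed)) + parsed$pos_shift)
      ev_kind <- c(ev_kind, parsed$kind)
      ev_detail <- c(ev_detail, parsed$detail)
      ev_count <- c(ev_count, parsed$count)
    }
  }
  events <- tibble(position = ev_pos, kind = ev_kind, detail = ev_detail,
                   count = ev_count) |>
    group_by(.data$position, .data$kind, .data$detail) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (nrow(events) > 0 && max(events$position) > gene$length) {
    stop("indel anchored beyond reference length", call. = FALSE)
  }
  position_counts(events, depth, library_id, sample_id)
}

# Tokenise one pileup read-base string. Returns a tibble of events with
# pos_shift: 0 for substitutions and deletions are re-anchored to their first
# deleted base (+1 from the anchoring call).
parse_pileup_bases <- function(s, line_no) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  kind <- character(0); detail <- character(0); shift <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }          # start mark + mapq char
    if (ch %in% c("$", "*", ".", ",", ">", "<")) { i <- i + 1L; next }
    if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- suppressWarnings(as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = "")))
      if (is.na(len) || len < 1 || j + len - 1L > n) {
        stop("malformed indel tag on pileup line ", line_no, call. = FALSE)
      }
      seq <- toupper(paste(chars[j:(j + len - 1L)], collapse = ""))
      if (ch == "+") {
        kind <- c(kind, "ins"); detail <- c(detail, seq); shift <- c(shift, 0L)
      } else {
        kind <- c(kind, "del"); detail <- c(detail, as.character(len))
        shift <- c(shift, 1L)  # anchor at first deleted base
      }
      i <- j + len
      next
    }
    if (toupper(ch) %in% DNA_BASES) {
      kind <- c(kind, "sub"); detail <- c(detail, toupper(ch)); shift <- c(shift, 0L)
      i <- i + 1L
      next
    }
    stop("unexpected character '", ch, "' on pileup line ", line_no, call. = FALSE)
  }
  if (length(kind) == 0) {
    return(tibble(kind = character(0), detail = character(0),
                  pos_shift = integer(0), count = integer(0)))
  }
  tibble(kind = kind, detail = detail, pos_shift = shift) |>
    group_by(.data$kind, .data$detail, .data$pos_shift) |>
    summarise(count = dplyr::n(), .groups = "drop")
}

COUNT_TSV_HEADER <- "# poolmut count table v1"

#' Read / write the internal count-table dialect
#'
#' A versioned TSV with columns `position`, `depth`, `event_kind`, `detail`,
#' `count`. Depth rows (`event_kind = "depth"`, one per position) carry the
#' per-position coverage; event rows carry non-reference counts. Reading a
#' table written by [write_count_tsv()] reproduces the object exactly.
#'
#' @param path File path.
#' @param library_id Library identifier (read) — defaults to the file stem.
#' @return [read_count_tsv()] returns a [position_counts];
#'   [write_count_tsv()] returns `path` invisibly.
#' @export
read_count_tsv <- function(path, library_id = sub("\\.tsv$", "", basename(path))) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  tbl <- readr::read_tsv(path, skip = skip, show_col_types = FALSE,
                         col_types = readr::cols(
                           position = readr::col_integer(),
                           depth = readr::col_integer(),
                           event_kind = readr::col_character(),
                           detail = readr::col_character(),
                           count = readr::col_integer()))
  if (any(tbl$count < 0, na.rm = TRUE)) stop("negative count in ", path, call. = FALSE)
  drows <- filter(tbl, .data$event_kind == "depth")
  L <- max(tbl$position)
  depth <- integer(L)
  depth[drows$position] <- drows$depth
  ev <- filter(tbl, .data$event_kind != "depth") |>
    select(position = "position", kind = "event_kind", detail = "detail",
           count = "count")
  if (anyDuplicated(ev[c("position", "kind", "detail")]) > 0) {
    stop("duplicate (position, event) rows in ", path, call. = FALSE)
  }
  position_counts(ev, depth, library_id)
}

#' @param pc A [position_counts] object.
#' @rdname read_count_tsv
#' @export
write_count_tsv <- function(pc, path) {
  stopifnot(inherits(pc, "position_counts"))
  depth_rows <- tibble(position = seq_len(pc$length), depth = pc$depth,
                       event_kind = "depth", detail = NA_character_,
                       count = NA_integer_)
  ev_rows <- pc$events |>
    mutate(depth = pc$depth[.data$position]) |>
    select("position", "depth", event_kind = "kind", "detail", "count")
  out <- bind_rows(depth_rows, ev_rows) |>
    arrange(.data$position, .data$event_kind != "depth", .data$event_kind,
            .data$detail)
  writeLines(COUNT_TSV_HEADER, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Convert counts to per-position event proportions
#'
#' Elementwise `count / depth` for every recorded event. Zero-depth positions
#' are retained with proportion 0 and flagged in the `zero_depth` column so
#' cross-library medians stay positionally aligned.
#'
#' @param pc A [position_counts] object.
#' @return Tibble with `library_id`, `sample_id`, `position`, `kind`,
#'   `detail`, `depth`, `prop`, `zero_depth`.
#' @export
to_proportions <- function(pc) {
  stopifnot(inherits(pc, "position_counts"))
  out <- as_tibble(pc) |>
    mutate(prop = ifelse(.data$depth > 0, .data$count / .data$depth, 0),
           zero_depth = .data$depth == 0) |>
    select("library_id", "sample_id", "position", "kind", "detail", "depth",
           "prop", "zero_depth")
  attr(out, "gene_length") <- pc$length
  out
}
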