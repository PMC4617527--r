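#' Run the full pooled-plaque analysis pipeline
#'
#' Orchestrates, across all libraries of an experiment: background (false
#' mutation proportion) estimation, indel masking, per-sample
#' threshold calling with replicate concordance, protein-impact and
#' mutation-class annotation, LOD/linear count adjustment, per-sample
#' clonality and corrected mutation frequency, group spectra and group
#' statistics.
#'
#' @param sample_sheet Data frame with columns `sample_id`, `group`,
#'   `n_plaques`, `mutant_pfu`, `total_pfu`.
#' @param counts Named list, one entry per `sample_id`, each a list of two
#'   [position_counts] (the technical replicates).
#' @param gene A [ref_gene]; library positions must span its length.
#' @param stringency Calling stringency (1.0, 0.75 or 0.5).
#' @param model A `clonality_model` for count adjustment; the default uses
#'   the published calibration (LOD 4, slope 1.1363, intercept 0.3123).
#' @param noise_mode `"all"` (median across all libraries, default) or
#'   `"leave_one_out"` (each sample's background excludes its own two
#'   libraries).
#' @param extra_noise_libraries Optional list of additional [position_counts]
#'   (e.g. a wild-type negative-control library) included in background
#'   estimation but not called.
#' @param B,mc_seed Monte-Carlo settings for spectrum tests.
#' @return A `pool_report` list: `calls` (annotated, with `adjusted_count`),
#'   `sample_summary`, `spectra` (per group), `spectrum_test`, `mf_test`,
#'   `fold_induction`, `noise_profile`, `mask`, `filter_log`.
#' @export
run_pipeline <- function(sample_sheet, counts, gene, stringency = 1.0,
                         model = clonality_model(), noise_mode = c("all", "leave_one_out"),
                         extra_noise_libraries = list(), B = 1e5,
                         mc_seed = 20151019) {
  noise_mode <- match.arg(noise_mode)
  assert_event_cols(sample_sheet,
                    c("sample_id", "group", "n_plaques", "mutant_pfu",
                      "total_pfu"))
  missing <- setdiff(sample_sheet$sample_id, names(counts))
  if (length(missing) > 0) {
    stop("no count data for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (sid in sample_sheet$sample_id) {
    if (length(counts[[sid]]) != 2) {
      stop("sample ", sid, " must have exactly two replicate libraries",
           call. = FALSE)
    }
    for (pc in counts[[sid]]) {
      if (pc$length != gene$length) {
        stop("library ", pc$library_id, " length ", pc$length,
             " does not match reference length ", gene$length, call. = FALSE)
      }
    }
  }

  all_pcs <- c(unlist(counts[sample_sheet$sample_id], recursive = FALSE,
                      use.names = FALSE),
               extra_noise_libraries)
  all_props <- purrr::map(all_pcs, to_proportions)
  names(all_props) <- purrr::map_chr(all_pcs, "library_id")
  profile_all <- estimate_noise(all_props)
  mask_all <- indel_mask(profile_all)

  filter_log <- list()
  calls <- purrr::map(sample_sheet$sample_id, function(sid) {
    pcs <- counts[[sid]]
    if (noise_mode == "leave_one_out") {
      prof <- estimate_noise(all_props,
                             exclude = purrr::map_chr(pcs, "library_id"))
      msk <- indel_mask(prof)
    } else {
      prof <- profile_all
      msk <- mask_all
    }
    np <- sample_sheet$n_plaques[sample_sheet$sample_id == sid]
    t1 <- subtract_noise(all_props[[pcs[[1]]$library_id]], prof)
    t2 <- subtract_noise(all_props[[pcs[[2]]$library_id]], prof)
    cl <- call_mutations(t1, t2, n_plaques = np, stringency = stringency,
                         mask = msk)
    disc <- discordant_events(t1, t2, n_plaques = np, stringency = stringency)
    filter_log[[sid]] <<- tibble(
      sample_id = sid,
      masked_indel_sites = nrow(msk),
      discordant_events = nrow(disc)
    )
    cl
  }) |> list_rbind()

  calls <- annotate_calls(calls, gene) |>
    mutate(adjusted_count = adjust_count(.data$raw_count, model))

  sample_summary <- tabulate_mutations(calls, count_col = "adjusted_count") |>
    rename(total_adjusted = "total") |>
    left_join(tabulate_mutations(calls, count_col = "raw_count") |>
                select("sample_id", total_raw = "total"),
              by = "sample_id") |>
    dplyr::right_join(as_tibble(sample_sheet), by = "sample_id") |>
    mutate(
      independent = dplyr::coalesce(.data$independent, 0L),
      total_adjusted = dplyr::coalesce(.data$total_adjusted, 0L),
      total_raw = dplyr::coalesce(.data$total_raw, 0L),
      clonality = clonality(.data$total_adjusted, .data$independent),
      mutant_frequency = .data$mutant_pfu / .data$total_pfu,
      mutation_frequency = corrected_mutation_frequency(
        .data$mutant_pfu, .data$total_pfu, .data$clonality)
    )

  groups <- unique(as.character(sample_sheet$group))
  spectra <- purrr::map(groups, function(gr) {
    ids <- sample_sheet$sample_id[sample_sheet$group == gr]
    build_spectrum(filter(calls, .data$sample_id %in% ids))
  })
  names(spectra) <- groups

  spectrum_test <- NULL
  mf_test <- NULL
  fold_induction <- NA_real_
  if (length(groups) == 2) {
    if (sum(spectra[[1]]$count) > 0 && sum(spectra[[2]]$count) > 0) {
      spectrum_test <- compare_spectra(spectra[[1]], spectra[[2]], B = B,
                                       mc_seed = mc_seed)
    }
    if (!any(is.na(sample_sheet$mutant_pfu))) {
      mf_test <- compare_mutant_frequency(sample_sheet)
      mf_group <- sample_summary |>
        group_by(.data$group) |>
        summarise(mean_mf = mean(.data$mutation_frequency), .groups = "drop")
      fold_induction <- mf_group$mean_mf[mf_group$group == groups[2]] /
        mf_group$mean_mf[mf_group$group == groups[1]]
    }
  }

  structure(
    list(calls = calls, sample_summary = sample_summary, spectra = spectra,
         spectrum_test = spectrum_test, mf_test = mf_test,
         fold_induction = fold_induction, noise_profile = profile_all,
         mask = mask_all, filter_log = list_rbind(filter_log),
         stringency = stringency, model = model, gene_name = gene$name),
    class = "pool_report"
  )
}

#' @export
print.pool_report <- function(x, ...) {
  cat("<pool_report> ", x$gene_name, ", stringency ", x$stringency, "\n",
      sep = "")
  cat("  samples: ", nrow(x$sample_summary), "; calls: ", nrow(x$calls),
      "; masked indel sites: ", nrow(x$mask), "\n", sep = "")
  if (!is.null(x$mf_test)) {
    cat("  mutant-frequency rate ratio: ",
        format(x$mf_test$rate_ratio, digits = 4),
        " (p = ", format(x$mf_test$p, digits = 3), ")\n", sep = "")
  }
  if (!is.na(x$fold_induction)) {
    cat("  clonality-corrected fold induction: ",
        format(x$fold_induction, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Export calls as a VCF-like TSV
#'
#' One row per call: gene name, 1-based position, REF base, ALT description,
#' per-replicate true proportions, counts and impact. A plain-text table, not
#' a formal VCF.
#'
#' @param calls Annotated call tibble.
#' @param gene A [ref_gene].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, gene, path) {
  chars <- strsplit(gene$sequence, "")[[1]]
  out <- calls |>
    mutate(
      chrom = gene$name,
      ref = chars[.data$position],
      alt = dplyr::case_when(
        .data$kind == "sub" ~ .data$detail,
        .data$kind == "ins" ~ paste0("ins", .data$detail),
        .data$kind == "del" ~ paste0("del", .data$detail, "bp")
      )
    ) |>
    select("chrom", pos = "position", "ref", "alt", "sample_id",
           dplyr::any_of(c("true_prop_rep1", "true_prop_rep2", "threshold_used",
                           "raw_count", "adjusted_count", "class", "impact")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a samtools-style text pileup for a library
#'
#' Inverse of [read_pileup()]: emits the classic 6-column pileup with
#' reference calls as `.`, substitutions as upper-case bases, insertions as
#' `+n<seq>` tags anchored at the preceding base, and deletions as `-n<seq>`
#' tags on the base before the first deleted base. Round-trips through
#' [read_pileup()] exactly.
#'
#' @param pc A [position_counts].
#' @param gene A [ref_gene].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pc, gene, path) {
  stopifnot(inherits(pc, "position_counts"))
  chars <- strsplit(gene$sequence, "")[[1]]
  ev <- pc$events
  lines <- character(pc$length)
  for (p in seq_len(pc$length)) {
    d <- pc$depth[p]
    here <- ev[ev$position == p, ]
    subs <- here[here$kind == "sub", ]
    ins <- here[here$kind == "ins", ]
    # deletions anchored at p are tagged on position p - 1
    dels <- ev[ev$kind == "del" & ev$position == p + 1L, ]
    n_sub <- sum(subs$count)
    if (n_sub > d) stop("event counts exceed depth at position ", p,
                        call. = FALSE)
    bases <- c(rep(".", d - n_sub), rep(subs$detail, subs$count))
    tags <- character(0)
    if (nrow(ins) > 0) {
      tags <- c(tags, rep(paste0("+", nchar(ins$detail), ins$detail),
                          ins$count))
    }
    if (nrow(dels) > 0 && p < pc$length) {
      del_len <- as.integer(dels$detail)
      del_seq <- purrr::map_chr(del_len, function(l) {
        paste(chars[(p + 1):min(p + l, pc$length)], collapse = "")
      })
      tags <- c(tags, rep(paste0("-", del_len, del_seq), dels$count))
    }
    if (length(tags) > 0) {
      k <- min(length(tags), length(bases))
      bases[seq_len(k)] <- paste0(bases[seq_len(k)], tags[seq_len(k)])
      if (length(tags) > k) {
        bases <- c(bases, paste0(".", tags[(k + 1):length(tags)]))
      }
    }
    quals <- strrep("I", max(d, 1))
    lines[p] <- paste(gene$name, p, chars[p], d,
                      paste(bases, collapse = ""), quals, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
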