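#' Load and correct a reporter-gene reference sequence
#'
#' Reads a single-record FASTA and applies an optional list of colony-specific
#' corrections (e.g. the Muta(TM)Mouse lacZ colony carries a handful of
#' variants relative to the archival coding sequence). Each correction states
#' the base expected in the FASTA at its position, so a stale variant list
#' fails loudly instead of silently corrupting the reference.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @param variants Optional data frame of corrections with columns
#'   `position` (1-based), `ref` (base expected in the FASTA) and `alt`
#'   (colony base to substitute); or a path to a TSV with those columns.
#' @param coding_offset 1-based position where codon 1 begins (default 1).
#' @param name Optional gene name; defaults to the FASTA record name.
#' @return A `ref_gene` object: list with `name`, `sequence` (upper-case
#'   character string), `length`, `coding_offset`, and `variants_applied`
#'   (tibble of corrections actually applied).
#' @examples
#' fa <- lacz_fasta_path()
#' gene <- load_reference(fa)
#' gene$length
#' @export
load_reference <- function(fasta_path, variants = NULL, coding_offset = 1,
                           name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1) {
    stop("expected exactly one FASTA record, found ", length(seqs), call. = FALSE)
  }
  sequence <- toupper(as.character(seqs[[1]]))
  if (is.null(name)) name <- sub("\\s.*$", "", names(seqs)[1])
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("reference sequence contains non-ACGT characters", call. = FALSE)
  }
  if (is.character(variants) && length(variants) == 1) {
    variants <- readr::read_tsv(variants, show_col_types = FALSE)
  }
  applied <- tibble(position = integer(), ref = character(), alt = character())
  if (!is.null(variants) && nrow(variants) > 0) {
    assert_event_cols(variants, c("position", "ref", "alt"))
    chars <- strsplit(sequence, "")[[1]]
    for (i in seq_len(nrow(variants))) {
      p <- as.integer(variants$position[i])
      if (p < 1 || p > length(chars)) {
        stop("variant position ", p, " outside reference", call. = FALSE)
      }
      if (chars[p] != toupper(variants$ref[i])) {
        stop("reference mismatch at position ", p, ": expected ",
             variants$ref[i], ", found ", chars[p], call. = FALSE)
      }
      chars[p] <- toupper(variants$alt[i])
    }
    sequence <- paste(chars, collapse = "")
    applied <- tibble(position = as.integer(variants$position),
                      ref = toupper(variants$ref), alt = toupper(variants$alt))
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         coding_offset = as.integer(coding_offset), variants_applied = applied),
    class = "ref_gene"
  )
}

#' @export
print.ref_gene <- function(x, ...) {
  cat("<ref_gene> ", x$name, ": ", x$length, " bp, codon 1 at position ",
      x$coding_offset, ", ", nrow(x$variants_applied),
      " correction(s) applied\n", sep = "")
  invisible(x)
}

#' Construct a ref_gene from a character string
#'
#' Convenience constructor used by the simulator and in tests.
#' @param sequence DNA string (A/C/G/T).
#' @param name Gene name.
#' @param coding_offset 1-based position of codon 1.
#' @return A `ref_gene` object.
#' @export
ref_gene <- function(sequence, name = "gene", coding_offset = 1) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) {
    stop("sequence contains non-ACGT characters", call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         coding_offset = as.integer(coding_offset),
         variants_applied = tibble(position = integer(), ref = character(),
                                   alt = character())),
    class = "ref_gene"
  )
}

#' Path to the bundled lacZ coding sequence
#'
#' The packaged reference is the 3075-bp Escherichia coli lacZ
#' (beta-galactosidase) coding sequence. The full archival gene record also
#' carries ~21 bp of flanking sequence (quoted gene length 3096 bp), so
#' censuses computed on the bundled CDS can differ from flank-inclusive ones
#' by a few runs; see the methods vignette.
#' @return Path to the FASTA file.
#' @export
lacz_fasta_path <- function() {
  system.file("extdata", "lacz_cds.fasta", package = "poolmut", mustWork = TRUE)
}

#' Find maximal homopolymer runs
#'
#' Maximal mononucleotide repeats of length `>= min_len`, 1-based inclusive
#' coordinates. Semiconductor and pyrosequencing indel error concentrates in
#' and around such runs, which motivates both the indel noise cap and the
#' indel/homopolymer association summary.
#'
#' @param gene A `ref_gene` or a DNA character string.
#' @param min_len Minimum run length (>= 2).
#' @return Tibble with columns `start`, `length`, `base`, sorted by `start`.
#' @examples
#' find_homopolymers("AAATCCG", min_len = 2)
#' @export
find_homopolymers <- function(gene, min_len = 2) {
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  sequence <- if (inherits(gene, "ref_gene")) gene$sequence else toupper(gene)
  r <- rle(strsplit(sequence, "")[[1]])
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_len
  tibble(start = start[keep], length = r$lengths[keep], base = r$values[keep])
}

#' Find alternating C/G stretches
#'
#' Maximal stretches of strictly alternating C and G (e.g. `CGCGC`, `GCGCG`)
#' of total length `>= min_len`. Used to census short CpG-like tracts, which
#' are mutable targets (methylation-mediated deamination, bulky guanine
#' adducts). The "alternating C/G, length >= 5" rule is one reasonable
#' operationalisation of a CpG stretch; it is a parameterised choice, not a
#' community standard.
#'
#' @param gene A `ref_gene` or a DNA character string.
#' @param min_len Minimum stretch length (>= 2).
#' @return Tibble with columns `start`, `length`.
#' @examples
#' find_cpg_stretches("ATCGCGCAT", min_len = 5)
#' @export
find_cpg_stretches <- function(gene, min_len = 5) {
  if (min_len < 2) stop("min_len must be >= 2", call. = FALSE)
  sequence <- if (inherits(gene, "ref_gene")) gene$sequence else toupper(gene)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_cg <- chars %in% c("C", "G")
  # run continues while current is C/G and differs from the previous base
  starts <- integer(0); lengths <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!is_cg[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && is_cg[j + 1L] && chars[j + 1L] != chars[j]) j <- j + 1L
    if (j - i + 1L >= min_len) {
      starts <- c(starts, i); lengths <- c(lengths, j - i + 1L)
    }
    i <- j + 1L
  }
  tibble(start = starts, length = lengths)
}

#' Classify the protein-level impact of a single event
#'
#' Substitutions are translated through the standard codon table and
#' classified as `silent`, `missense`, or `nonsense`; indels are
#' `frameshift_indel` unless their length is a multiple of 3
#' (`inframe_indel`). Each event is classified independently against the
#' reference codon, matching per-event reporting in reporter-gene assays.
#'
#' @param gene A `ref_gene`.
#' @param position 1-based position of the event.
#' @param kind `"sub"`, `"ins"` or `"del"`.
#' @param detail Alternative base (sub), inserted sequence (ins), or deleted
#'   length in bp (del).
#' @return One of `"silent"`, `"missense"`, `"nonsense"`,
#'   `"frameshift_indel"`, `"inframe_indel"`.
#' @examples
#' g <- ref_gene("ATGGAATAA")
#' classify_impact(g, 5, "sub", "T")  # GAA -> GTA, missense
#' @export
classify_impact <- function(gene, position, kind, detail) {
  stopifnot(inherits(gene, "ref_gene"))
  cds_end <- gene$coding_offset +
    3L * ((gene$length - gene$coding_offset + 1L) %/% 3L) - 1L
  if (position < gene$coding_offset || position > cds_end) {
    stop("position ", position, " outside the coding region", call. = FALSE)
  }
  if (kind %in% c("ins", "del")) {
    len <- if (kind == "ins") nchar(as.character(detail)) else as.integer(detail)
    return(if (len %% 3L == 0L) "inframe_indel" else "frameshift_indel")
  }
  if (kind != "sub") stop("unknown event kind: ", kind, call. = FALSE)
  alt <- toupper(as.character(detail))
  off <- position - gene$coding_offset  # 0-based within CDS
  codon_start <- gene$coding_offset + 3L * (off %/% 3L)
  codon <- substr(gene$sequence, codon_start, codon_start + 2L)
  pos_in_codon <- off %% 3L + 1L
  if (substr(codon, pos_in_codon, pos_in_codon) == alt) {
    stop("alternative base equals the reference base at position ", position,
         call. = FALSE)
  }
  mutant <- codon
  substr(mutant, pos_in_codon, pos_in_codon) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[codon])
  aa_alt <- unname(code[mutant])
  if (aa_alt == aa_ref) "silent" else if (aa_alt == "*") "nonsense" else "missense"
}

#' Add protein impact and mutation class annotations to a call table
#'
#' @param calls Tibble of calls with `position`, `kind`, `detail`.
#' @param gene A `ref_gene`.
#' @return The input with `ref` (reference base), `class` (collapsed mutation
#'   class) and `impact` columns added.
#' @export
annotate_calls <- function(calls, gene) {
  assert_event_cols(calls)
  if (nrow(calls) == 0) {
    return(mutate(calls, ref = character(0), class = character(0),
                  impact = character(0)))
  }
  chars <- strsplit(gene$sequence, "")[[1]]
  calls |>
    mutate(
      ref = chars[.data$position],
      class = classify_mutation_class(.data$ref, .data$kind, .data$detail),
      impact = purrr::pmap_chr(
        list(.data$position, .data$kind, .data$detail),
        function(p, k, d) classify_impact(gene, p, k, d)
      )
    )
}
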