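# shared fixtures: tiny deterministic objects built in code

toy_gene_fixed <- function() {
  # 30 bp, starts with ATG, hand-chosen so positions are easy to reason about
  poolmut::ref_gene("ATGGAATACCTGAAATCCGGGCGCGCATAA", name = "toygene")
}

# a position_counts built directly from an event table
pc_fixture <- function(events, depth, library_id = "s1_A", L = NULL) {
  if (is.null(L)) L <- max(10, if (nrow(events)) max(events$position) else 10)
  poolmut::position_counts(events, rep(as.integer(depth), L), library_id)
}

# proportion tibble from bare vectors (one library)
props_fixture <- function(position, kind, detail, prop, depth = 10000,
                          library_id = "s1_A", gene_length = 100) {
  out <- tibble::tibble(
    library_id = library_id,
    sample_id = sub("_[AB]$", "", library_id),
    position = as.integer(position), kind = kind,
    detail = as.character(detail),
    depth = as.integer(depth), prop = prop, zero_depth = depth == 0
  )
  attr(out, "gene_length") <- gene_length
  out
}

# true-proportion tibble (as produced by subtract_noise) from bare vectors
true_props_fixture <- function(position, kind, detail, true_prop,
                               library_id = "s1_A", gene_length = 100) {
  out <- props_fixture(position, kind, detail, prop = true_prop,
                       library_id = library_id, gene_length = gene_length)
  out$false_prop <- 0
  out$true_prop <- true_prop
  out
}

# first-principles Pearson chi-squared statistic on a contingency table
pearson_chi2_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# brute-force protein impact oracle: translate full mutant CDS and diff
impact_oracle <- function(gene, position, alt) {
  seq <- gene$sequence
  substr(seq, position, position) <- alt
  code <- Biostrings::GENETIC_CODE
  codons <- function(s) {
    vapply(seq(1, nchar(s) - 2, by = 3),
           function(i) unname(code[substr(s, i, i + 2)]), character(1))
  }
  p0 <- codons(gene$sequence)
  p1 <- codons(seq)
  if (identical(p0, p1)) return("silent")
  changed <- which(p0 != p1)
  if (any(p1[changed] == "*")) "nonsense" else "missense"
}
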