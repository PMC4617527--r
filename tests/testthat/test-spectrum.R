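test_that("mutation classes collapse complementary strands", {
  expect_equal(classify_mutation_class("G", "sub", "T"), "GC>TA")
  expect_equal(classify_mutation_class("C", "sub", "A"), "GC>TA")
  expect_equal(classify_mutation_class("A", "sub", "G"), "AT>GC")
  expect_equal(classify_mutation_class("G", "sub", "A"), "GC>AT")
  expect_equal(classify_mutation_class("T", "ins", "T"), "insertion")
  expect_equal(classify_mutation_class("T", "del", "1"), "deletion")
  expect_equal(class_group(c("GC>AT", "AT>GC")), rep("transition", 2))
  expect_equal(class_group(c("GC>TA", "GC>CG", "AT>TA", "AT>CG")),
               rep("transversion", 4))
  expect_error(classify_mutation_class("G", "sub", "G"), "equals")
})

test_that("classification is involution-safe under complementation", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) {
    for (a in setdiff(names(comp), r)) {
      expect_equal(classify_mutation_class(r, "sub", a),
                   classify_mutation_class(comp[[r]], "sub", comp[[a]]))
    }
  }
  # all 12 directed changes land in the six substitution classes
  combos <- expand.grid(r = names(comp), a = names(comp),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$r != combos$a, ]
  cls <- classify_mutation_class(combos$r, "sub", combos$a)
  expect_setequal(unique(cls),
                  c("GC>AT", "GC>TA", "GC>CG", "AT>GC", "AT>TA", "AT>CG"))
  expect_equal(unname(table(cls)[unique(cls)]), rep(2L, 6),
               ignore_attr = TRUE)
})

test_that("build_spectrum weights independent vs total mutations correctly", {
  calls <- tibble::tibble(
    sample_id = "s1", position = c(10L, 20L), kind = "sub",
    detail = c("T", "T"), ref = c("G", "A"),
    class = c("GC>TA", "AT>TA"), adjusted_count = c(3L, 1L))
  sp_ind <- build_spectrum(calls, independent_only = TRUE)
  expect_equal(sp_ind$proportion[sp_ind$class == "GC>TA"], 0.5)
  sp_tot <- build_spectrum(calls, independent_only = FALSE)
  expect_equal(sp_tot$proportion[sp_tot$class == "GC>TA"], 0.75)
  expect_equal(sp_tot$proportion[sp_tot$class == "AT>TA"], 0.25)
  # proportions sum to one whenever mutations exist
  expect_equal(sum(sp_ind$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(sp_tot$proportion), 1, tolerance = 1e-12)
})

test_that("compare_spectra matches a first-principles Pearson statistic", {
  mk <- function(counts) {
    tb <- tibble::tibble(
      class = poolmut:::MUTATION_CLASSES[seq_along(counts)],
      count = as.integer(counts),
      proportion = counts / sum(counts))
    structure(tb, n_mutations = sum(counts),
              class = c("mut_spectrum", class(tb)))
  }
  a <- mk(c(10, 0)); b <- mk(c(0, 10))
  res <- compare_spectra(a, b)
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)

  ident <- compare_spectra(mk(c(30, 30, 30)), mk(c(30, 30, 30)))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)

  # random tables vs the oracle
  set.seed(7)
  for (i in 1:20) {
    ca <- rpois(5, 40) + 1; cb <- rpois(5, 40) + 1
    res <- compare_spectra(mk(ca), mk(cb))
    expect_equal(res$chi2, pearson_chi2_oracle(rbind(ca, cb)),
                 tolerance = 1e-10)
    if (!res$monte_carlo) {
      expect_equal(res$p,
                   stats::pchisq(res$chi2, res$df, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
  expect_error(compare_spectra(mk(c(0, 0)), mk(c(1, 1))), "empty")
})

test_that("Monte-Carlo p-values are deterministic and in range", {
  mk <- function(counts) {
    tb <- tibble::tibble(class = poolmut:::MUTATION_CLASSES[seq_along(counts)],
                         count = as.integer(counts),
                         proportion = counts / sum(counts))
    structure(tb, n_mutations = sum(counts),
              class = c("mut_spectrum", class(tb)))
  }
  a <- mk(c(3, 1, 0, 2)); b <- mk(c(1, 4, 2, 0))
  r1 <- compare_spectra(a, b, B = 2000)
  r2 <- compare_spectra(a, b, B = 2000)
  expect_true(r1$monte_carlo)
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 0); expect_lte(r1$p, 1)
})

test_that("per-class comparison applies the multiplicity correction", {
  mk <- function(counts) {
    tb <- tibble::tibble(class = poolmut:::MUTATION_CLASSES,
                         count = as.integer(counts),
                         proportion = counts / sum(counts))
    structure(tb, n_mutations = sum(counts),
              class = c("mut_spectrum", class(tb)))
  }
  a <- mk(c(50, 20, 10, 10, 5, 5, 10, 20))
  b <- mk(c(10, 80, 15, 5, 5, 5, 10, 30))
  res <- compare_spectra_by_class(a, b, method = "holm", B = 2000)
  expect_equal(nrow(res), 8)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("compare_mutant_frequency estimates the rate ratio by Poisson regression", {
  pools <- tibble::tibble(
    group = rep(c("control", "treated"), each = 4),
    mutant_pfu = c(10, 12, 9, 11, 100, 120, 90, 110),
    total_pfu = rep(1e6, 8))
  res <- compare_mutant_frequency(pools)
  expect_equal(res$method, "poisson-regression")
  expect_equal(res$rate_ratio, 10, tolerance = 0.01)
  expect_lt(res$p, 0.001)

  # identical rates -> ratio ~ 1
  same <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         mutant_pfu = rep(50, 6), total_pfu = rep(1e6, 6))
  expect_equal(compare_mutant_frequency(same)$rate_ratio, 1, tolerance = 1e-6)

  # single animal per group still runs, flagged
  single <- tibble::tibble(group = c("a", "b"), mutant_pfu = c(5, 50),
                           total_pfu = 1e6)
  res1 <- compare_mutant_frequency(single)
  expect_match(res1$flag, "single-animal")

  # all-zero group falls back to the exact test
  zero <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         mutant_pfu = c(0, 0, 0, 5, 6, 7),
                         total_pfu = rep(1e6, 6))
  resz <- compare_mutant_frequency(zero)
  expect_equal(resz$method, "exact")
})

test_that("Poisson rate ratio recovers the generating ratio over seeds", {
  ratios <- purrr::map_dbl(1:20, function(seed) {
    set.seed(seed)
    pools <- tibble::tibble(
      group = rep(c("control", "treated"), each = 6),
      total_pfu = round(runif(12, 3e5, 8e5)))
    pools$mutant_pfu <- rpois(12, pools$total_pfu *
                                ifelse(pools$group == "treated", 80e-5, 1e-5))
    compare_mutant_frequency(pools)$rate_ratio
  })
  # control counts are small (~5/animal), so per-seed ratios scatter with
  # SE(log RR) ~ 0.18; the mean must sit on the generating ratio
  expect_equal(mean(ratios), 80, tolerance = 0.1)
  expect_true(all(abs(log(ratios / 80)) < 3 * 0.19))
})

test_that("find_hotspots counts per-sample-distinct mutations across samples", {
  calls <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("s", 1:5), position = 100L,
                   kind = "sub", detail = "T", raw_count = 1L),
    tibble::tibble(sample_id = "s1", position = 200L, kind = "sub",
                   detail = "A", raw_count = 5L))
  hs <- find_hotspots(calls, min_independent = 4)
  expect_equal(hs$position, 100L)       # 5 independent > 4
  expect_equal(hs$n_independent, 5L)
  # 5 copies in one animal = 1 independent: not a hotspot
  expect_false(200L %in% hs$position)
  # min 0 returns every mutated position once
  all_pos <- find_hotspots(calls, min_independent = 0)
  expect_setequal(all_pos$position, c(100L, 200L))
  expect_equal(nrow(find_hotspots(calls[0, ], 4)), 0)
})

test_that("homopolymer_association counts indels inside or adjacent to runs", {
  runs <- tibble::tibble(start = c(10L, 50L), length = c(3L, 5L),
                         base = c("A", "G"))
  calls <- tibble::tibble(
    sample_id = "s1",
    position = c(11L, 9L, 30L, 54L, 12L),
    kind = c("del", "del", "del", "ins", "sub"),
    detail = c("1", "1", "1", "G", "T"))
  res <- homopolymer_association(calls, runs, min_run_len = 3, adjacency_bp = 1)
  del <- res[res$kind == "del", ]
  expect_equal(del$n_total, 3L)
  expect_equal(del$n_inside_or_adjacent, 2L)  # inside (11) and adjacent (9)
  ins <- res[res$kind == "ins", ]
  expect_equal(ins$n_inside_or_adjacent, 1L)  # 54 inside the 50-54 run
  expect_false("sub" %in% res$kind)
})

test_that("power_simulation behaves at its boundaries and on realistic spectra", {
  classes <- rep(poolmut:::MUTATION_CLASSES[1:6], times = c(50, 220, 50, 10, 20, 10))
  # k = n: the subsample is the population, power 1
  res <- power_simulation(classes, k = length(classes), n_iter = 100, seed = 3)
  expect_equal(res$power, 1)
  expect_error(power_simulation(classes, k = length(classes) + 1), "exceeds")
  expect_error(power_simulation(classes, k = 10, n_iter = 10), "n_iter")
  # determinism under a fixed seed
  r1 <- power_simulation(classes, k = 40, n_iter = 100, seed = 5, B = 500)
  r2 <- power_simulation(classes, k = 40, n_iter = 100, seed = 5, B = 500)
  expect_identical(r1$power, r2$power)
})

test_that("100 sampled mutants give high power to recover a 350-mutant spectrum", {
  set.seed(2)
  classes <- sample(poolmut:::MUTATION_CLASSES, 350, replace = TRUE,
                    prob = class_probs_bap())
  res <- power_simulation(classes, k = 100, n_iter = 1000, alpha = 0.05,
                          seed = 9, B = 500)
  expect_gte(res$power, 0.7)
})
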