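test_that("calling_threshold scales the expected single-copy proportion", {
  expect_equal(calling_threshold(100, 1.0), 0.01)
  expect_equal(calling_threshold(100, 0.75), 0.0075)
  expect_equal(calling_threshold(100, 0.5), 0.005)
  expect_equal(calling_threshold(1, 1.0), 1.0)
  expect_equal(calling_threshold(200, 0.5), 0.0025)
  expect_error(calling_threshold(0), "positive")
  expect_error(calling_threshold(100, 0.9), "stringency")
})

test_that("call_mutations enforces threshold, concordance, mask and copy rounding", {
  r1 <- true_props_fixture(c(25L, 40L, 60L, 70L),
                           c("sub", "sub", "sub", "del"),
                           c("A", "T", "G", "1"),
                           c(0.012, 0.10, 0.020, 0.05))
  r2 <- true_props_fixture(c(25L, 40L, 60L, 70L),
                           c("sub", "sub", "sub", "del"),
                           c("A", "T", "G", "1"),
                           c(0.011, 0.10, 0.004, 0.05),
                           library_id = "s1_B")
  mask <- tibble::tibble(position = 70L, kind = "del", detail = "1")
  calls <- call_mutations(r1, r2, n_plaques = 100, stringency = 1.0,
                          mask = mask)
  # (0.012, 0.011): called, round(0.0115/0.01) = 1
  expect_equal(calls$raw_count[calls$position == 25], 1L)
  # (0.10, 0.10): ten copies among 100 plaques
  expect_equal(calls$raw_count[calls$position == 40], 10L)
  # (0.020, 0.004): fails replicate concordance
  expect_false(60L %in% calls$position)
  # masked indel: not called despite clearing the threshold in both reps
  expect_false(70L %in% calls$position)
  # the discordant event is reported in the companion diagnostic
  disc <- discordant_events(r1, r2, n_plaques = 100)
  expect_equal(disc$position, 60L)
})

test_that("raw copy estimation uses the stringent denominator at every stringency", {
  r1 <- true_props_fixture(10L, "sub", "A", 0.10)
  r2 <- true_props_fixture(10L, "sub", "A", 0.10, library_id = "s1_B")
  for (s in c(1.0, 0.75, 0.5)) {
    calls <- call_mutations(r1, r2, n_plaques = 100, stringency = s)
    expect_equal(calls$raw_count, 10L)
    expect_equal(calls$threshold_used, s * 0.01)
  }
})

test_that("lowering stringency never removes a call", {
  set.seed(14)
  n <- 40
  mk <- function(lib) true_props_fixture(
    sample.int(500, n), "sub", sample(c("A", "C", "G", "T"), n, replace = TRUE),
    runif(n, 0, 0.03), library_id = lib, gene_length = 500)
  r1 <- mk("s1_A"); r2 <- mk("s1_B")
  r2[c("position", "kind", "detail")] <- r1[c("position", "kind", "detail")]
  key <- function(d) paste(d$position, d$kind, d$detail)
  strict <- call_mutations(r1, r2, n_plaques = 100, stringency = 1.0)
  medium <- call_mutations(r1, r2, n_plaques = 100, stringency = 0.75)
  loose <- call_mutations(r1, r2, n_plaques = 100, stringency = 0.5)
  expect_true(all(key(strict) %in% key(medium)))
  expect_true(all(key(medium) %in% key(loose)))
})

test_that("tabulate_mutations separates independent from recurrent copies", {
  calls <- tibble::tibble(sample_id = "s1", position = 25L, kind = "sub",
                          detail = "A", raw_count = 5L)
  tab <- tabulate_mutations(calls)
  expect_equal(tab$independent, 1L)
  expect_equal(tab$total, 5L)
  expect_equal(tab$recurrent, 4L)

  calls3 <- tibble::tibble(sample_id = "s1", position = c(1L, 2L, 3L),
                           kind = "sub", detail = "A", raw_count = 1L)
  tab3 <- tabulate_mutations(calls3)
  expect_equal(tab3$independent, 3L)
  expect_equal(tab3$total, 3L)

  empty <- tabulate_mutations(calls3[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("noise-only pools yield zero calls at the stringent threshold across seeds", {
  gene <- random_toy_gene(300, seed = 2)
  for (seed in 1:8) {
    cfg <- sim_config(gene = gene, n_samples = 4, n_plaques = 100,
                      depth = 20000, pcr_n_events = 5, seed = seed)
    sim <- simulate_pools(cfg, wild_type = TRUE)
    ss <- sim$sample_sheet
    ss$mutant_pfu <- 0L; ss$total_pfu <- 1L
    rep <- run_pipeline(ss, sim$samples, gene, stringency = 1.0,
                        model = clonality_model())
    expect_equal(nrow(rep$calls), 0)
  }
})

test_that("spiked mutations well above threshold are recovered reliably", {
  # property of the calling step given a correct background profile: events
  # at true proportion >= 1.5x threshold and depth >= 1e4 are recovered
  gene <- random_toy_gene(300, seed = 2)
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    # 20 plaques -> threshold 0.05; clones at copies >= 2 sit at >= 2x
    cfg <- sim_config(gene = gene, n_samples = 2, n_plaques = 20,
                      clonal_fraction = 0.5, depth = 10000,
                      pcr_n_events = 0, hotspot_weight = 1, seed = seed)
    sim <- simulate_pools(cfg)
    profile <- structure(
      dplyr::rename(sim$noise_truth, false_prop = rate),
      indel_cap = max(sim$noise_truth$rate[sim$noise_truth$kind == "sub"]),
      class = c("noise_profile", class(sim$noise_truth)))
    for (sid in names(sim$samples)) {
      reps <- purrr::map(sim$samples[[sid]],
                         ~ subtract_noise(to_proportions(.x), profile))
      calls <- call_mutations(reps[[1]], reps[[2]], n_plaques = 20,
                              stringency = 1.0, mask = indel_mask(profile))
      spiked <- dplyr::filter(sim$truth, sample_id == sid, copies >= 2,
                              !paste(position, kind, detail) %in%
                                paste(indel_mask(profile)$position,
                                      indel_mask(profile)$kind,
                                      indel_mask(profile)$detail))
      if (nrow(spiked) == 0) next
      called <- paste(calls$position, calls$kind, calls$detail)
      hits <- hits + sum(paste(spiked$position, spiked$kind, spiked$detail)
                         %in% called)
      total <- total + nrow(spiked)
    }
  }
  expect_gt(total, 20)
  expect_gte(hits / total, 0.95)
})
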