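test_that("noiseless single-plaque pool puts every read on the mutation", {
  gene <- random_toy_gene(150, seed = 6)
  cfg <- sim_config(gene = gene, n_samples = 1, n_plaques = 1,
                    clonal_fraction = 0, depth = 10000,
                    sub_noise_range = c(0, 0), pcr_n_events = 0, seed = 13)
  sim <- simulate_pools(cfg)
  expect_equal(nrow(sim$truth), 1)
  for (pc in sim$samples[[1]]) {
    ev <- pc$events
    expect_equal(nrow(ev), 1)
    expect_equal(ev$count, 10000L)
    expect_equal(ev$position, sim$truth$position)
    expect_equal(ev$detail, sim$truth$detail)
  }
})

test_that("clonal_fraction 0 gives all-distinct single-copy truth summing to n_plaques", {
  cfg <- sim_config(gene = random_toy_gene(300, seed = 2), n_samples = 3,
                    n_plaques = 40, clonal_fraction = 0, depth = 1000,
                    seed = 4)
  sim <- simulate_pools(cfg)
  truth <- dplyr::filter(sim$truth, driver)
  expect_true(all(truth$copies == 1))
  per_sample <- dplyr::count(truth, sample_id, wt = copies)
  expect_true(all(per_sample$n == 40))

  # with clonal expansion the copies still sum to the plaque count
  cfg2 <- sim_config(gene = random_toy_gene(300, seed = 2), n_samples = 3,
                     n_plaques = 40, clonal_fraction = 0.4, depth = 1000,
                     seed = 4)
  truth2 <- dplyr::filter(simulate_pools(cfg2)$truth, driver)
  per_sample2 <- dplyr::count(truth2, sample_id, wt = copies)
  expect_true(all(per_sample2$n == 40))
  expect_gt(max(truth2$copies), 1)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(gene = random_toy_gene(200, seed = 3), n_samples = 2,
                    n_plaques = 30, depth = 2000, seed = 77)
  s1 <- simulate_pools(cfg)
  s2 <- simulate_pools(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$noise_truth, s2$noise_truth)
  for (sid in names(s1$samples)) {
    for (r in 1:2) {
      expect_identical(s1$samples[[sid]][[r]]$events,
                       s2$samples[[sid]][[r]]$events)
    }
  }
})

test_that("event proportions track copies/n_plaques plus noise within binomial error", {
  gene <- random_toy_gene(200, seed = 9)
  depth <- 50000
  cfg <- sim_config(gene = gene, n_samples = 2, n_plaques = 25,
                    clonal_fraction = 0.3, depth = depth, pcr_n_events = 0,
                    seed = 19)
  sim <- simulate_pools(cfg)
  noise_key <- paste(sim$noise_truth$position, sim$noise_truth$kind,
                     sim$noise_truth$detail)
  for (sid in names(sim$samples)) {
    truth <- dplyr::filter(sim$truth, sample_id == sid)
    pr <- to_proportions(sim$samples[[sid]][[1]])
    joined <- dplyr::left_join(
      truth, pr, by = c("position", "kind", "detail", "sample_id"))
    rate <- sim$noise_truth$rate[match(
      paste(truth$position, truth$kind, truth$detail), noise_key)]
    rate[is.na(rate)] <- 0
    expected <- truth$copies / 25 + rate
    sd3 <- 3 * sqrt(expected * (1 - expected) / depth)
    obs <- dplyr::coalesce(joined$prop, 0)
    expect_true(all(abs(obs - expected) <= sd3 + 1e-9))
  }
})

test_that("the noise field is shared across libraries (binomial dispersion)", {
  gene <- random_toy_gene(200, seed = 10)
  depth <- 20000
  cfg <- sim_config(gene = gene, n_samples = 4, n_plaques = 20, depth = depth,
                    pcr_n_events = 0, seed = 23)
  sim <- simulate_pools(cfg, wild_type = TRUE)
  props <- purrr::map(unlist(sim$samples, recursive = FALSE), to_proportions)
  wide <- dplyr::bind_rows(props) |>
    dplyr::group_by(position, kind, detail) |>
    dplyr::summarise(m = sum(prop) / 8, v = sum((prop - sum(prop) / 8)^2) / 7,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(m * depth >= 20)
  # variance of binomial proportions around a shared rate: E[v] = m(1-m)/depth;
  # the mean dispersion ratio across events concentrates near 1
  ratio <- wide$v / (wide$m * (1 - wide$m) / depth)
  expect_gt(nrow(wide), 50)
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("elevated indel noise sits at long homopolymers", {
  gene <- ref_gene(paste0(strrep("ACGT", 20), "AAAAA", strrep("TGCA", 20),
                          "GGGG", strrep("CATG", 10)))
  cfg <- sim_config(gene = gene, n_samples = 3, n_plaques = 20, depth = 1000,
                    indel_noise_multiplier = 50, homopolymer_min_len = 4,
                    seed = 31)
  noise <- poolmut:::build_noise_field(cfg)
  runs <- find_homopolymers(gene, min_len = 4)
  hp <- unlist(purrr::map2(runs$start - 1, runs$start + runs$length, seq))
  indels <- dplyr::filter(noise, kind %in% c("ins", "del"))
  inside <- dplyr::filter(indels, position %in% hp)
  outside <- dplyr::filter(indels, !position %in% hp)
  expect_gt(mean(inside$rate), 10 * mean(outside$rate))
  expect_true(all(noise$rate <= cfg$indel_noise_max))
})

test_that("hitchhiker mutations are silent and marked non-driver", {
  cfg <- sim_config(gene = random_toy_gene(300, seed = 12), n_samples = 2,
                    n_plaques = 60, hitchhiker_rate = 0.2, depth = 1000,
                    seed = 41)
  sim <- simulate_pools(cfg)
  hh <- dplyr::filter(sim$truth, !driver)
  expect_gt(nrow(hh), 0)
  for (i in seq_len(nrow(hh))) {
    expect_equal(classify_impact(cfg$gene, hh$position[i], hh$kind[i],
                                 hh$detail[i]), "silent")
  }
  # drivers alone still account for every plaque
  drv <- dplyr::count(dplyr::filter(sim$truth, driver), sample_id, wt = copies)
  expect_true(all(drv$n == 60))
})
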