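test_that("without recombination the whole chromosome is retained forever", {
  sizes <- cb4_chromosomes(map_length = 0)
  traj <- simulate_backcross(backcross_config("I", 5e6, chrom_sizes = sizes,
                                              generations = 10, seed = 4))
  expect_true(all(traj$start == 0))
  expect_true(all(traj$end == sizes$length[1]))
})

test_that("backcross trajectories are nested, shrink monotonically and keep the marker", {
  for (seed in 1:30) {
    cfg <- backcross_config("X", 10e6, generations = 15, seed = seed)
    traj <- simulate_backcross(cfg)
    expect_true(all(diff(traj$start) >= 0))
    expect_true(all(diff(traj$end) <= 0))
    expect_true(all(diff(traj$size_bp) <= 0))
    expect_true(all(traj$start < 10e6 & traj$end > 10e6))
    expect_lte(traj$size_bp[traj$generation == 15],
               traj$size_bp[traj$generation == 7])
  }
})

test_that("recombination suppression keeps the suppressed region intact", {
  supp <- tibble::tibble(start = 5e6, end = 15e6, multiplier = 0)
  cfg <- backcross_config("X", 10e6, generations = 15, suppressors = supp,
                          seed = 8)
  traj <- simulate_backcross(cfg)
  final <- traj[traj$generation == 15, ]
  expect_lte(final$start, 5e6)
  expect_gte(final$end, 15e6)
})

test_that("backcross simulation is deterministic under a fixed seed", {
  cfg <- backcross_config("II", 8e6, seed = 123)
  expect_identical(simulate_backcross(cfg), simulate_backcross(cfg))
})

test_that("planted recessive embryonic lethality raises Emb by the homozygote fraction", {
  model <- viability_model(
    survival = tibble::tibble(genotype = "G/G", sex = "both", survival = 0,
                              stage = "emb"))
  rec <- simulate_progeny_counts("G/+", "G/+", model = model, n = 20000,
                                 emb_baseline = 0.10, seed = 17)
  observed <- rec$unhatched / rec$eggs
  # expected: 25% homozygote death plus baseline on the survivors
  expected <- 0.25 + 0.75 * 0.10
  se <- sqrt(expected * (1 - expected) / rec$eggs)
  expect_lte(abs(observed - expected), 3 * se)
  expect_error(simulate_progeny_counts("G/+", "G/+", n = 0), "positive")
})

test_that("progeny count structure respects its invariants", {
  rec <- simulate_progeny_counts("G/+", "+/0", linkage = "x", n = 500,
                                 replicates = 4, emb_baseline = 0.1,
                                 lva_baseline = 0.14, seed = 31)
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$unhatched <= rec$eggs))
  expect_true(all(rec$adults <= rec$l1))
  expect_true(all(rec$males_gfp + rec$males_nongfp +
                    rec$females_gfp + rec$females_nongfp == rec$adults))
})

test_that("segregation-distortion perturbation skews the conceived sex ratio", {
  rec <- simulate_progeny_counts("G/+", "G/+", n = 20000,
                                 male_x_transmission = 0.8, seed = 41)
  males <- rec$males_gfp + rec$males_nongfp
  expect_lt(males / rec$adults, 0.3)
})

test_that("genotype matrices round-trip and planted assembly errors are recovered", {
  panel <- toy_panel(15, chrom = "X", spacing = 1.4e6)
  truth <- tibble::tibble(strain = "s1", chrom = "X", start = 4e6, end = 12e6)
  clean <- simulate_genotype_matrix(truth, panel, seed = 5)
  got <- call_boundaries(clean[, c("marker", "call")], panel, cb4_chromosomes())
  expect_lte(got$outer_start, 4e6)
  expect_gte(got$outer_end, 12e6)
  expect_gte(got$inner_start, 4e6)
  expect_lte(got$inner_end, 12e6)

  corrupted <- simulate_genotype_matrix(truth, panel,
                                        assembly_errors = "m6", seed = 5)
  exc <- flag_assembly_errors(corrupted[, c("marker", "call")], panel)
  expect_equal(exc$marker, "m6")

  expect_identical(simulate_genotype_matrix(truth, panel, seed = 9),
                   simulate_genotype_matrix(truth, panel, seed = 9))
  expect_error(simulate_genotype_matrix(truth, panel, assembly_errors = "zz"),
               "not in panel")
})

test_that("noise-free coverage simulation is an exact step function", {
  truth <- gintervals("V", 1e6, 3e6)
  tr <- simulate_coverage(truth, chrom_length = 5e6, baseline_depth = 10,
                          fold = 5.5, sigma = 0)
  expect_equal(sort(unique(tr$depth)), c(10, 55))
  inside <- tr$start >= 1e6 & tr$end <= 3e6
  expect_true(all(tr$depth[inside] == 55))
  # a whole-chromosome plant leaves no flanking contrast: nothing called
  whole <- simulate_coverage(gintervals("V", 0, 5e6), chrom_length = 5e6,
                             sigma = 0)
  expect_equal(nrow(call_coverage_introgression(whole)), 0)
})

test_that("a simulated dataset carries planted truth through to classification", {
  loci <- tibble::tibble(chrom = "X", start = 5e6, end = 16e6,
                         effect = "male_inviable", penetrance = 1,
                         dominance = "recessive")
  sim <- simulate_hi_dataset(hi_model(loci), n_lines = 6, chroms = "X",
                             seed = 55)
  expect_equal(nrow(sim$lines), 6)
  expect_true(all(c("truth_male_inviable", "male_cross_progeny") %in%
                    names(sim$lines)))
  flags <- classify_dataset(sim)
  covered <- sim$lines$strain[sim$lines$truth_male_inviable]
  expect_gt(length(covered), 0)
  inv <- flags[flags$flag == "male_inviable" & flags$strain %in% covered, ]
  expect_true(all(inv$value))
  # determinism under seed
  sim2 <- simulate_hi_dataset(hi_model(loci), n_lines = 6, chroms = "X",
                              seed = 55)
  expect_identical(sim$lines, sim2$lines)
  expect_identical(sim$phenotypes, sim2$phenotypes)
})
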