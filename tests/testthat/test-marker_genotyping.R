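test_that("boundary calling applies the flanking-negative rule", {
  panel <- toy_panel(7)
  calls <- tibble::tibble(marker = paste0("m", 1:7),
                          call = c("-", "-", "+", "+", "+", "-", "-"))
  got <- call_boundaries(calls, panel, cb4_chromosomes())
  expect_equal(got$inner_start, 3e6)
  expect_equal(got$inner_end, 5e6)
  expect_equal(got$outer_start, 2e6)
  expect_equal(got$outer_end, 6e6)
  expect_equal(got$size_bp, 4e6)
  expect_equal(nrow(got$exceptions[[1]]), 0)
})

test_that("an isolated contradicting call is treated as an exception, not a boundary", {
  panel <- toy_panel(7)
  calls <- tibble::tibble(marker = paste0("m", 1:7),
                          call = c("-", "+", "+", "-", "+", "+", "-"))
  got <- call_boundaries(calls, panel, cb4_chromosomes())
  expect_equal(nrow(got), 1)
  expect_equal(c(got$inner_start, got$inner_end), c(2e6, 6e6))
  expect_equal(c(got$outer_start, got$outer_end), c(1e6, 7e6))
  expect_equal(got$exceptions[[1]]$marker, "m4")

  # mirror case: "+" embedded in a "-" run is flagged too
  mirror <- tibble::tibble(marker = paste0("m", 1:7),
                           call = c("-", "-", "+", "-", "-", "+", "+"))
  exc <- flag_assembly_errors(mirror, panel)
  expect_true("m3" %in% exc$marker)

  # two adjacent contradictions exceed the default exception run length:
  # reported as a second segment with a warning instead
  two <- tibble::tibble(marker = paste0("m", 1:9),
                        call = c("-", "+", "+", "-", "-", "+", "+", "+", "-"))
  expect_equal(nrow(flag_assembly_errors(two, toy_panel(9))), 0)
  expect_warning(seg <- call_boundaries(two, toy_panel(9), cb4_chromosomes()),
                 "disjoint")
  expect_equal(nrow(seg), 2)
})

test_that("all-negative strains and unknown markers are rejected", {
  panel <- toy_panel(5)
  allneg <- tibble::tibble(marker = paste0("m", 1:5), call = rep("-", 5))
  expect_error(call_boundaries(allneg, panel, cb4_chromosomes()),
               "no introgression detected")
  stray <- tibble::tibble(marker = c("m1", "mX"), call = c("+", "+"))
  expect_error(call_boundaries(stray, panel, cb4_chromosomes()),
               "absent from panel")
})

test_that("a terminal '+' run extends the outer boundary to the chromosome end", {
  panel <- toy_panel(5)
  calls <- tibble::tibble(marker = paste0("m", 1:5),
                          call = c("+", "+", "-", "-", "-"))
  got <- call_boundaries(calls, panel, cb4_chromosomes())
  expect_equal(got$outer_start, 0)
  expect_equal(got$outer_end, 3e6)
  right <- tibble::tibble(marker = paste0("m", 1:5),
                          call = c("-", "-", "-", "+", "+"))
  got2 <- call_boundaries(right, panel, cb4_chromosomes())
  expect_equal(got2$outer_end, cb4_chromosomes()$length[1])
})

test_that("NA calls are transparent: skipped for runs, never exceptions", {
  panel <- toy_panel(7)
  calls <- tibble::tibble(marker = paste0("m", 1:7),
                          call = c("-", NA, "+", "+", NA, "+", "-"))
  got <- call_boundaries(calls, panel, cb4_chromosomes())
  expect_equal(nrow(got), 1)
  expect_equal(c(got$inner_start, got$inner_end), c(3e6, 6e6))
  expect_equal(c(got$outer_start, got$outer_end), c(1e6, 7e6))
  expect_equal(nrow(got$exceptions[[1]]), 0)
})

test_that("round trip on error-free simulated matrices: inner within truth within outer", {
  set.seed(101)
  sizes <- cb4_chromosomes()
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    panel <- toy_panel(n, chrom = "V", spacing = floor(19.4e6 / (n + 1)))
    mids <- panel$mid
    lo <- runif(1, 0, 17e6); hi <- lo + runif(1, 1e6, 19.4e6 - lo)
    # the consensus rule needs at least two concordant positive markers: a
    # single positive is indistinguishable from an assembly error
    if (sum(mids >= lo & mids < hi) < 2) next
    geno <- simulate_genotype_matrix(
      tibble::tibble(strain = "s", chrom = "V", start = lo, end = hi), panel)
    got <- call_boundaries(geno[, c("marker", "call")], panel, sizes,
                           strain = "s")
    expect_equal(nrow(got), 1)
    expect_gte(lo, got$outer_start)
    expect_lte(hi, got$outer_end)
    expect_lte(got$outer_start, got$inner_start)
    expect_gte(got$outer_end, got$inner_end)
    expect_gte(got$inner_start, lo - 1)
    expect_lte(got$inner_end, hi + 1)
  }
})

test_that("outer interval shrinks (never grows) as the panel densifies", {
  set.seed(202)
  sizes <- cb4_chromosomes()
  truth <- tibble::tibble(strain = "s", chrom = "I", start = 4e6, end = 9e6)
  prev_size <- Inf
  for (n in c(5, 10, 20, 40)) {
    panel <- toy_panel(n, chrom = "I", spacing = floor(15e6 / (n + 1)))
    geno <- simulate_genotype_matrix(truth, panel)
    got <- call_boundaries(geno[, c("marker", "call")], panel, sizes)
    expect_lte(got$size_bp, prev_size)
    prev_size <- got$size_bp
  }
})

test_that("callset concordance matches hand-computed Jaccard and offsets", {
  same <- compare_callsets(gintervals("V", 0, 7.75e6), gintervals("V", 0, 7.75e6))
  expect_equal(same$jaccard, 1)
  expect_equal(c(same$left_offset_bp, same$right_offset_bp), c(0, 0))
  # PCR boundary of 7.75 Mb vs a deeper-coverage reference of 7.10 Mb
  pcr <- compare_callsets(gintervals("V", 0, 7.75e6), gintervals("V", 0, 7.10e6))
  expect_equal(pcr$jaccard, 7.10 / 7.75, tolerance = 1e-12)
  expect_equal(pcr$right_offset_bp, 0.65e6)
  disj <- compare_callsets(gintervals("V", 0, 1e6), gintervals("V", 2e6, 3e6))
  expect_equal(disj$jaccard, 0)
  expect_warning(cross <- compare_callsets(gintervals("I", 0, 1e6),
                                           gintervals("II", 0, 1e6)),
                 "different chromosomes")
  expect_equal(cross$jaccard, 0)
})
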