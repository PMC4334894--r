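ann <- function(strain, chrom, start, end, label, metric = NA_real_) {
  tibble::tibble(strain = strain, chrom = chrom, start = start, end = end,
                 label = label, metric = metric)
}

test_that("contrasting an inviable with a sterile introgression localizes a viability interval", {
  a <- ann("sev", "X", 14.00e6, 15.11e6, "male_inviable")
  b <- ann("mild", "X", 14.00e6, 14.62e6, "male_sterile")
  got <- refine_interval(a, b)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(14.62e6, 15.11e6))
  expect_equal(got$end - got$start, 490000)
  expect_equal(got$class, "male_viability")
})

test_that("identical and two-sided contrasts behave as set algebra", {
  a <- ann("a", "I", 2e6, 8e6, "male_sterile")
  expect_warning(empty <- refine_interval(a, ann("b", "I", 2e6, 8e6, "male_fertile")),
                 "identical")
  expect_equal(nrow(empty), 0)
  two <- refine_interval(a, ann("b", "I", 4e6, 6e6, "male_fertile"))
  expect_equal(nrow(two), 2)
  expect_equal(two$start, c(2e6, 6e6))
  expect_equal(two$end, c(4e6, 8e6))
  expect_error(refine_interval(ann("a", "I", 0, 1e6, "male_inviable"),
                               ann("b", "I", 2e6, 3e6, "male_sterile")),
               "uninformative")
  expect_error(refine_interval(ann("a", "I", 0, 3e6, "male_fertile"),
                               ann("b", "I", 0, 2e6, "male_sterile")),
               "more severe")
})

test_that("refined candidates never overlap the milder interval and stay inside the severe one", {
  set.seed(31)
  for (rep in 1:30) {
    s1 <- sample(0:5000, 1); e1 <- s1 + sample(500:4000, 1)
    s2 <- sample(max(0, s1 - 1000):(e1 - 1), 1)
    e2 <- s2 + sample(200:4000, 1)
    if (min(e1, e2) <= max(s1, s2)) next
    a <- ann("a", "toy", s1, e1, "male_inviable")
    b <- ann("b", "toy", s2, e2, "male_sterile")
    got <- suppressWarnings(refine_interval(a, b))
    want <- base_setdiff(a, b, 10000)
    have <- unlist(purrr::map2(got$start, got$end, function(s, e) seq(s, e - 1)))
    if (nrow(got) == 0) have <- integer(0)
    expect_equal(sort(have), sort(want))
  }
})

test_that("a sharply more severe nested introgression implicates a suppressor", {
  sub <- ann("inner", "X", 17e6, 19.34e6, "male_sterile", metric = 4.9)
  sup <- ann("outer", "X", 15.5e6, 20.75e6, "male_sterile", metric = 51.1)
  got <- detect_suppressor(sub, sup)
  expect_gt(nrow(got), 0)
  expect_equal(got$class[1], "suppressor")
  # the second metric (overall GFP progeny) also clears the margin
  sub2 <- dplyr::mutate(sub, metric = 3.4)
  sup2 <- dplyr::mutate(sup, metric = 37.6)
  expect_gt(nrow(detect_suppressor(sub2, sup2)), 0)
  # equal severities: nothing
  expect_equal(nrow(detect_suppressor(dplyr::mutate(sub, metric = 40),
                                      dplyr::mutate(sup, metric = 40))), 0)
  # asymmetric: swapping roles gives containment failure
  expect_error(detect_suppressor(sup, sub), "contained")
  # swapped severities (superset more severe) yields none
  expect_equal(nrow(detect_suppressor(dplyr::mutate(sub, metric = 51.1),
                                      dplyr::mutate(sup, metric = 4.9))), 0)
})

test_that("the minimal locus map lower-bounds planted locus counts", {
  # two disjoint male-sterile loci isolated by fertile partners
  set <- dplyr::bind_rows(
    ann("s1", "X", 0e6, 3e6, "male_sterile"),
    ann("f1", "X", 2e6, 3e6, "male_fertile"),
    ann("s2", "X", 7e6, 10e6, "male_sterile"),
    ann("f2", "X", 9e6, 10e6, "male_fertile"))
  got <- minimal_locus_map(set)
  bound <- got$locus_count_lower_bound
  expect_equal(bound$n[bound$class == "male_fertility"], 2L)
  # single introgression: empty map
  single <- minimal_locus_map(ann("s", "X", 0, 1e6, "male_sterile"))
  expect_equal(nrow(single$candidates), 0)
  expect_equal(nrow(single$loci), 0)
  # inviable-vs-sterile contrast pattern gives one male-viability candidate
  pair <- dplyr::bind_rows(
    ann("inv", "X", 14.00e6, 15.11e6, "male_inviable"),
    ann("ste", "X", 14.00e6, 14.62e6, "male_sterile"))
  m <- minimal_locus_map(pair)
  expect_equal(nrow(m$loci[m$loci$class == "male_viability", ]), 1)
  expect_equal(m$locus_count_lower_bound$n[
    m$locus_count_lower_bound$class == "male_viability"], 1L)
})

test_that("concordant overlapping candidates are intersected for tightest support", {
  set <- dplyr::bind_rows(
    ann("sev1", "X", 0e6, 6e6, "male_sterile"),
    ann("mildA", "X", 0e6, 4e6, "male_fertile"),
    ann("mildB", "X", 0e6, 5e6, "male_fertile"))
  got <- minimal_locus_map(set)
  loci <- got$loci[got$loci$class == "male_fertility", ]
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(5e6, 6e6))
  expect_equal(loci$support, 2L)
})
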