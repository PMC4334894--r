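test_that("embryonic lethality and larval arrest rates follow their definitions", {
  expect_equal(emb_rate(tibble::tibble(eggs = 100, unhatched = 20)), 0.20)
  expect_equal(emb_rate(tibble::tibble(eggs = 100, unhatched = 0)), 0)
  expect_equal(emb_rate(tibble::tibble(eggs = c(100, 100), unhatched = c(10, 30)),
                        pooled = TRUE), 0.20)
  expect_warning(
    r <- emb_rate(tibble::tibble(eggs = c(0, 100), unhatched = c(0, 10))),
    "zero eggs")
  expect_equal(r, 0.1)
  expect_error(emb_rate(tibble::tibble(eggs = 10, unhatched = 11)), "exceed")

  expect_equal(lva_rate(tibble::tibble(l1 = 80, adults = 70)), 0.125)
  expect_equal(lva_rate(tibble::tibble(l1 = 80, adults = 80)), 0)
  expect_equal(lva_rate(tibble::tibble(l1 = 80, adults = 0)), 1)
  expect_error(lva_rate(tibble::tibble(l1 = 10, adults = 11)), "exceed")
})

test_that("chi-squared ratio test matches closed-form two-class values", {
  perfect <- chi_squared_ratio(c(50, 50), c(0.5, 0.5))
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  expect_equal(chi_squared_ratio(c(75, 25), c(0.75, 0.25))$statistic, 0)
  skew <- chi_squared_ratio(c(60, 40), c(0.5, 0.5))
  expect_equal(skew$statistic, 4)
  expect_equal(skew$df, 1)
  expect_equal(skew$p_value, 0.04550026, tolerance = 1e-6)
  expect_error(chi_squared_ratio(c(1, 2), c(1, 0)), "positive")
  expect_error(chi_squared_ratio(c(1, 2), c(0.7, 0.7)), "sum to 1")
})

test_that("chi-squared ordering agrees with the likelihood-ratio statistic on small counts", {
  n <- 12
  x2 <- vapply(0:n, function(a) chi_squared_ratio(c(a, n - a), c(0.5, 0.5))$statistic,
               numeric(1))
  g <- vapply(0:n, function(a) g_statistic(c(a, n - a), c(0.5, 0.5)), numeric(1))
  expect_equal(order(x2), order(g))
})

test_that("group comparison reduces to t-squared for two groups and fast-paths zero variance", {
  set.seed(21)
  a <- rnorm(6, 0.2, 0.05); b <- rnorm(6, 0.3, 0.05)
  d <- tibble::tibble(group = rep(c("line", "ctrl"), each = 6), value = c(a, b))
  cmp <- compare_to_control(d, "ctrl")
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(cmp$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p_omnibus, tt$p.value, tolerance = 1e-10)
  expect_equal(cmp$pairwise$p_adj, tt$p.value, tolerance = 1e-8)

  same <- tibble::tibble(group = rep(c("a", "ctrl"), each = 3), value = 0.1)
  fast <- compare_to_control(same, "ctrl")
  expect_equal(fast$f_statistic, 0)
  expect_equal(fast$pairwise$p_adj, 1)
  diffm <- tibble::tibble(group = rep(c("a", "ctrl"), each = 3),
                          value = rep(c(0.9, 0.1), each = 3))
  expect_equal(compare_to_control(diffm, "ctrl")$pairwise$p_adj, 0)
})

test_that("a strongly affected group is significant against control at p < 0.01", {
  d <- tibble::tibble(
    group = rep(c("line1", "line2", "ctrl"), each = 3),
    value = c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1) +
      rep(c(0, 0.001, -0.001), 3))
  cmp <- compare_to_control(d, "ctrl")
  p2 <- cmp$pairwise$p_adj[cmp$pairwise$group == "line2"]
  expect_lt(p2, 0.01)
  p1 <- cmp$pairwise$p_adj[cmp$pairwise$group == "line1"]
  expect_gt(p1, 0.5)
})

test_that("dominance calls use strict exceedance of control plus the recessive fraction", {
  expect_true(dominance_call(0.40, 0.10))
  expect_false(dominance_call(0.30, 0.10))
  expect_true(dominance_call(0.351, 0.10))
  expect_false(dominance_call(0.35, 0.10))
})

test_that("categorical HI definitions drive the classifier flags", {
  rec <- tibble::tibble(replicate = 1:3, eggs = 100, unhatched = 10, l1 = 90,
                        adults = 80, males_gfp = 20, males_nongfp = 20,
                        females_gfp = 20, females_nongfp = 20)
  # no progeny from the male-direction cross but a productive reciprocal
  sterile <- suppressWarnings(
    classify_line(rec, NULL, "x_het", male_cross_progeny = 0,
                  reciprocal_progeny = 100))
  expect_true(tidy(sterile)$value[tidy(sterile)$flag == "male_sterile"])

  # zero GFP males but GFP females present in an X-linked cross
  xinv <- dplyr::mutate(rec, males_gfp = 0)
  inv <- suppressWarnings(classify_line(xinv, NULL, "x_het"))
  expect_true(tidy(inv)$value[tidy(inv)$flag == "male_inviable"])

  # five failed homozygosing attempts
  hom <- suppressWarnings(
    classify_line(rec, NULL, "autosomal_het", attempts_to_homozygose = 5))
  expect_true(tidy(hom)$value[tidy(hom)$flag == "homozygous_inviable"])
  hom4 <- suppressWarnings(
    classify_line(rec, NULL, "autosomal_het", attempts_to_homozygose = 4))
  expect_false(tidy(hom4)$value[tidy(hom4)$flag == "homozygous_inviable"])
})

test_that("without a control only categorical and segregation flags are evaluated", {
  rec <- tibble::tibble(replicate = 1:3, eggs = 100, unhatched = 10, l1 = 90,
                        adults = 80, males_gfp = 20, males_nongfp = 20,
                        females_gfp = 20, females_nongfp = 20)
  expect_warning(call <- classify_line(rec, NULL, "autosomal_het"),
                 "no control")
  f <- tidy(call)
  expect_false(any(f$evaluated[f$flag %in% c("emb_elevated", "fertility_reduced")]))
  expect_true(all(f$evaluated[f$flag %in% c("sex_ratio_distorted",
                                            "gfp_segregation_distorted")]))
  expect_equal(glance(call)$scheme, "autosomal_het")
})

test_that("segregation distortion is tested against the scheme expectation", {
  # autosomal het x het at the Mendelian 75:25 - not distorted
  ok <- tibble::tibble(replicate = 1, eggs = 400, unhatched = 0, l1 = 400,
                       adults = 400, males_gfp = 150, males_nongfp = 50,
                       females_gfp = 150, females_nongfp = 50)
  suppressWarnings(call <- classify_line(ok, NULL, "autosomal_het"))
  f <- tidy(call)
  expect_equal(f$statistic[f$flag == "gfp_segregation_distorted"], 0)
  expect_equal(f$expectation[f$flag == "gfp_segregation_distorted"], 0.75)
  # X-linked line with no GFP males: expectation switches to 1/3
  xinv <- tibble::tibble(replicate = 1, eggs = 300, unhatched = 0, l1 = 300,
                         adults = 300, males_gfp = 0, males_nongfp = 100,
                         females_gfp = 100, females_nongfp = 100)
  suppressWarnings(xcall <- classify_line(xinv, NULL, "x_het"))
  xf <- tidy(xcall)
  expect_equal(xf$expectation[xf$flag == "gfp_segregation_distorted"], 1 / 3,
               tolerance = 1e-12)
  expect_equal(xf$statistic[xf$flag == "gfp_segregation_distorted"], 0)
})
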