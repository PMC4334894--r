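# Exact Mendelian expectation engine for single-locus XX/XO crosses.
#
# Probabilities are computed with integer weights over a common denominator,
# so the expected ratios (3/4, 1/2, 1/3, 1/8, 1/9, ...) are exact rationals;
# they are converted to double only at the interface. Sex determination is
# XX/XO: males are hemizygous for the X and produce X-bearing and nullo-X
# gametes at exactly 1/2 each.

ALLELE_ORDER <- c("G", "+")

normalize_genotype <- function(genotype, sex, linkage) {
  g <- gsub("O", "0", toupper_keep(genotype))
  parts <- strsplit(g, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts <- c(parts, if (sex == "male" && linkage == "x") "0")
  if (linkage == "x" && sex == "male") {
    if (!identical(sort(parts), sort(c(parts[parts != "0"][1], "0"))) ||
        sum(parts == "0") != 1 || !parts[parts != "0"] %in% ALLELE_ORDER) {
      abort(sprintf("X-linked males are hemizygous: expected 'G/0' or '+/0', got '%s'", genotype))
    }
    return(paste0(parts[parts != "0"], "/0"))
  }
  if (length(parts) != 2 || !all(parts %in% ALLELE_ORDER)) {
    abort(sprintf("invalid %s genotype '%s' for a %s", linkage, genotype, sex))
  }
  paste(parts[order(match(parts, ALLELE_ORDER))], collapse = "/")
}

toupper_keep <- function(x) chartr("go", "GO", x)

#' Gamete distribution of a parent at a single locus
#'
#' @param genotype Genotype string: `"G/G"`, `"G/+"`, `"+/+"`, or for
#'   X-linked males `"G/0"` / `"+/0"` (also written `"G/O"`).
#' @param sex `"female"` (XX) or `"male"` (XO).
#' @param linkage `"autosomal"` or `"x"`.
#' @return Tibble with columns `allele` (`"G"`, `"+"`, or `"0"` for the
#'   nullo-X gamete of XO males) and exact `num`/`den` weight columns plus
#'   `prob`.
#' @examples
#' enumerate_gametes("G/+", "female", "autosomal")
#' enumerate_gametes("G/0", "male", "x")
#' @export
enumerate_gametes <- function(genotype, sex = c("female", "male"),
                              linkage = c("autosomal", "x")) {
  sex <- match.arg(sex)
  linkage <- match.arg(linkage)
  g <- normalize_genotype(genotype, sex, linkage)
  alleles <- strsplit(g, "/", fixed = TRUE)[[1]]
  tab <- table(alleles)
  tibble(allele = names(tab), num = as.integer(tab), den = 2L,
         prob = as.integer(tab) / 2)
}

#' Per-class viability and fertility model
#'
#' @param survival Tibble with columns `genotype`, `sex` (`"female"`,
#'   `"male"` or `"both"`), `survival` in `[0, 1]` and optionally `stage`
#'   (`"emb"` or `"larval"`, used by the progeny-count simulator to attribute
#'   deaths; default `"emb"`). Classes not listed survive with probability 1.
#' @param sterile Tibble with columns `genotype`, `sex` for classes that are
#'   sterile (used when such an individual is a parent).
#' @param sex_ratio Probability of a female at conception (default 0.5).
#' @return A list of class `viability_model`.
#' @examples
#' viability_model(survival = tibble::tibble(genotype = "G/0", sex = "male",
#'                                           survival = 0))
#' @export
viability_model <- function(survival = NULL, sterile = NULL, sex_ratio = 0.5) {
  if (is.null(survival)) {
    survival <- tibble(genotype = character(), sex = character(),
                       survival = numeric(), stage = character())
  }
  if (!"stage" %in% names(survival)) survival$stage <- "emb"
  if (nrow(survival) && (any(survival$survival < 0 | survival$survival > 1))) {
    abort("survival probabilities must lie in [0, 1]")
  }
  if (is.null(sterile)) sterile <- tibble(genotype = character(), sex = character())
  if (sex_ratio <= 0 || sex_ratio >= 1) abort("sex_ratio must be in (0, 1)")
  structure(list(survival = survival, sterile = sterile,
                 sex_ratio = sex_ratio), class = "viability_model")
}

model_lookup <- function(model, genotype, sex, what = c("survival", "stage")) {
  what <- match.arg(what)
  s <- model$survival
  hit <- which(s$genotype == genotype & (s$sex == sex | s$sex == "both"))
  if (!length(hit)) return(if (what == "survival") 1 else "emb")
  if (what == "survival") s$survival[hit[1]] else s$stage[hit[1]]
}

is_sterile <- function(model, genotype, sex) {
  st <- model$sterile
  any(st$genotype == genotype & (st$sex == sex | st$sex == "both"))
}

#' Expected progeny distribution of a single-locus XX/XO cross
#'
#' Enumerates the cross product of the parents' gamete distributions, applies
#' XX/XO sex determination (for X-linked loci the father's nullo-X gamete
#' makes a male; for autosomal loci the sexes segregate independently at
#' `sex_ratio`), applies per-class survival and renormalizes over survivors.
#' All probabilities are exact rationals when the survival values are 0/1
#' (and `sex_ratio` is 1/2).
#'
#' @param mother,father Parental genotypes (see [enumerate_gametes()]).
#' @param linkage `"autosomal"` or `"x"`.
#' @param model A [viability_model()].
#' @return A tibble of class `progeny_dist` with columns `genotype`, `sex`,
#'   `gfp` (carries at least one G allele), `prob_pre` (at conception) and
#'   `prob_post` (among survivors); exact integer weights are carried in
#'   attributes `num_pre`, `num_post`, `den_pre`, `den_post` when available.
#' @examples
#' expected_progeny("G/+", "G/+") # autosomal het x het: 75% GFP
#' expected_progeny("G/+", "+/0", linkage = "x")
#' @export
expected_progeny <- function(mother, father, linkage = c("autosomal", "x"),
                             model = viability_model()) {
  linkage <- match.arg(linkage)
  mg <- normalize_genotype(mother, "female", linkage)
  fg <- normalize_genotype(father, "male", linkage)
  if (is_sterile(model, mg, "female") || is_sterile(model, fg, "male")) {
    abort("cross yields no progeny: a parent is sterile under the model")
  }
  gm <- enumerate_gametes(mg, "female", linkage)
  gf <- enumerate_gametes(fg, "male", linkage)
  combos <- tidyr::expand_grid(
    m = seq_len(nrow(gm)), f = seq_len(nrow(gf)))
  if (linkage == "x") {
    classes <- purrr::pmap_dfr(combos, function(m, f) {
      a <- gm$allele[m]; b <- gf$allele[f]
      w <- gm$num[m] * gf$num[f]
      if (b == "0") {
        tibble(genotype = paste0(a, "/0"), sex = "male", num = w)
      } else {
        alleles <- c(a, b)
        tibble(genotype = paste(alleles[order(match(alleles, ALLELE_ORDER))],
                                collapse = "/"),
               sex = "female", num = w)
      }
    })
    den <- gm$den[1] * gf$den[1]
    exact_sex <- TRUE
  } else {
    geno <- purrr::pmap_dfr(combos, function(m, f) {
      alleles <- c(gm$allele[m], gf$allele[f])
      tibble(genotype = paste(alleles[order(match(alleles, ALLELE_ORDER))],
                              collapse = "/"),
             num = gm$num[m] * gf$num[f])
    })
    exact_sex <- isTRUE(all.equal(model$sex_ratio, 0.5))
    classes <- tidyr::expand_grid(geno, sex = c("female", "male"))
    if (exact_sex) {
      classes$num <- classes$num * 1L
      den <- gm$den[1] * gf$den[1] * 2L
    } else {
      classes$num <- classes$num *
        ifelse(classes$sex == "female", model$sex_ratio, 1 - model$sex_ratio) * 2
      den <- gm$den[1] * gf$den[1] * 2
    }
  }
  dist <- classes %>%
    dplyr::group_by(.data$genotype, .data$sex) %>%
    dplyr::summarise(num = sum(.data$num), .groups = "drop") %>%
    dplyr::arrange(.data$sex, .data$genotype)
  surv <- purrr::map2_dbl(dist$genotype, dist$sex,
                          function(g, s) model_lookup(model, g, s, "survival"))
  exact <- exact_sex && all(surv %in% c(0, 1))
  num_post <- dist$num * surv
  den_post <- sum(num_post)
  if (den_post == 0) abort("infeasible model: all progeny classes are inviable")
  out <- dist %>%
    dplyr::mutate(gfp = grepl("G", .data$genotype, fixed = TRUE),
                  survival = surv,
                  prob_pre = .data$num / den,
                  prob_post = num_post / den_post) %>%
    dplyr::select("genotype", "sex", "gfp", "survival", "prob_pre", "prob_post")
  attr(out, "exact") <- exact
  attr(out, "num_pre") <- dist$num
  attr(out, "den_pre") <- den
  attr(out, "num_post") <- num_post
  attr(out, "den_post") <- den_post
  attr(out, "linkage") <- linkage
  attr(out, "parents") <- c(mother = mg, father = fg)
  class(out) <- c("progeny_dist", class(out))
  out
}

#' Conditional class probability from a progeny distribution
#'
#' @param dist A [expected_progeny()] result.
#' @param event Predicate over the distribution's columns (`genotype`, `sex`,
#'   `gfp`), e.g. `gfp` or `genotype == "G/G"`.
#' @param condition Optional conditioning predicate; default conditions on
#'   the whole (surviving, or pre-selection) population.
#' @param stage `"post"` (after viability selection, the default) or `"pre"`
#'   (at conception).
#' @return Probability as a double; exact when the distribution is exact
#'   (numerator/denominator integer arithmetic).
#' @examples
#' d <- expected_progeny("G/+", "G/+")
#' expected_fraction(d, gfp)                      # 0.75
#' expected_fraction(d, gfp, sex == "male")       # 0.75
#' expected_fraction(d, genotype == "G/G" & sex == "male", stage = "pre")
#' @export
expected_fraction <- function(dist, event, condition = NULL,
                              stage = c("post", "pre")) {
  stage <- match.arg(stage)
  ev <- eval_tidy(enquo(event), data = dist)
  cq <- enquo(condition)
  cond <- if (quo_is_null(cq)) rep(TRUE, nrow(dist)) else eval_tidy(cq, data = dist)
  num <- attr(dist, if (stage == "post") "num_post" else "num_pre")
  top <- sum(num[ev & cond])
  bottom <- sum(num[cond])
  if (bottom == 0) abort("conditioning event has zero probability")
  top / bottom
}

#' Probability that a randomly chosen GFP pair is doubly homozygous
#'
#' In the homozygosing step of an introgression scheme, one GFP-expressing
#' male and one GFP-expressing female are picked from the F1 of a cross and
#' mated. This returns the probability that both carry the introgression
#' homozygously (hemizygous X-linked males count as fully introgressed), i.e.
#' the expected fraction of plates that breed true. For an autosomal
#' heterozygote-by-heterozygote cross this is (1/3)^2 = 1/9.
#'
#' @param dist A [expected_progeny()] result for the cross the parents are
#'   drawn from.
#' @return Probability as a double.
#' @examples
#' homozygosing_success_probability(expected_progeny("G/+", "G/+")) # 1/9
#' @export
homozygosing_success_probability <- function(dist) {
  linkage <- attr(dist, "linkage")
  p_f <- expected_fraction(dist, .data$genotype == "G/G",
                           .data$gfp & .data$sex == "female")
  hom_male <- if (linkage == "x") "G/0" else "G/G"
  p_m <- expected_fraction(dist, .data$genotype == hom_male,
                           .data$gfp & .data$sex == "male")
  p_f * p_m
}

#' @rdname expected_progeny
#' @param x A `progeny_dist`.
#' @param ... Ignored.
#' @export
tidy.progeny_dist <- function(x, ...) {
  as_tibble(x)
}

#' @rdname expected_progeny
#' @export
glance.progeny_dist <- function(x, ...) {
  tibble(linkage = attr(x, "linkage"),
         mother = attr(x, "parents")[["mother"]],
         father = attr(x, "parents")[["father"]],
         exact = attr(x, "exact"),
         gfp_fraction = expected_fraction(x, .data$gfp),
         male_fraction = expected_fraction(x, .data$sex == "male"),
         surviving_fraction = attr(x, "den_post") / attr(x, "den_pre"))
}
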