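# Phenotype rates, tests against Mendelian expectations and controls, and
# HI category assignment.
#
# Replicate-level rates feed the ANOVA/Tukey comparisons; segregation and
# sex-ratio tests use pooled counts (Pearson chi-squared on counts, no
# continuity correction).

#' Embryonic lethality rate
#'
#' Fraction of eggs laid that fail to hatch. Replicates with zero eggs are
#' excluded with a warning.
#'
#' @param record Tibble with per-replicate columns `eggs` and `unhatched`.
#' @param pooled If `TRUE`, return the single pooled rate
#'   (total unhatched / total eggs); otherwise per-replicate rates.
#' @return Numeric vector of rates (or a single pooled rate).
#' @examples
#' emb_rate(tibble::tibble(eggs = c(100, 100), unhatched = c(10, 30)))
#' @export
emb_rate <- function(record, pooled = FALSE) {
  stopifnot(all(c("eggs", "unhatched") %in% names(record)))
  record <- record[!is.na(record$eggs) & !is.na(record$unhatched), , drop = FALSE]
  if (any(record$unhatched > record$eggs)) {
    abort("unhatched eggs cannot exceed eggs laid")
  }
  drop <- record$eggs == 0
  if (any(drop)) {
    warn(sprintf("%d replicate(s) with zero eggs excluded", sum(drop)))
    record <- record[!drop, , drop = FALSE]
  }
  if (pooled) sum(record$unhatched) / sum(record$eggs)
  else record$unhatched / record$eggs
}

#' Larval arrest rate
#'
#' Fraction of hatched L1 larvae that fail to reach adulthood:
#' `(L1 - adults) / L1`.
#'
#' @param record Tibble with per-replicate columns `l1` and `adults`.
#' @inheritParams emb_rate
#' @return Numeric vector of rates (or a single pooled rate).
#' @examples
#' lva_rate(tibble::tibble(l1 = 80, adults = 70))
#' @export
lva_rate <- function(record, pooled = FALSE) {
  stopifnot(all(c("l1", "adults") %in% names(record)))
  record <- record[!is.na(record$l1) & !is.na(record$adults), , drop = FALSE]
  if (any(record$adults > record$l1)) {
    abort("adults cannot exceed hatched L1 larvae")
  }
  drop <- record$l1 == 0
  if (any(drop)) {
    warn(sprintf("%d replicate(s) with zero L1 excluded", sum(drop)))
    record <- record[!drop, , drop = FALSE]
  }
  if (pooled) (sum(record$l1) - sum(record$adults)) / sum(record$l1)
  else (record$l1 - record$adults) / record$l1
}

#' Pearson chi-squared test of observed counts against expected fractions
#'
#' @param observed Integer counts per class.
#' @param expected Expected fractions per class (must sum to 1, all > 0).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi_squared_ratio(c(60, 40), c(0.5, 0.5)) # X^2 = 4, p ~ 0.0455
#' @export
chi_squared_ratio <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    abort("observed and expected must have the same length")
  }
  if (abs(sum(expected) - 1) > 1e-8) abort("expected fractions must sum to 1")
  if (any(expected <= 0)) abort("expected fractions must all be positive")
  ct <- suppressWarnings(chisq.test(observed, p = expected, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Compare replicate-level rates among groups (one-way ANOVA + Tukey HSD)
#'
#' An omnibus one-way ANOVA over all groups followed by Tukey's Honestly
#' Significant Difference post-hoc test; pairwise adjusted p-values against
#' the control group are returned. When every group has zero within-group
#' variance the exact-equality fast path applies: equal means give p = 1,
#' differing means p = 0.
#'
#' @param data Tibble with columns `group` and `value` (replicate-level rates
#'   or brood sizes).
#' @param control Name of the control group.
#' @return List with `f_statistic`, `p_omnibus` and a `pairwise` tibble
#'   (`group`, `diff` = group mean minus control mean, `p_adj`).
#' @examples
#' d <- tibble::tibble(group = rep(c("line", "ctrl"), each = 3),
#'                     value = c(0.9, 0.8, 0.85, 0.1, 0.12, 0.11))
#' compare_to_control(d, "ctrl")
#' @export
compare_to_control <- function(data, control) {
  stopifnot(all(c("group", "value") %in% names(data)))
  if (!control %in% data$group) abort("control group not present in data")
  groups <- unique(data$group)
  if (length(groups) < 2) abort("need at least 2 groups")
  sizes <- table(data$group)
  if (any(sizes < 2)) abort("need at least 2 replicates per group")
  means <- tapply(data$value, data$group, mean)
  vars <- tapply(data$value, data$group, stats::var)
  others <- setdiff(groups, control)
  if (all(vars == 0)) {
    equal <- abs(means[others] - means[control]) < .Machine$double.eps^.5
    return(list(
      f_statistic = 0,
      p_omnibus = if (all(abs(means - means[1]) < .Machine$double.eps^.5)) 1 else 0,
      pairwise = tibble(group = others,
                        diff = unname(means[others] - means[control]),
                        p_adj = unname(ifelse(equal, 1, 0)))))
  }
  d <- data.frame(group = factor(data$group), value = data$value)
  fit <- aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pair_names <- rownames(tk)
  wanted <- purrr::map_dfr(others, function(g) {
    fwd <- paste0(g, "-", control)
    rev <- paste0(control, "-", g)
    if (fwd %in% pair_names) {
      tibble(group = g, diff = tk[fwd, "diff"], p_adj = tk[fwd, "p adj"])
    } else {
      tibble(group = g, diff = -tk[rev, "diff"], p_adj = tk[rev, "p adj"])
    }
  })
  list(f_statistic = an[["F value"]][1], p_omnibus = an[["Pr(>F)"]][1],
       pairwise = wanted)
}

#' Dominance call for a heterozygous introgression
#'
#' A heterozygous introgression is called dominant for a lethality phenotype
#' when the hybrid rate exceeds the control rate plus the fraction expected
#' from fully penetrant recessive lethality of the homozygous class (25% in a
#' heterozygote-by-heterozygote autosomal cross). Strict inequality.
#'
#' @param het_rate,control_rate Rates in `[0, 1]`.
#' @param expected_recessive_fraction Expected homozygote fraction
#'   (default 0.25).
#' @return Logical.
#' @examples
#' dominance_call(0.40, 0.10) # TRUE: 0.40 > 0.35
#' @export
dominance_call <- function(het_rate, control_rate,
                           expected_recessive_fraction = 0.25) {
  stopifnot(het_rate >= 0, het_rate <= 1, control_rate >= 0, control_rate <= 1)
  het_rate > control_rate + expected_recessive_fraction
}

scheme_expectations <- function(scheme, male_inviable = FALSE) {
  switch(scheme,
    autosomal_het = list(
      dist = expected_progeny("G/+", "G/+", "autosomal"),
      gfp_overall = 0.75),
    x_het = {
      model <- if (male_inviable) {
        viability_model(survival = tibble(genotype = "G/0", sex = "male",
                                          survival = 0))
      } else viability_model()
      d <- expected_progeny("G/+", "+/0", "x", model)
      list(dist = d, gfp_overall = expected_fraction(d, .data$gfp))
    },
    homozygous = list(dist = NULL, gfp_overall = NA_real_),
    abort(sprintf("unknown crossing scheme '%s'", scheme))
  )
}

flag_row <- function(flag, value, statistic = NA_real_, p_value = NA_real_,
                     expectation = NA_real_, evaluated = TRUE,
                     sig_tiers = c(0.05, 0.01)) {
  tier <- if (is.na(p_value)) NA_character_
          else if (p_value < sig_tiers[2]) "**"
          else if (p_value < sig_tiers[1]) "*"
          else ""
  tibble(flag = flag, value = value, statistic = statistic,
         p_value = p_value, tier = tier, expectation = expectation,
         evaluated = evaluated)
}

#' Classify a line's hybrid-incompatibility phenotypes
#'
#' Computes every HI flag for one introgression line from its raw phenotype
#' counts: categorical calls (male sterility = no progeny from the
#' male-direction test cross; male inviability = no GFP males despite GFP
#' females; homozygous inviability = five failed homozygosing attempts),
#' segregation and sex-ratio chi-squared tests against the crossing scheme's
#' Mendelian expectation, and embryonic lethality / larval arrest / brood
#' size comparisons against the control via ANOVA + Tukey, with dominance
#' calls for the lethality phenotypes. Without a control record only the
#' categorical and chi-squared flags are evaluated.
#'
#' @param record Phenotype tibble for the line, one row per replicate, with
#'   any of the columns `eggs`, `unhatched`, `l1`, `adults`, `males_gfp`,
#'   `males_nongfp`, `females_gfp`, `females_nongfp`, `brood`.
#' @param control Phenotype tibble for the control strain (same columns), or
#'   `NULL`.
#' @param scheme Crossing scheme the counts come from: `"autosomal_het"`
#'   (het x het), `"x_het"` (X-linked heterozygous female x wild male) or
#'   `"homozygous"`.
#' @param attempts_to_homozygose Number of failed homozygosing attempts
#'   (`NA` if not attempted).
#' @param male_cross_progeny Total progeny in the male-direction test cross
#'   (GFP males x recipient females); `NA` if not assayed.
#' @param reciprocal_progeny Total progeny in the reciprocal cross, used to
#'   confirm that the female direction was productive.
#' @param sig_tiers Significance tiers (default `c(0.05, 0.01)`).
#' @param homozygosing_threshold Failed attempts required to call the
#'   introgression homozygous-inviable (default 5).
#' @return Object of class `hi_call`: list with `flags` tibble (one row per
#'   flag: `flag`, `value`, `statistic`, `p_value`, `tier`, `expectation`,
#'   `evaluated`) and `scheme`. Use [tidy()] / [glance()] to extract.
#' @export
classify_line <- function(record, control = NULL,
                          scheme = c("autosomal_het", "x_het", "homozygous"),
                          attempts_to_homozygose = NA_integer_,
                          male_cross_progeny = NA_real_,
                          reciprocal_progeny = NA_real_,
                          sig_tiers = c(0.05, 0.01),
                          homozygosing_threshold = 5) {
  scheme <- match.arg(scheme)
  has <- function(col, df = record) col %in% names(df) && !all(is.na(df[[col]]))
  sum_col <- function(col, df = record) sum(df[[col]], na.rm = TRUE)

  flags <- list()

  # categorical definitions
  male_sterile <- !is.na(male_cross_progeny) && male_cross_progeny == 0 &&
    (is.na(reciprocal_progeny) || reciprocal_progeny > 0)
  flags$male_sterile <- flag_row("male_sterile", male_sterile,
                                 evaluated = !is.na(male_cross_progeny))
  gfp_m <- if (has("males_gfp")) sum_col("males_gfp") else NA_real_
  gfp_f <- if (has("females_gfp")) sum_col("females_gfp") else NA_real_
  male_inviable <- scheme == "x_het" && !is.na(gfp_m) && !is.na(gfp_f) &&
    gfp_m == 0 && gfp_f > 0
  flags$male_inviable <- flag_row("male_inviable", male_inviable,
                                  evaluated = scheme == "x_het" &&
                                    !is.na(gfp_m) && !is.na(gfp_f))
  flags$homozygous_inviable <- flag_row(
    "homozygous_inviable",
    !is.na(attempts_to_homozygose) &&
      attempts_to_homozygose >= homozygosing_threshold,
    evaluated = !is.na(attempts_to_homozygose))

  # segregation tests against the scheme expectation (pooled counts)
  exp_scheme <- scheme_expectations(scheme, male_inviable = male_inviable)
  sex_cols <- c("males_gfp", "males_nongfp", "females_gfp", "females_nongfp")
  if (all(purrr::map_lgl(sex_cols, has))) {
    males <- sum_col("males_gfp") + sum_col("males_nongfp")
    females <- sum_col("females_gfp") + sum_col("females_nongfp")
    sr <- chi_squared_ratio(c(males, females), c(0.5, 0.5))
    flags$sex_ratio_distorted <- flag_row(
      "sex_ratio_distorted", sr$p_value < sig_tiers[1], sr$statistic,
      sr$p_value, expectation = 0.5, sig_tiers = sig_tiers)
    if (!is.na(exp_scheme$gfp_overall)) {
      gfp <- sum_col("males_gfp") + sum_col("females_gfp")
      nongfp <- sum_col("males_nongfp") + sum_col("females_nongfp")
      e <- exp_scheme$gfp_overall
      gs <- chi_squared_ratio(c(gfp, nongfp), c(e, 1 - e))
      flags$gfp_segregation_distorted <- flag_row(
        "gfp_segregation_distorted", gs$p_value < sig_tiers[1], gs$statistic,
        gs$p_value, expectation = e, sig_tiers = sig_tiers)
    } else {
      flags$gfp_segregation_distorted <- flag_row(
        "gfp_segregation_distorted", NA, evaluated = FALSE)
    }
  } else {
    flags$sex_ratio_distorted <- flag_row("sex_ratio_distorted", NA,
                                          evaluated = FALSE)
    flags$gfp_segregation_distorted <- flag_row("gfp_segregation_distorted",
                                                NA, evaluated = FALSE)
  }

  # control comparisons on replicate-level rates
  ctl_compare <- function(line_values, control_values, flag_up, flag_down = NULL) {
    d <- dplyr::bind_rows(tibble(group = "line", value = line_values),
                          tibble(group = "control", value = control_values))
    cmp <- compare_to_control(d, "control")
    p <- cmp$pairwise$p_adj[1]
    up <- cmp$pairwise$diff[1] > 0
    rows <- list(flag_row(flag_up, p < sig_tiers[1] && up,
                          cmp$f_statistic, p, sig_tiers = sig_tiers))
    if (!is.null(flag_down)) {
      rows <- c(rows, list(flag_row(flag_down, p < sig_tiers[1] && !up,
                                    cmp$f_statistic, p,
                                    sig_tiers = sig_tiers)))
    }
    rows
  }
  can_stat <- !is.null(control)
  unevaluated <- function(flag) flag_row(flag, NA, evaluated = FALSE)
  if (can_stat && has("eggs") && has("eggs", control)) {
    r <- ctl_compare(emb_rate(record), emb_rate(control), "emb_elevated")
    flags$emb_elevated <- r[[1]]
    flags$dominant_emb <- flag_row(
      "dominant_emb",
      isTRUE(r[[1]]$value) &&
        dominance_call(emb_rate(record, pooled = TRUE),
                       emb_rate(control, pooled = TRUE)),
      expectation = 0.25)
  } else {
    flags$emb_elevated <- unevaluated("emb_elevated")
    flags$dominant_emb <- unevaluated("dominant_emb")
  }
  if (can_stat && has("l1") && has("l1", control)) {
    r <- ctl_compare(lva_rate(record), lva_rate(control), "lva_elevated")
    flags$lva_elevated <- r[[1]]
    flags$dominant_lva <- flag_row(
      "dominant_lva",
      isTRUE(r[[1]]$value) &&
        dominance_call(lva_rate(record, pooled = TRUE),
                       lva_rate(control, pooled = TRUE)),
      expectation = 0.25)
  } else {
    flags$lva_elevated <- unevaluated("lva_elevated")
    flags$dominant_lva <- unevaluated("dominant_lva")
  }
  if (can_stat && has("brood") && has("brood", control)) {
    r <- ctl_compare(record$brood[!is.na(record$brood)],
                     control$brood[!is.na(control$brood)],
                     "fertility_elevated", "fertility_reduced")
    flags$fertility_elevated <- r[[1]]
    flags$fertility_reduced <- r[[2]]
  } else {
    flags$fertility_elevated <- unevaluated("fertility_elevated")
    flags$fertility_reduced <- unevaluated("fertility_reduced")
  }
  if (!can_stat) {
    warn("no control record: statistical flags marked unevaluated")
  }
  structure(list(flags = dplyr::bind_rows(flags), scheme = scheme,
                 sig_tiers = sig_tiers),
            class = "hi_call")
}

#' @rdname classify_line
#' @param x An `hi_call`.
#' @param ... Ignored.
#' @export
tidy.hi_call <- function(x, ...) x$flags

#' @rdname classify_line
#' @export
glance.hi_call <- function(x, ...) {
  f <- x$flags
  tibble(scheme = x$scheme,
         n_flags_evaluated = sum(f$evaluated),
         n_flags_set = sum(f$evaluated & !is.na(f$value) & f$value == TRUE))
}

#' @export
print.hi_call <- function(x, ...) {
  cat(sprintf("<hi_call> scheme: %s\n", x$scheme))
  print(x$flags)
  invisible(x)
}
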