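# Interval-contrast refinement: overlapping introgressions with discordant
# HI phenotypes localize the loci responsible. The region present in the more
# severe introgression but absent from the milder one must contain a locus
# required for the milder phenotype's capability.

MALE_SEVERITY <- c(male_fertile = 1, male_sterile = 2, male_inviable = 3)
HOM_SEVERITY <- c(homozygous_viable = 1, homozygous_inviable = 2)

# capability lost at the step from the milder to the severe phenotype
contrast_class <- function(severe, milder) {
  if (severe == "male_inviable") "male_viability"
  else if (severe == "male_sterile") "male_fertility"
  else if (severe == "homozygous_inviable") "homozygous_viability"
  else abort("uninformative phenotype contrast")
}

severity_of <- function(label) {
  s <- c(MALE_SEVERITY, HOM_SEVERITY)[label]
  if (anyNA(s)) {
    abort(sprintf("unknown phenotype label: %s",
                  paste(label[is.na(s)], collapse = ", ")))
  }
  unname(s)
}

same_family <- function(a, b) {
  (a %in% names(MALE_SEVERITY) && b %in% names(MALE_SEVERITY)) ||
    (a %in% names(HOM_SEVERITY) && b %in% names(HOM_SEVERITY))
}

interval_setdiff <- function(a, b) {
  ra <- IRanges::IRanges(a$start + 1L, as.integer(a$end))
  rb <- IRanges::IRanges(b$start + 1L, as.integer(b$end))
  d <- IRanges::setdiff(ra, rb)
  tibble(chrom = a$chrom,
         start = as.numeric(IRanges::start(d)) - 1,
         end = as.numeric(IRanges::end(d)))
}

#' Refine a candidate HI interval from a discordant introgression pair
#'
#' Given an introgression `a` with a strictly more severe phenotype than an
#' overlapping introgression `b`, the set difference `a \ b` (possibly two
#' flanking segments) must contain a locus required for the capability that
#' `b` retains. Example: an X-linked male-inviable introgression spanning
#' 14.00-15.11 Mb contrasted with a male-sterile one spanning 14.00-14.62 Mb
#' localizes a ~490 kb male-viability interval at 14.62-15.11 Mb.
#'
#' @param a One-row tibble: `strain`, `chrom`, `start`, `end`, `label`
#'   (severe member).
#' @param b One-row tibble for the milder member.
#' @return Interval tibble of candidates with columns `chrom`, `start`, `end`,
#'   `class` (the capability localized), `severe_strain`, `milder_strain`;
#'   zero rows (with a warning) when the intervals are identical.
#' @examples
#' a <- tibble::tibble(strain = "sevA", chrom = "X", start = 14.00e6,
#'                     end = 15.11e6, label = "male_inviable")
#' b <- tibble::tibble(strain = "milB", chrom = "X", start = 14.00e6,
#'                     end = 14.62e6, label = "male_sterile")
#' refine_interval(a, b)
#' @export
refine_interval <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  validate_intervals(a); validate_intervals(b)
  if (a$chrom != b$chrom || min(a$end, b$end) <= max(a$start, b$start)) {
    abort("contrast uninformative: introgressions do not overlap")
  }
  if (!same_family(a$label, b$label) || severity_of(a$label) <= severity_of(b$label)) {
    abort("'a' must carry the strictly more severe phenotype of the same family")
  }
  d <- interval_setdiff(a, b)
  if (nrow(d) == 0) {
    warn("identical intervals: contrast yields no candidate")
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), severe_strain = character(),
                  milder_strain = character()))
  }
  d %>% dplyr::mutate(class = contrast_class(a$label, b$label),
                      severe_strain = a$strain, milder_strain = b$strain)
}

#' Detect a linked suppressor from nested same-phenotype introgressions
#'
#' When an introgression nested inside a larger one shows markedly *greater*
#' severity on a quantitative metric (e.g. percentage of GFP-expressing
#' males), the extra material in the superset plausibly carries a suppressor
#' of the phenotype. The candidate suppressor region is the superset minus
#' the subset. Asymmetric by construction: the subset must be the more severe
#' member.
#'
#' @param subset,superset One-row tibbles (`strain`, `chrom`, `start`, `end`,
#'   `label`, `metric`); `subset` must be contained in `superset` and share
#'   its phenotype label. `metric` is a percentage where lower = more severe.
#' @param margin Minimum severity difference in metric units (default 20
#'   percentage points).
#' @return Interval tibble of the suppressor region(s) (possibly zero rows
#'   when the severity contrast is below `margin`).
#' @examples
#' sub <- tibble::tibble(strain = "inner", chrom = "X", start = 17e6,
#'                       end = 19.34e6, label = "male_sterile", metric = 4.9)
#' sup <- tibble::tibble(strain = "outer", chrom = "X", start = 15.5e6,
#'                       end = 20.75e6, label = "male_sterile", metric = 51.1)
#' detect_suppressor(sub, sup)
#' @export
detect_suppressor <- function(subset, superset, margin = 20) {
  stopifnot(nrow(subset) == 1, nrow(superset) == 1)
  if (subset$chrom != superset$chrom ||
      subset$start < superset$start || subset$end > superset$end) {
    abort("'subset' must be contained within 'superset'")
  }
  if (subset$label != superset$label) {
    abort("suppressor detection needs a shared phenotype class")
  }
  if (!(superset$metric - subset$metric > margin)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), severe_strain = character(),
                  milder_strain = character()))
  }
  interval_setdiff(superset, subset) %>%
    dplyr::mutate(class = "suppressor",
                  severe_strain = subset$strain,
                  milder_strain = superset$strain)
}

# maximum set of mutually disjoint intervals (greedy by end coordinate)
max_disjoint_count <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  iv <- dplyr::arrange(iv, .data$end)
  n <- 0L; last_end <- -Inf
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] >= last_end) {
      n <- n + 1L
      last_end <- iv$end[i]
    }
  }
  n
}

#' Map minimal candidate HI loci from a set of annotated introgressions
#'
#' Computes every informative pairwise contrast ([refine_interval()]) among
#' overlapping introgressions, intersects overlapping candidates of the same
#' class (tightest mutual support), and reports a lower bound on the number of
#' distinct loci per class as the size of a maximum set of mutually disjoint
#' candidate intervals.
#'
#' @param introgressions Tibble with columns `strain`, `chrom`, `start`,
#'   `end`, `label`.
#' @return List with `candidates` (all pairwise candidate intervals),
#'   `loci` (consolidated per class: `chrom`, `start`, `end`, `class`,
#'   `support` = number of supporting pairs) and `locus_count_lower_bound`
#'   (tibble `class`, `n`). Empty tibbles when no informative pairs exist.
#' @export
minimal_locus_map <- function(introgressions) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  class = character(), severe_strain = character(),
                  milder_strain = character())
  n <- nrow(introgressions)
  cands <- empty
  if (n >= 2) {
    pairs <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) %>%
      dplyr::filter(.data$i != .data$j)
    cands <- purrr::pmap_dfr(pairs, function(i, j) {
      a <- introgressions[i, ]; b <- introgressions[j, ]
      if (a$chrom != b$chrom || !same_family(a$label, b$label) ||
          severity_of(a$label) <= severity_of(b$label) ||
          min(a$end, b$end) <= max(a$start, b$start)) {
        return(NULL)
      }
      suppressWarnings(refine_interval(a, b))
    })
    if (is.null(cands) || nrow(cands) == 0) cands <- empty
  }
  if (nrow(cands) == 0) {
    return(list(candidates = empty,
                loci = empty[, c("chrom", "start", "end", "class")],
                locus_count_lower_bound = tibble(class = character(),
                                                 n = integer())))
  }
  # within each class, intersect mutually overlapping candidates
  loci <- cands %>%
    dplyr::group_by(.data$class, .data$chrom) %>%
    dplyr::reframe({
      iv <- dplyr::pick("start", "end") %>% dplyr::arrange(.data$start)
      out <- iv[1, ]; support <- 1L
      res <- NULL
      if (nrow(iv) > 1) {
        for (k in seq(2, nrow(iv))) {
          if (iv$start[k] < out$end[nrow(out)]) {
            out$start[nrow(out)] <- max(out$start[nrow(out)], iv$start[k])
            out$end[nrow(out)] <- min(out$end[nrow(out)], iv$end[k])
            support[nrow(out)] <- support[nrow(out)] + 1L
          } else {
            out <- dplyr::bind_rows(out, iv[k, ])
            support <- c(support, 1L)
          }
        }
      }
      dplyr::mutate(out, support = support)
    }) %>%
    dplyr::select("chrom", "start", "end", "class", "support")
  # per-class lower bound: sum of per-chromosome greedy disjoint counts
  bounds <- cands %>%
    dplyr::group_by(.data$class, .data$chrom) %>%
    dplyr::summarise(n = max_disjoint_count(dplyr::pick("start", "end")),
                     .groups = "drop") %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  list(candidates = cands, loci = loci, locus_count_lower_bound = bounds)
}

#' Plot annotated introgressions along chromosomes
#'
#' @param introgressions Tibble (`strain`, `chrom`, `start`, `end`, `label`).
#' @param loci Optional candidate-locus tibble from [minimal_locus_map()].
#' @return A ggplot of introgression spans colored by phenotype label.
#' @export
plot_introgression_map <- function(introgressions, loci = NULL) {
  iv <- introgressions %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(y = dplyr::row_number()) %>%
    dplyr::ungroup()
  p <- ggplot2::ggplot(iv) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$label),
                          linewidth = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "phenotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(loci) && nrow(loci)) {
    p <- p + ggplot2::geom_rect(
      data = loci, inherit.aes = FALSE, alpha = 0.2, fill = "grey40",
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf))
  }
  p
}
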