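# Coordinate conventions: all intervals are 0-based, half-open [start, end)
# in base pairs. Megabase rendering (2 decimals, half-up) happens only at the
# reporting layer.

#' cb4 chromosome sizes
#'
#' Chromosome lengths of the *C. briggsae* cb4 assembly used throughout the
#' package as the default coordinate system, together with a default genetic
#' map length of 0.5 Morgans per chromosome (a *Caenorhabditis*-like uniform
#' map used by the backcross simulator; see `vignette("nilhi-methods")`).
#'
#' @param map_length Genetic map length per chromosome in Morgans (recycled).
#'
#' @return A tibble with columns `chrom` (character), `length` (bp, double)
#'   and `map_length` (Morgans, double).
#' @examples
#' cb4_chromosomes()
#' @export
cb4_chromosomes <- function(map_length = 0.5) {
  tibble(
    chrom = c("I", "II", "III", "IV", "V", "X"),
    length = c(15.45, 16.62, 14.57, 17.48, 19.49, 21.54) * 1e6,
    map_length = rep_len(map_length, 6)
  )
}

#' Construct a validated table of genomic intervals
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Interval bounds in bp, 0-based half-open.
#' @param chrom_sizes Optional chromosome-size tibble (columns `chrom`,
#'   `length`); when supplied, intervals exceeding their chromosome are
#'   rejected.
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' gintervals("X", 14.62e6, 15.11e6)
#' @export
gintervals <- function(chrom, start, end, chrom_sizes = NULL) {
  iv <- tibble(chrom = as.character(chrom),
               start = as.numeric(start), end = as.numeric(end))
  validate_intervals(iv, chrom_sizes)
  iv
}

validate_intervals <- function(iv, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad)) {
    abort(sprintf("invalid interval at row %d: need 0 <= start < end", bad[1]))
  }
  if (!is.null(chrom_sizes)) {
    len <- chrom_length(chrom_sizes, iv$chrom)
    over <- which(iv$end > len)
    if (length(over)) {
      abort(sprintf("interval at row %d extends past end of chromosome %s",
                    over[1], iv$chrom[over[1]]))
    }
  }
  invisible(iv)
}

chrom_length <- function(chrom_sizes, chrom) {
  idx <- match(chrom, chrom_sizes$chrom)
  if (anyNA(idx)) {
    abort(sprintf("unknown chromosome: %s",
                  paste(unique(chrom[is.na(idx)]), collapse = ", ")))
  }
  chrom_sizes$length[idx]
}

#' Interval length in bp and Mb
#'
#' @param iv Interval tibble (`chrom`, `start`, `end`).
#' @return `interval_length()` returns lengths in bp; `bp_to_mb()` renders bp
#'   as Mb rounded half-up to 2 decimals, the convention used in coverage
#'   tables.
#' @examples
#' interval_length(gintervals("X", 14.62e6, 15.11e6)) # 490000
#' bp_to_mb(490000)                                   # 0.49
#' @export
interval_length <- function(iv) {
  validate_intervals(iv)
  iv$end - iv$start
}

#' @rdname interval_length
#' @param bp Length(s) in base pairs.
#' @export
bp_to_mb <- function(bp) round_half_up(bp / 1e6, 2)

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Consolidate intervals into a minimal sorted non-overlapping set
#'
#' Overlapping and abutting intervals on the same chromosome are merged
#' (half-open convention: `end == start` adjacency merges); chromosomes are
#' never merged across. Idempotent and order-invariant.
#'
#' @param iv Interval tibble (`chrom`, `start`, `end`); zero rows allowed.
#' @return Interval tibble sorted by chromosome and start.
#' @examples
#' consolidate_intervals(gintervals("I", c(1, 2, 7), c(3, 5, 8)))
#' @export
consolidate_intervals <- function(iv) {
  if (nrow(iv) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  validate_intervals(iv)
  iv %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::reframe({
      r <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1L,
                                            end = as.integer(.data$end)))
      tibble(start = as.numeric(IRanges::start(r)) - 1,
             end = as.numeric(IRanges::end(r)))
    }) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Fraction of a chromosome covered by a consolidated interval set
#'
#' @param iv Interval tibble restricted to (or filtered down to) `chrom`.
#' @param chrom_sizes Chromosome-size tibble (`chrom`, `length`).
#' @param chrom Chromosome name.
#' @return Percentage in `[0, 100]`, unrounded (use [round_pct()] for the
#'   2-decimal reporting convention).
#' @examples
#' coverage_fraction(gintervals("I", 0, 15.13e6), cb4_chromosomes(), "I")
#' @export
coverage_fraction <- function(iv, chrom_sizes, chrom) {
  len <- chrom_length(chrom_sizes, chrom)
  iv <- consolidate_intervals(iv[iv$chrom == chrom, , drop = FALSE])
  if (nrow(iv) == 0) return(0)
  100 * sum(iv$end - iv$start) / len
}

#' @rdname coverage_fraction
#' @param pct Percentage(s) to render.
#' @export
round_pct <- function(pct) round_half_up(pct, 2)

#' Genome-wide introgression coverage landscape
#'
#' Consolidates introgression intervals per chromosome and per viability
#' category and summarises consolidated size (Mb) and percentage of the
#' chromosome covered, with autosomal and overall aggregate rows. This
#' reproduces the layout of a coverage-statistics table for an introgression
#' panel ("redundant parts are consolidated").
#'
#' @param introgressions Tibble with columns `chrom`, `start`, `end` and
#'   `category` (one of `"homozygous_viable"`, `"homozygous_inviable"`,
#'   `"heterozygous"`).
#' @param chrom_sizes Chromosome-size tibble; defaults to [cb4_chromosomes()].
#' @param x_chrom Name of the X chromosome, excluded from the autosomal
#'   aggregate.
#' @return Tibble with columns `chrom`, `chrom_mb`, `category` (including
#'   `"all"`), `size_mb` and `pct`; `size_mb`/`pct` rendered to 2 decimals.
#' @examples
#' iv <- tibble::tibble(chrom = "I", start = 0, end = 15.13e6,
#'                      category = "heterozygous")
#' build_landscape(iv)
#' @export
build_landscape <- function(introgressions, chrom_sizes = cb4_chromosomes(),
                            x_chrom = "X") {
  categories <- c("homozygous_viable", "homozygous_inviable", "heterozygous")
  if (nrow(introgressions) > 0) {
    validate_intervals(introgressions, chrom_sizes)
    bad <- setdiff(unique(introgressions$category), categories)
    if (length(bad)) {
      abort(sprintf("unknown introgression category: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  per_chrom_cat <- function(iv, chrom) {
    cons <- consolidate_intervals(iv[iv$chrom == chrom, , drop = FALSE])
    sum(cons$end - cons$start)
  }
  rows <- tidyr::expand_grid(chrom = chrom_sizes$chrom,
                             category = c("all", categories)) %>%
    dplyr::mutate(
      size_bp = purrr::map2_dbl(.data$chrom, .data$category, function(ch, cat) {
        iv <- introgressions
        if (cat != "all") iv <- iv[iv$category == cat, , drop = FALSE]
        per_chrom_cat(iv, ch)
      }),
      chrom_bp = chrom_length(chrom_sizes, .data$chrom)
    )
  aggregate_rows <- function(rows, label, chroms) {
    rows %>%
      dplyr::filter(.data$chrom %in% chroms) %>%
      dplyr::group_by(.data$category) %>%
      dplyr::summarise(size_bp = sum(.data$size_bp),
                       chrom_bp = sum(.data$chrom_bp), .groups = "drop") %>%
      dplyr::mutate(chrom = label, .before = 1)
  }
  autosomes <- setdiff(chrom_sizes$chrom, x_chrom)
  out <- dplyr::bind_rows(
    rows,
    aggregate_rows(rows, "Autosomal", autosomes),
    aggregate_rows(rows, "Overall", chrom_sizes$chrom)
  )
  out %>%
    dplyr::transmute(
      chrom = .data$chrom,
      chrom_mb = bp_to_mb(.data$chrom_bp),
      category = .data$category,
      size_mb = bp_to_mb(.data$size_bp),
      pct = round_pct(100 * .data$size_bp / .data$chrom_bp)
    )
}

#' Plot an introgression coverage landscape
#'
#' @param landscape Output of [build_landscape()].
#' @return A ggplot: coverage percentage per chromosome, one bar per category.
#' @export
plot_landscape <- function(landscape) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$chrom, y = .data$pct,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "linkage group", y = "chromosome covered (%)",
                  fill = "introgression class") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
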