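# Read-depth window based introgression detection: a donor fragment inserted
# into the recipient background shows strongly elevated coverage when the
# introgression strain's reads are mapped to the donor assembly. Regions with
# five-fold higher depth than flanking (baseline) regions are called.

#' Construct a windowed coverage track
#'
#' @param chrom Chromosome name (single value).
#' @param depth Per-window mean depth, in window order from position 0.
#' @param window Window size in bp (default 10,000).
#' @return Tibble of class `coverage_track` with columns `chrom`, `start`,
#'   `end`, `depth`.
#' @export
coverage_track <- function(chrom, depth, window = 10000) {
  if (any(depth < 0)) abort("window depths must be non-negative")
  n <- length(depth)
  out <- tibble(chrom = as.character(chrom[1]),
                start = (seq_len(n) - 1) * window,
                end = seq_len(n) * window,
                depth = as.numeric(depth))
  class(out) <- c("coverage_track", class(out))
  out
}

#' Normalize a coverage track by total bases sequenced
#'
#' Depths are rescaled to depth per gigabase sequenced, so tracks from
#' libraries of different size are comparable.
#'
#' @param track `coverage_track` (or tibble with a `depth` column).
#' @param total_bases Total bases sequenced for the sample (> 0).
#' @return The track with `depth` divided by `total_bases / 1e9`.
#' @export
normalize_track <- function(track, total_bases) {
  if (!is.numeric(total_bases) || total_bases <= 0) {
    abort("total_bases must be a positive number")
  }
  if (any(track$depth < 0)) abort("window depths must be non-negative")
  track$depth <- track$depth / (total_bases / 1e9)
  track
}

#' Coverage-call configuration
#'
#' @param fold Enrichment threshold over baseline (default 5, > 1).
#' @param min_windows Minimum above-threshold windows per call (default 3).
#' @param gap Maximum run of sub-threshold windows merged into a call
#'   (default 1).
#' @param baseline Baseline estimator: `"global_median"` (chromosome-wide
#'   median excluding candidate runs, one re-estimation pass) or
#'   `"local_flank"` (median of `flank_windows` windows on each side of a
#'   candidate run).
#' @param flank_windows Flank width for the local estimator (default 20).
#' @param epsilon Floor applied when the baseline estimate is zero but
#'   positive windows exist.
#' @return A list of class `coverage_call_config`.
#' @export
coverage_call_config <- function(fold = 5, min_windows = 3, gap = 1,
                                 baseline = c("global_median", "local_flank"),
                                 flank_windows = 20, epsilon = 1e-6) {
  if (fold <= 1) abort("fold must exceed 1")
  if (min_windows < 1) abort("min_windows must be at least 1")
  structure(list(fold = fold, min_windows = min_windows, gap = gap,
                 baseline = match.arg(baseline),
                 flank_windows = flank_windows, epsilon = epsilon),
            class = "coverage_call_config")
}

# Merge TRUE-runs of `above` separated by <= gap FALSE windows; return
# runs as a tibble of window indices (from, to).
merge_runs <- function(above, gap) {
  r <- call_runs(ifelse(above, "+", "-"))
  pos <- r[r$call == "+", , drop = FALSE]
  if (nrow(pos) == 0) return(pos[, c("from", "to")])
  merged <- pos[1, c("from", "to")]
  if (nrow(pos) > 1) {
    for (i in seq(2, nrow(pos))) {
      last <- nrow(merged)
      if (pos$from[i] - merged$to[last] - 1 <= gap) {
        merged$to[last] <- pos$to[i]
      } else {
        merged <- dplyr::bind_rows(merged, pos[i, c("from", "to")])
      }
    }
  }
  merged
}

#' Call introgressed regions from a coverage track
#'
#' Baseline depth is estimated robustly (median of windows outside candidate
#' runs, re-estimated once). Runs containing at least `min_windows` windows
#' with depth at least `fold` times the baseline seed the calls; because
#' multiplicative noise lets individual enriched windows dip below the hard
#' threshold, each seed run is then extended outward through contiguous
#' windows that remain above the geometric midpoint `sqrt(fold)` times
#' baseline (windows closer to the enriched level than to the baseline), and
#' runs separated by at most `gap` sub-threshold windows are merged. Calls
#' are invariant to rescaling all depths by a constant. Multi-segment output
#' is first-class: secondary enriched regions are reported as additional
#' intervals.
#'
#' @param track A [coverage_track()].
#' @param config A [coverage_call_config()].
#' @return Interval tibble (`chrom`, `start`, `end`) of called regions, plus
#'   attributes `baseline` (depth) and `fold` (per-window enrichment vector).
#' @examples
#' tr <- coverage_track("V", c(rep(1, 50), rep(6, 50), rep(1, 100)))
#' call_coverage_introgression(tr)
#' @export
call_coverage_introgression <- function(track, config = coverage_call_config()) {
  d <- track$depth
  if (length(d) < 2 * config$min_windows) {
    abort("track too short: need at least 2 * min_windows windows")
  }
  b0 <- median(d)
  cand <- d >= config$fold * max(b0, config$epsilon)
  baseline <- if (all(cand)) b0 else median(d[!cand])
  if (baseline == 0 && any(d > 0)) {
    warn("baseline depth is zero; flooring at epsilon")
    baseline <- config$epsilon
  }
  above <- d >= config$fold * baseline
  runs <- merge_runs(above, config$gap)
  if (nrow(runs)) {
    n_above <- purrr::map_dbl(seq_len(nrow(runs)),
                              function(i) sum(above[runs$from[i]:runs$to[i]]))
    runs <- runs[n_above >= config$min_windows, , drop = FALSE]
  }
  if (config$baseline == "local_flank" && nrow(runs)) {
    keep <- purrr::map_lgl(seq_len(nrow(runs)), function(i) {
      lo <- max(1, runs$from[i] - config$flank_windows)
      hi <- min(length(d), runs$to[i] + config$flank_windows)
      flank_idx <- c(if (lo <= runs$from[i] - 1) seq(lo, runs$from[i] - 1),
                     if (runs$to[i] + 1 <= hi) seq(runs$to[i] + 1, hi))
      fb <- if (length(flank_idx)) max(median(d[flank_idx]), config$epsilon)
            else baseline
      median(d[runs$from[i]:runs$to[i]]) >= config$fold * fb
    })
    runs <- runs[keep, , drop = FALSE]
  }
  # hysteresis extension: grow seed runs through windows above the geometric
  # midpoint between baseline and the fold threshold
  ext <- sqrt(config$fold) * baseline
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      while (runs$from[i] > 1 && d[runs$from[i] - 1] >= ext) {
        runs$from[i] <- runs$from[i] - 1
      }
      while (runs$to[i] < length(d) && d[runs$to[i] + 1] >= ext) {
        runs$to[i] <- runs$to[i] + 1
      }
    }
    # extension can bring neighbouring runs within the gap tolerance: merge
    runs <- dplyr::arrange(runs, .data$from)
    merged <- runs[1, ]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$from[i] <= merged$to[nrow(merged)] + 1 + config$gap) {
        merged$to[nrow(merged)] <- max(merged$to[nrow(merged)], runs$to[i])
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  out <- tibble(chrom = track$chrom[1],
                start = track$start[runs$from],
                end = track$end[runs$to])
  attr(out, "baseline") <- baseline
  attr(out, "fold") <- d / baseline
  out
}

#' @rdname coverage_track
#' @param object A `coverage_track`.
#' @param calls Optional interval tibble of calls to shade.
#' @param ... Ignored.
#' @export
autoplot.coverage_track <- function(object, calls = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("chromosome %s position (Mb)", object$chrom[1]),
                  y = "normalized depth") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + ggplot2::geom_rect(
      data = calls, inherit.aes = FALSE, alpha = 0.2, fill = "firebrick",
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf))
  }
  p
}
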