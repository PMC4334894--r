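# Boundary calling from ordered species-specific PCR marker calls.
#
# Marker position is the amplicon midpoint. Calls are "+" (donor-specific
# product amplified), "-" (no product) or NA (failed reaction; transparent:
# skipped for run construction and never flagged as an exception).

#' Construct / validate a marker panel
#'
#' @param marker Marker (primer pair) names, unique.
#' @param chrom Chromosome per marker.
#' @param start,end Amplicon span in bp, 0-based half-open.
#' @return Tibble sorted by chromosome and midpoint, with a `mid` column.
#' @export
marker_panel <- function(marker, chrom, start, end) {
  panel <- tibble(marker = as.character(marker), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end))
  validate_intervals(panel)
  if (anyDuplicated(panel$marker)) abort("marker names must be unique")
  panel <- panel %>%
    dplyr::mutate(mid = (.data$start + .data$end) / 2) %>%
    dplyr::arrange(.data$chrom, .data$mid)
  dup <- panel %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::filter(duplicated(.data$mid))
  if (nrow(dup)) abort("markers on one chromosome must have unique midpoints")
  panel
}

# Split a vector of "+"/"-" calls into maximal runs.
call_runs <- function(call) {
  r <- rle(call)
  ends <- cumsum(r$lengths)
  tibble(call = r$values, len = r$lengths,
         from = ends - r$lengths + 1, to = ends)
}

#' Flag exceptional marker calls (candidate assembly errors)
#'
#' A maximal run of contradicting calls of length at most `exception_max_run`,
#' flanked on both sides by runs of at least `min_consensus` consistent calls
#' (falling back to 1 where the flanking run touches the panel edge), is
#' flagged as an exception. Such calls contradict the consensus of multiple
#' surrounding primers and typically indicate that the genomic region covering
#' the primer belongs elsewhere in the assembly; they are excluded from
#' boundary computation. NA calls are transparent.
#'
#' @param calls Tibble with columns `marker` and `call` (values `"+"`, `"-"`
#'   or `NA`) for one strain and one chromosome.
#' @param panel Marker panel ([marker_panel()]), used for ordering.
#' @param exception_max_run Longest contradicting run still treated as an
#'   exception (default 1).
#' @param min_consensus Minimum consistent flanking run length (default 2).
#' @return Tibble with columns `marker`, `call` and `consensus_call` (the
#'   surrounding run's call); zero rows when nothing is flagged.
#' @export
flag_assembly_errors <- function(calls, panel, exception_max_run = 1,
                                 min_consensus = 2) {
  x <- ordered_calls(calls, panel)
  x <- x[!is.na(x$call), , drop = FALSE]
  empty <- tibble(marker = character(), call = character(),
                  consensus_call = character())
  if (nrow(x) < 3) return(empty)
  runs <- call_runs(x$call)
  n <- nrow(runs)
  if (n < 3) return(empty)
  flagged <- purrr::map_dfr(seq(2, n - 1), function(i) {
    left <- runs[i - 1, ]; right <- runs[i + 1, ]
    need_left <- if (left$from == 1) 1 else min_consensus
    need_right <- if (right$to == nrow(x)) 1 else min_consensus
    if (runs$len[i] <= exception_max_run &&
        left$call == right$call && left$call != runs$call[i] &&
        left$len >= need_left && right$len >= need_right) {
      idx <- seq(runs$from[i], runs$to[i])
      tibble(marker = x$marker[idx], call = x$call[idx],
             consensus_call = left$call)
    } else {
      NULL
    }
  })
  if (nrow(flagged) == 0) empty else flagged
}

ordered_calls <- function(calls, panel) {
  x <- dplyr::inner_join(panel, calls, by = "marker")
  if (nrow(x) < nrow(calls)) {
    missing <- setdiff(calls$marker, panel$marker)
    abort(sprintf("calls for markers absent from panel: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(unique(x$chrom)) > 1) {
    abort("call_boundaries() works on one chromosome at a time")
  }
  ok <- is.na(x$call) | x$call %in% c("+", "-")
  if (!all(ok)) {
    abort(sprintf("invalid genotype call '%s' at marker %s",
                  x$call[!ok][1], x$marker[!ok][1]))
  }
  dplyr::arrange(x, .data$mid)
}

#' Call introgression boundaries for one strain on one chromosome
#'
#' Applies the consensus rule: exceptional calls are flagged and excluded,
#' then the inner interval spans the outermost consensus "+" markers and the
#' outer interval extends to the nearest consensus "-" marker midpoint on each
#' side (or the chromosome end when the "+" run reaches the terminal marker).
#' The outer interval is the reported introgression size estimate. Multiple
#' disjoint consensus "+" runs yield a multi-segment result with a warning
#' (possible assembly error).
#'
#' @inheritParams flag_assembly_errors
#' @param chrom_sizes Chromosome-size tibble (`chrom`, `length`).
#' @param strain Strain label carried into the result.
#' @param zygosity Zygosity annotation from crossing records (PCR with
#'   donor-specific primers cannot distinguish heterozygotes from
#'   homozygotes); one of `"heterozygous"`, `"homozygous"`, `"hemizygous"`,
#'   `"unknown"`.
#' @return A tibble of class `introgression_call`, one row per segment, with
#'   columns `strain`, `chrom`, `segment`, `inner_start`, `inner_end`,
#'   `outer_start`, `outer_end`, `size_bp`, `zygosity` and list-column
#'   `exceptions`.
#' @examples
#' panel <- marker_panel(paste0("m", 1:7), "I", (1:7) * 1e6 - 500,
#'                       (1:7) * 1e6 + 500)
#' calls <- tibble::tibble(marker = paste0("m", 1:7),
#'                         call = c("-", "-", "+", "+", "+", "-", "-"))
#' call_boundaries(calls, panel, cb4_chromosomes())
#' @export
call_boundaries <- function(calls, panel, chrom_sizes, strain = "strain",
                            zygosity = "unknown", exception_max_run = 1,
                            min_consensus = 2) {
  x <- ordered_calls(calls, panel)
  chrom <- x$chrom[1]
  clen <- chrom_length(chrom_sizes, chrom)
  exc <- flag_assembly_errors(calls, panel, exception_max_run, min_consensus)
  keep <- x[!is.na(x$call) & !(x$marker %in% exc$marker), , drop = FALSE]
  if (nrow(keep) == 0 || !any(keep$call == "+")) {
    abort(sprintf("no introgression detected for strain %s on chromosome %s",
                  strain, chrom))
  }
  runs <- call_runs(keep$call)
  pos_runs <- runs[runs$call == "+", , drop = FALSE]
  if (nrow(pos_runs) > 1) {
    warn(sprintf(paste("strain %s: %d disjoint consensus '+' runs on %s;",
                       "possible assembly error, reporting multiple segments"),
                 strain, nrow(pos_runs), chrom))
  }
  segs <- purrr::map_dfr(seq_len(nrow(pos_runs)), function(i) {
    from <- pos_runs$from[i]; to <- pos_runs$to[i]
    inner_start <- keep$mid[from]
    inner_end <- keep$mid[to]
    outer_start <- if (from == 1) 0 else keep$mid[from - 1]
    outer_end <- if (to == nrow(keep)) clen else keep$mid[to + 1]
    tibble(strain = strain, chrom = chrom, segment = i,
           inner_start = inner_start, inner_end = inner_end,
           outer_start = outer_start, outer_end = outer_end,
           size_bp = outer_end - outer_start, zygosity = zygosity,
           exceptions = list(exc))
  })
  class(segs) <- c("introgression_call", class(segs))
  segs
}

#' Call introgressions for every strain in a genotype matrix
#'
#' @param genotypes Long genotype tibble (`strain`, `marker`, `call`).
#' @param panel Marker panel.
#' @param chrom_sizes Chromosome-size tibble.
#' @param zygosity Optional tibble (`strain`, `zygosity`) of crossing-record
#'   annotations.
#' @param ... Passed to [call_boundaries()].
#' @return Row-bound `introgression_call` tibble across strains; strains on
#'   multi-chromosome panels are called per chromosome.
#' @export
call_introgressions <- function(genotypes, panel, chrom_sizes,
                                zygosity = NULL, ...) {
  zyg_for <- function(s) {
    if (is.null(zygosity)) return("unknown")
    z <- zygosity$zygosity[match(s, zygosity$strain)]
    if (is.na(z)) "unknown" else z
  }
  out <- genotypes %>%
    dplyr::inner_join(panel[, c("marker", "chrom")], by = "marker") %>%
    dplyr::group_by(.data$strain, .data$chrom) %>%
    dplyr::group_map(function(g, key) {
      res <- tryCatch(
        call_boundaries(g[, c("marker", "call")], panel, chrom_sizes,
                        strain = key$strain, zygosity = zyg_for(key$strain),
                        ...),
        error = function(e) NULL)
      res
    }) %>%
    purrr::compact() %>%
    dplyr::bind_rows()
  class(out) <- c("introgression_call", class(out))
  out
}

#' Concordance between a PCR boundary call and a reference interval
#'
#' Used to compare marker-based outer intervals against an independent
#' boundary estimate (for example a read-depth call).
#'
#' @param call One-row interval tibble (`chrom`, `start`, `end`), e.g. a
#'   PCR outer interval.
#' @param reference One-row interval tibble for the same chromosome.
#' @return One-row tibble: `jaccard`, `left_offset_bp`, `right_offset_bp`
#'   (signed, call minus reference).
#' @examples
#' compare_callsets(gintervals("V", 0, 7.75e6), gintervals("V", 0, 7.10e6))
#' @export
compare_callsets <- function(call, reference) {
  stopifnot(nrow(call) == 1, nrow(reference) == 1)
  validate_intervals(call); validate_intervals(reference)
  if (call$chrom != reference$chrom) {
    warn("call and reference are on different chromosomes; concordance is 0")
    return(tibble(jaccard = 0, left_offset_bp = NA_real_,
                  right_offset_bp = NA_real_))
  }
  inter <- max(0, min(call$end, reference$end) - max(call$start, reference$start))
  union <- (call$end - call$start) + (reference$end - reference$start) - inter
  tibble(jaccard = inter / union,
         left_offset_bp = call$start - reference$start,
         right_offset_bp = call$end - reference$end)
}
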