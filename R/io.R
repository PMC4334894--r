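# File formats. Interval output is BED (0-based half-open). Marker panels
# come in 1-based inclusive (the convention primer coordinates are reported
# in) and are converted at the boundary. Readers enforce the type invariants
# at load and name the offending row/column on failure.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a chromosome-size table
#'
#' Two-column headerless TSV (`chrom`, `length`), FASTA-index style.
#'
#' @param path File path.
#' @return Chromosome-size tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- read_tsv_quiet(path, col_names = c("chrom", "length"),
                      col_types = "cd")
  if (any(x$length <= 0)) abort("chromosome lengths must be positive")
  if (anyDuplicated(x$chrom)) abort("duplicate chromosome names")
  x$map_length <- 0.5
  x
}

#' Read a marker panel TSV
#'
#' Columns `marker`, `chrom`, `start`, `end`, 1-based inclusive amplicon
#' coordinates; converted to the internal 0-based half-open convention
#' (`start - 1`, `end`).
#'
#' @param path File path.
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols())
  need <- c("marker", "chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("marker panel missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  marker_panel(x$marker, x$chrom, x$start - 1, x$end)
}

#' Read a genotype matrix CSV
#'
#' Wide CSV: first column `strain`, remaining columns one per marker, cells
#' in `{+, -, NA}` (empty cells read as `NA`).
#'
#' @param path File path.
#' @return Long genotype tibble (`strain`, `marker`, `call`).
#' @export
read_genotype_matrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (names(x)[1] != "strain") abort("first column must be 'strain'")
  long <- tidyr::pivot_longer(x, -"strain", names_to = "marker",
                              values_to = "call")
  bad <- which(!(is.na(long$call) | long$call %in% c("+", "-", "NA")))
  if (length(bad)) {
    abort(sprintf("invalid genotype call '%s' (strain %s, marker %s)",
                  long$call[bad[1]], long$strain[bad[1]], long$marker[bad[1]]))
  }
  long$call[long$call == "NA"] <- NA_character_
  long
}

#' Read a phenotype count table
#'
#' TSV with one row per replicate; recognised columns: `strain`, `replicate`,
#' `eggs`, `unhatched`, `l1`, `adults`, `males_gfp`, `males_nongfp`,
#' `females_gfp`, `females_nongfp`, `brood`. Count invariants (`unhatched <=
#' eggs`, `adults <= l1`) are enforced.
#'
#' @param path File path.
#' @return Phenotype tibble.
#' @export
read_phenotype_table <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols())
  if (!"strain" %in% names(x)) abort("phenotype table needs a 'strain' column")
  if (all(c("eggs", "unhatched") %in% names(x))) {
    bad <- which(x$unhatched > x$eggs)
    if (length(bad)) {
      abort(sprintf("row %d: unhatched exceeds eggs", bad[1]))
    }
  }
  if (all(c("l1", "adults") %in% names(x))) {
    bad <- which(x$adults > x$l1)
    if (length(bad)) abort(sprintf("row %d: adults exceed L1", bad[1]))
  }
  x
}

#' Read a bedGraph coverage track
#'
#' Headerless TSV `chrom`, `start`, `end`, `depth` with fixed-width windows
#' tiling one chromosome in order.
#'
#' @param path File path.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path) {
  x <- read_tsv_quiet(path, col_names = c("chrom", "start", "end", "depth"),
                      col_types = "cddd")
  if (length(unique(x$chrom)) != 1) {
    abort("coverage track must cover a single chromosome")
  }
  w <- unique(x$end - x$start)
  if (length(w) != 1 || any(x$start != (seq_len(nrow(x)) - 1) * w)) {
    abort("windows must tile the chromosome in order with fixed width")
  }
  coverage_track(x$chrom[1], x$depth, window = w)
}

#' Write / read intervals as BED
#'
#' BED is 0-based half-open, matching the internal convention; no conversion
#' is applied. An optional `name` column becomes the 4th BED field.
#'
#' @param iv Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path File path.
#' @return `write_bed()` returns `iv` invisibly; `read_bed()` returns an
#'   interval tibble.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  cols <- intersect(c("chrom", "start", "end", "name"), names(iv))
  out <- dplyr::arrange(iv[, cols], .data$chrom, .data$start)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(iv)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- read_tsv_quiet(path, col_names = FALSE, col_types = readr::cols())
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  validate_intervals(x)
  as_tibble(x)
}

#' Run the full HI-mapping pipeline
#'
#' Stages, in order: marker-based boundary calling for every strain, optional
#' coverage-track concordance, HI classification against the control strain,
#' interval-contrast locus refinement, and the genome-wide coverage
#' landscape. Inputs may be given as file paths (read with the package's
#' readers) or as in-memory tibbles.
#'
#' @param genotypes Genotype matrix (path or long tibble).
#' @param panel Marker panel (path or tibble).
#' @param phenotypes Phenotype count table (path or tibble) with a `strain`
#'   column covering the introgression strains and the control.
#' @param control Name of the control strain in `phenotypes`.
#' @param schemes Tibble (`strain`, `scheme`) of crossing schemes; strains
#'   missing from it default to `"autosomal_het"` on autosomes and `"x_het"`
#'   on the X.
#' @param chrom_sizes Chromosome sizes (path or tibble; default
#'   [cb4_chromosomes()]).
#' @param coverage Optional named list of coverage tracks (paths or
#'   [coverage_track()]s) keyed by strain, for PCR/NGS concordance.
#' @param zygosity Optional tibble (`strain`, `zygosity`).
#' @param categories Optional tibble (`strain`, `category`) of homozygous
#'   viability classes for the landscape; defaults to `"heterozygous"`.
#' @param out_dir Optional directory: writes `introgressions.bed`,
#'   `landscape.tsv`, `hi_flags.tsv` and `candidate_loci.bed`.
#' @return List: `calls`, `concordance`, `hi_flags`, `refined`, `landscape`.
#' @export
run_pipeline <- function(genotypes, panel, phenotypes, control,
                         schemes = NULL, chrom_sizes = cb4_chromosomes(),
                         coverage = NULL, zygosity = NULL, categories = NULL,
                         out_dir = NULL) {
  if (is.character(panel)) panel <- read_marker_panel(panel)
  if (is.character(genotypes)) genotypes <- read_genotype_matrix(genotypes)
  if (is.character(phenotypes)) phenotypes <- read_phenotype_table(phenotypes)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)

  calls <- call_introgressions(genotypes, panel, chrom_sizes,
                               zygosity = zygosity)
  if (nrow(calls) == 0) warn("boundary calling produced no introgressions")

  concordance <- NULL
  if (!is.null(coverage)) {
    concordance <- purrr::imap_dfr(coverage, function(track, strain) {
      if (is.character(track)) track <- read_coverage(track)
      cov_calls <- call_coverage_introgression(track)
      pcr <- calls[calls$strain == strain, , drop = FALSE]
      if (nrow(pcr) == 0 || nrow(cov_calls) == 0) {
        return(tibble(strain = strain, jaccard = NA_real_,
                      left_offset_bp = NA_real_, right_offset_bp = NA_real_))
      }
      pcr1 <- gintervals(pcr$chrom[1], pcr$outer_start[1], pcr$outer_end[1])
      dplyr::mutate(compare_callsets(pcr1, cov_calls[1, c("chrom", "start", "end")]),
                    strain = strain, .before = 1)
    })
  }

  strains <- unique(calls$strain)
  ctl <- phenotypes[phenotypes$strain == control, , drop = FALSE]
  if (nrow(ctl) == 0) {
    warn("control strain absent from phenotype table; statistical flags unevaluated")
    ctl <- NULL
  }
  scheme_for <- function(s) {
    if (!is.null(schemes) && s %in% schemes$strain) {
      return(schemes$scheme[match(s, schemes$strain)])
    }
    if (any(calls$strain == s & calls$chrom == "X")) "x_het" else "autosomal_het"
  }
  hi_flags <- purrr::map_dfr(strains, function(s) {
    rec <- phenotypes[phenotypes$strain == s, , drop = FALSE]
    if (nrow(rec) == 0) return(NULL)
    call <- classify_line(rec, ctl, scheme = scheme_for(s))
    dplyr::mutate(tidy(call), strain = s, scheme = scheme_for(s), .before = 1)
  })

  # refinement from categorical flags
  label_for <- function(s) {
    f <- hi_flags[hi_flags$strain == s, , drop = FALSE]
    val <- function(fl) isTRUE(f$value[f$flag == fl])
    if (val("male_inviable")) "male_inviable"
    else if (val("male_sterile")) "male_sterile"
    else "male_fertile"
  }
  annotated <- calls %>%
    dplyr::transmute(strain = .data$strain, chrom = .data$chrom,
                     start = .data$outer_start, end = .data$outer_end) %>%
    dplyr::mutate(label = purrr::map_chr(.data$strain, label_for))
  refined <- minimal_locus_map(annotated)

  cats <- calls %>%
    dplyr::transmute(chrom = .data$chrom, start = .data$outer_start,
                     end = .data$outer_end, strain = .data$strain)
  cats$category <- if (is.null(categories)) "heterozygous" else {
    ifelse(is.na(match(cats$strain, categories$strain)), "heterozygous",
           categories$category[match(cats$strain, categories$strain)])
  }
  landscape <- build_landscape(cats[, c("chrom", "start", "end", "category")],
                               chrom_sizes,
                               x_chrom = intersect(c("X", "chrX"),
                                                   chrom_sizes$chrom)[1])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(dplyr::transmute(calls, chrom = .data$chrom,
                               start = .data$outer_start,
                               end = .data$outer_end, name = .data$strain),
              file.path(out_dir, "introgressions.bed"))
    readr::write_tsv(landscape, file.path(out_dir, "landscape.tsv"),
                     progress = FALSE)
    readr::write_tsv(hi_flags, file.path(out_dir, "hi_flags.tsv"),
                     progress = FALSE)
    if (nrow(refined$loci)) {
      write_bed(dplyr::transmute(refined$loci, chrom = .data$chrom,
                                 start = .data$start, end = .data$end,
                                 name = .data$class),
                file.path(out_dir, "candidate_loci.bed"))
    }
  }
  list(calls = calls, concordance = concordance, hi_flags = hi_flags,
       refined = refined, landscape = landscape)
}
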