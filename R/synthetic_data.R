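# Generators for every input the pipeline consumes: serial-backcross
# introgression intervals (Poisson crossovers on a genetic map, selection on
# the GFP marker each generation), multinomial progeny counts under planted
# viability/sterility models, PCR genotype matrices with optional call error
# and assembly-error corruption, and noisy window coverage tracks.

local_seed_if <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
}

#' Backcross simulation configuration
#'
#' @param chrom Chromosome carrying the GFP marker.
#' @param gfp_pos Marker position in bp.
#' @param chrom_sizes Chromosome-size tibble with `map_length` (Morgans);
#'   default [cb4_chromosomes()] (0.5 Morgans per chromosome, uniform
#'   Morgans/bp).
#' @param linkage `"autosomal"` or `"x"`. Both schemes perform one meiosis of
#'   the donor-carrying chromosome per backcross generation (autosomal
#'   introgressions alternate transmitting sex, X-linked ones pass through
#'   carrier females); the segment dynamics are identical.
#' @param generations Backcross generations (default 15).
#' @param suppressors Optional tibble (`start`, `end`, `multiplier`) of
#'   recombination-rate multiplier intervals (0 suppresses crossovers
#'   locally), emulating the recombination-resistant regions seen in real
#'   introgression panels.
#' @param seed Optional integer seed.
#' @return A list of class `backcross_config`.
#' @export
backcross_config <- function(chrom = "X", gfp_pos = NULL,
                             chrom_sizes = cb4_chromosomes(),
                             linkage = if (chrom == "X") "x" else "autosomal",
                             generations = 15, suppressors = NULL,
                             seed = NULL) {
  len <- chrom_length(chrom_sizes, chrom)
  if (is.null(gfp_pos)) gfp_pos <- len / 2
  if (gfp_pos <= 0 || gfp_pos >= len) {
    abort("gfp_pos must lie strictly within the chromosome")
  }
  if (generations < 1) abort("generations must be at least 1")
  if (!is.null(suppressors) && any(suppressors$multiplier < 0)) {
    abort("rate multipliers must be non-negative")
  }
  ml <- chrom_sizes$map_length[match(chrom, chrom_sizes$chrom)]
  structure(list(chrom = chrom, length = len, gfp_pos = gfp_pos,
                 map_length = ml, linkage = linkage,
                 generations = generations, suppressors = suppressors,
                 seed = seed),
            class = "backcross_config")
}

# piecewise-linear bp <-> Morgan map; returns list(to_g, to_bp, total)
genetic_map <- function(cfg) {
  base_rate <- cfg$map_length / cfg$length # Morgans per bp
  breaks <- c(0, cfg$length)
  mult <- c(1)
  if (!is.null(cfg$suppressors) && nrow(cfg$suppressors)) {
    s <- dplyr::arrange(cfg$suppressors, .data$start)
    breaks <- sort(unique(c(0, s$start, s$end, cfg$length)))
    mult <- purrr::map_dbl(breaks[-length(breaks)], function(b) {
      hit <- which(s$start <= b & s$end > b)
      if (length(hit)) s$multiplier[hit[1]] else 1
    })
  }
  widths <- diff(breaks)
  g_knots <- c(0, cumsum(widths * mult * base_rate))
  to_g <- function(x) stats::approx(breaks, g_knots, xout = x, rule = 2)$y
  # inverse: zero-rate segments are flat in genetic space, so the inverse has
  # jump discontinuities there; interpolate only within positive-rate segments
  n_seg <- length(breaks) - 1
  seg <- tibble(bp0 = breaks[-(n_seg + 1)], bp1 = breaks[-1],
                g0 = g_knots[-(n_seg + 1)], g1 = g_knots[-1])
  seg <- seg[seg$g1 > seg$g0, , drop = FALSE]
  total <- g_knots[length(g_knots)]
  chrom_len <- breaks[length(breaks)]
  to_bp <- function(g) {
    vapply(g, function(x) {
      if (x <= 0) return(0)
      if (x >= total) return(chrom_len)
      i <- which(seg$g0 <= x & x <= seg$g1)[1]
      seg$bp0[i] + (x - seg$g0[i]) / (seg$g1[i] - seg$g0[i]) *
        (seg$bp1[i] - seg$bp0[i])
    }, numeric(1))
  }
  list(to_g = to_g, to_bp = to_bp, total = total)
}

#' Simulate a serial-backcross introgression trajectory
#'
#' Each backcross generation performs one meiosis of the donor-segment
#' chromosome against the recipient homolog: crossover count is Poisson on
#' the genetic map (no interference), positions uniform in genetic distance,
#' and the GFP-carrying recombinant is selected (one GFP gamete chosen
#' uniformly, mirroring single-worm selection). The retained donor segment is
#' the previous segment intersected with the crossover-free block containing
#' the GFP position, so the trajectory is nested and non-increasing and every
#' interval contains the GFP locus.
#'
#' @param cfg A [backcross_config()].
#' @return Tibble with columns `generation` (0 = unrecombined F1 chromosome),
#'   `chrom`, `start`, `end`, `size_bp`.
#' @examples
#' simulate_backcross(backcross_config("X", 10e6, seed = 1))
#' @export
simulate_backcross <- function(cfg) {
  local_seed_if(cfg$seed)
  map <- genetic_map(cfg)
  g_gfp <- map$to_g(cfg$gfp_pos)
  a <- 0; b <- cfg$length
  out <- tibble(generation = 0:cfg$generations, chrom = cfg$chrom,
                start = NA_real_, end = NA_real_)
  out$start[1] <- a; out$end[1] <- b
  for (t in seq_len(cfg$generations)) {
    k <- rpois(1, map$total)
    if (k > 0) {
      xo <- sort(runif(k, 0, map$total))
      left <- xo[xo < g_gfp]
      right <- xo[xo > g_gfp]
      if (length(left)) a <- max(a, map$to_bp(max(left)))
      if (length(right)) b <- min(b, map$to_bp(min(right)))
    }
    out$start[t + 1] <- a; out$end[t + 1] <- b
  }
  out$size_bp <- out$end - out$start
  out
}

#' Simulate progeny counts for one or more replicates of a cross
#'
#' Draws pre-selection genotype-by-sex class counts from the exact Mendelian
#' distribution, applies per-class viability (deaths attributed to the
#' embryonic or larval stage per the model), then baseline embryonic
#' lethality and larval arrest, and tabulates survivors by sex and GFP
#' status.
#'
#' @inheritParams expected_progeny
#' @param n Progeny (eggs) per replicate (> 0).
#' @param replicates Number of replicates (default 1).
#' @param emb_baseline,lva_baseline Baseline embryonic-lethality and
#'   larval-arrest rates applied to every class.
#' @param male_x_transmission For segregation-distortion perturbations:
#'   probability that a sperm carries the X (default 0.5, Mendelian). Values
#'   away from 0.5 skew the conceived sex ratio.
#' @param seed Optional integer seed.
#' @return Tibble, one row per replicate: `replicate`, `eggs`, `unhatched`,
#'   `l1`, `adults`, `males_gfp`, `males_nongfp`, `females_gfp`,
#'   `females_nongfp`.
#' @examples
#' simulate_progeny_counts("G/+", "G/+", n = 200, replicates = 5, seed = 1)
#' @export
simulate_progeny_counts <- function(mother, father,
                                    linkage = c("autosomal", "x"),
                                    model = viability_model(), n,
                                    replicates = 1,
                                    emb_baseline = 0, lva_baseline = 0,
                                    male_x_transmission = 0.5, seed = NULL) {
  if (n <= 0) abort("n must be positive")
  linkage <- match.arg(linkage)
  local_seed_if(seed)
  dist <- expected_progeny(mother, father, linkage, model)
  p <- dist$prob_pre
  if (male_x_transmission != 0.5) {
    w <- ifelse(dist$sex == "male", (1 - male_x_transmission) / 0.5,
                male_x_transmission / 0.5)
    p <- p * w / sum(p * w)
  }
  stage <- purrr::map2_chr(dist$genotype, dist$sex,
                           function(g, s) model_lookup(model, g, s, "stage"))
  purrr::map_dfr(seq_len(replicates), function(r) {
    counts <- as.vector(rmultinom(1, n, p))
    # embryonic stage: class lethality then baseline
    emb_class <- rbinom(length(counts),
                        ifelse(stage == "emb", counts, 0L),
                        1 - dist$survival)
    after_emb_class <- counts - emb_class
    emb_base <- rbinom(length(counts), after_emb_class, emb_baseline)
    hatched <- after_emb_class - emb_base
    # larval stage
    lva_class <- rbinom(length(counts),
                        ifelse(stage == "larval", hatched, 0L),
                        1 - dist$survival)
    after_lva_class <- hatched - lva_class
    lva_base <- rbinom(length(counts), after_lva_class, lva_baseline)
    adults <- after_lva_class - lva_base
    tab <- function(sex, gfp) sum(adults[dist$sex == sex & dist$gfp == gfp])
    tibble(replicate = r, eggs = n,
           unhatched = sum(emb_class + emb_base),
           l1 = n - sum(emb_class + emb_base),
           adults = sum(adults),
           males_gfp = tab("male", TRUE),
           males_nongfp = tab("male", FALSE),
           females_gfp = tab("female", TRUE),
           females_nongfp = tab("female", FALSE))
  })
}

#' Simulate a PCR genotype matrix from true introgression intervals
#'
#' A marker is truly `"+"` when its amplicon midpoint lies inside the
#' strain's introgression interval. Markers named in `assembly_errors` have
#' their truth inverted (the amplicon actually maps elsewhere in the genome,
#' reproducing the signature of a mis-assembled primer), then independent
#' call flips are applied at `error_rate`.
#'
#' @param truths Tibble (`strain`, `chrom`, `start`, `end`) of true
#'   introgression intervals.
#' @param panel A [marker_panel()] covering the chromosome(s).
#' @param error_rate Per-call flip probability (default 0).
#' @param assembly_errors Character vector of marker names to corrupt.
#' @param na_rate Per-call probability of a failed reaction (`NA`).
#' @param seed Optional integer seed.
#' @return Long genotype tibble (`strain`, `marker`, `call`).
#' @export
simulate_genotype_matrix <- function(truths, panel, error_rate = 0,
                                     assembly_errors = character(),
                                     na_rate = 0, seed = NULL) {
  local_seed_if(seed)
  bad <- setdiff(assembly_errors, panel$marker)
  if (length(bad)) {
    abort(sprintf("assembly_errors not in panel: %s", paste(bad, collapse = ", ")))
  }
  purrr::pmap_dfr(truths, function(strain, chrom, start, end, ...) {
    pm <- panel[panel$chrom == chrom, , drop = FALSE]
    truth <- pm$mid >= start & pm$mid < end
    truth[pm$marker %in% assembly_errors] <- !truth[pm$marker %in% assembly_errors]
    flip <- runif(nrow(pm)) < error_rate
    call <- ifelse(xor(truth, flip), "+", "-")
    call[runif(nrow(pm)) < na_rate] <- NA_character_
    tibble(strain = strain, marker = pm$marker, call = call)
  })
}

#' Simulate a windowed coverage track with a planted introgression
#'
#' Depth is lognormal multiplicative noise around a baseline, multiplied by
#' `fold` inside the planted interval (window assignment by midpoint).
#'
#' @param truth One-row interval tibble (`chrom`, `start`, `end`), or `NULL`
#'   for a uniform track.
#' @param chrom_length Chromosome length in bp.
#' @param window Window size in bp (default 10,000).
#' @param baseline_depth Baseline mean depth (default 30).
#' @param fold Enrichment inside the planted interval (default 5.5).
#' @param sigma Lognormal noise sigma (default 0.2; 0 gives an exact step).
#' @param seed Optional integer seed.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(truth, chrom_length, window = 10000,
                              baseline_depth = 30, fold = 5.5, sigma = 0.2,
                              seed = NULL) {
  if (fold <= 1) abort("fold must exceed 1")
  local_seed_if(seed)
  n <- ceiling(chrom_length / window)
  mid <- (seq_len(n) - 0.5) * window
  mu <- rep(baseline_depth, n)
  chrom <- "chr"
  if (!is.null(truth)) {
    stopifnot(nrow(truth) == 1)
    chrom <- truth$chrom
    inside <- mid >= truth$start & mid < truth$end
    mu[inside] <- mu[inside] * fold
  }
  noise <- if (sigma == 0) rep(1, n) else exp(rnorm(n, 0, sigma))
  coverage_track(chrom, mu * noise, window = window)
}

#' Planted hybrid-incompatibility model
#'
#' @param loci Tibble of planted loci: `chrom`, `start`, `end`, `effect`
#'   (`"emb_lethal"`, `"larval_arrest"`, `"male_sterile"`, `"male_inviable"`,
#'   `"fertility_shift"`), `penetrance` in `[0, 1]`, `dominance`
#'   (`"recessive"`/`"dominant"`) and, for `fertility_shift`,
#'   `brood_multiplier`. `NULL` for a null model (no HI).
#' @param emb_baseline Baseline embryonic lethality (default 0.10, a
#'   realistic inbred-recipient value; see the methods vignette).
#' @param lva_baseline Baseline larval arrest (default 0.141, the rate of the
#'   inbred *C. nigoni* reference strain).
#' @param brood_mean Mean 72-hour brood size (default 150, Poisson).
#' @return A list of class `hi_model`.
#' @export
hi_model <- function(loci = NULL, emb_baseline = 0.10, lva_baseline = 0.141,
                     brood_mean = 150) {
  if (is.null(loci)) {
    loci <- tibble(chrom = character(), start = numeric(), end = numeric(),
                   effect = character(), penetrance = numeric(),
                   dominance = character(), brood_multiplier = numeric())
  }
  if (!"brood_multiplier" %in% names(loci)) loci$brood_multiplier <- NA_real_
  if (!"dominance" %in% names(loci)) loci$dominance <- "recessive"
  if (nrow(loci) && any(loci$penetrance < 0 | loci$penetrance > 1)) {
    abort("penetrances must lie in [0, 1]")
  }
  structure(list(loci = loci, emb_baseline = emb_baseline,
                 lva_baseline = lva_baseline, brood_mean = brood_mean),
            class = "hi_model")
}

# viability model + fertility consequences for one line given covered loci
line_effects <- function(covered, linkage) {
  surv <- tibble(genotype = character(), sex = character(),
                 survival = numeric(), stage = character())
  male_sterile <- FALSE
  brood_multiplier <- 1
  affected <- function(effect, dominance) {
    # genotype classes in the assay cross expressing the effect
    if (dominance == "dominant") {
      if (linkage == "x") c("G/G", "G/+", "G/0") else c("G/G", "G/+")
    } else {
      if (linkage == "x") c("G/G", "G/0") else "G/G"
    }
  }
  for (i in seq_len(nrow(covered))) {
    loc <- covered[i, ]
    gts <- affected(loc$effect, loc$dominance)
    if (loc$effect %in% c("emb_lethal", "larval_arrest")) {
      surv <- dplyr::bind_rows(surv, tibble(
        genotype = gts, sex = "both", survival = 1 - loc$penetrance,
        stage = if (loc$effect == "emb_lethal") "emb" else "larval"))
    } else if (loc$effect == "male_inviable") {
      male_gts <- intersect(gts, if (linkage == "x") "G/0" else c("G/G", "G/+"))
      surv <- dplyr::bind_rows(surv, tibble(
        genotype = male_gts, sex = "male", survival = 1 - loc$penetrance,
        stage = "emb"))
    } else if (loc$effect == "male_sterile") {
      male_sterile <- TRUE
    } else if (loc$effect == "fertility_shift") {
      brood_multiplier <- brood_multiplier * loc$brood_multiplier
    }
  }
  # resolve duplicate (genotype, sex) entries: independent effects multiply
  if (nrow(surv)) {
    surv <- surv %>%
      dplyr::group_by(.data$genotype, .data$sex, .data$stage) %>%
      dplyr::summarise(survival = prod(.data$survival), .groups = "drop") %>%
      dplyr::select("genotype", "sex", "survival", "stage")
  }
  list(survival = surv, male_sterile = male_sterile,
       brood_multiplier = brood_multiplier)
}

#' Simulate a full HI-mapping dataset with planted truth
#'
#' Generates `n_lines` introgression lines: each line's introgression
#' interval comes from [simulate_backcross()] on a randomly chosen
#' chromosome, its phenotype counts from [simulate_progeny_counts()] under
#' the viability consequences of the planted loci its introgression covers
#' (recessive effects are expressed only in homozygous/hemizygous classes of
#' the assay cross), plus brood-size replicates and a male-direction test
#' cross outcome. A control record (recipient-strain inbreeding cross) and
#' per-line truth labels are emitted for recovery scoring.
#'
#' @param model An [hi_model()].
#' @param n_lines Number of lines.
#' @param replicates Viability-assay replicates per line (default 5).
#' @param n_per_rep Eggs per replicate (default 200).
#' @param brood_replicates Brood-size replicates (default 10).
#' @param chrom_sizes Chromosome-size tibble with `map_length`.
#' @param chroms Chromosomes lines are drawn on (default all).
#' @param generations Backcross generations (default 15).
#' @param seed Optional integer seed.
#' @return List of class `hi_dataset`: `lines` (strain, chrom, start, end,
#'   linkage, scheme, truth flags), `phenotypes` (per-line replicate counts),
#'   `broods` (per-line brood replicates), `control`, `control_broods`,
#'   `model`.
#' @export
simulate_hi_dataset <- function(model, n_lines, replicates = 5,
                                n_per_rep = 200, brood_replicates = 10,
                                chrom_sizes = cb4_chromosomes(),
                                chroms = chrom_sizes$chrom, generations = 15,
                                seed = NULL) {
  local_seed_if(seed)
  control <- simulate_progeny_counts(
    "+/+", "+/+", "autosomal", n = n_per_rep, replicates = replicates,
    emb_baseline = model$emb_baseline, lva_baseline = model$lva_baseline)
  control_broods <- tibble(replicate = seq_len(brood_replicates),
                           brood = rpois(brood_replicates, model$brood_mean))
  lines <- list(); phenos <- list(); broods <- list()
  for (i in seq_len(n_lines)) {
    strain <- sprintf("SIM%04d", i)
    chrom <- sample(chroms, 1)
    len <- chrom_length(chrom_sizes, chrom)
    cfg <- backcross_config(chrom, gfp_pos = runif(1, 0.05, 0.95) * len,
                            chrom_sizes = chrom_sizes,
                            generations = generations)
    traj <- simulate_backcross(cfg)
    seg <- traj[nrow(traj), ]
    linkage <- cfg$linkage
    scheme <- if (linkage == "x") "x_het" else "autosomal_het"
    covered <- model$loci %>%
      dplyr::filter(.data$chrom == seg$chrom, .data$start < seg$end,
                    .data$end > seg$start)
    eff <- line_effects(covered, linkage)
    vm <- viability_model(survival = eff$survival)
    mother <- "G/+"
    father <- if (linkage == "x") "+/0" else "G/+"
    ph <- simulate_progeny_counts(mother, father, linkage, vm, n = n_per_rep,
                                  replicates = replicates,
                                  emb_baseline = model$emb_baseline,
                                  lva_baseline = model$lva_baseline)
    br <- tibble(replicate = seq_len(brood_replicates),
                 brood = rpois(brood_replicates,
                               model$brood_mean * eff$brood_multiplier))
    male_cross <- if (eff$male_sterile) 0 else rpois(1, n_per_rep)
    lines[[i]] <- tibble(
      strain = strain, chrom = seg$chrom, start = seg$start, end = seg$end,
      linkage = linkage, scheme = scheme,
      male_cross_progeny = male_cross,
      truth_male_sterile = eff$male_sterile,
      truth_male_inviable = any(covered$effect == "male_inviable") &&
        linkage == "x",
      truth_emb_lethal = any(covered$effect == "emb_lethal"),
      truth_larval_arrest = any(covered$effect == "larval_arrest"),
      truth_fertility_shift = any(covered$effect == "fertility_shift"))
    phenos[[i]] <- dplyr::mutate(ph, strain = strain, .before = 1)
    broods[[i]] <- dplyr::mutate(br, strain = strain, .before = 1)
  }
  structure(list(lines = dplyr::bind_rows(lines),
                 phenotypes = dplyr::bind_rows(phenos),
                 broods = dplyr::bind_rows(broods),
                 control = control, control_broods = control_broods,
                 model = model),
            class = "hi_dataset")
}

#' Classify every line of a simulated (or assembled) HI dataset
#'
#' Maps [classify_line()] over the dataset's lines, joining brood replicates
#' into each record.
#'
#' @param dataset An `hi_dataset` (see [simulate_hi_dataset()]).
#' @return Tibble: one row per strain and flag, with the flag columns of
#'   [classify_line()].
#' @export
classify_dataset <- function(dataset) {
  control <- dataset$control
  control$brood <- NA_real_
  control <- dplyr::bind_rows(
    control, tibble(brood = dataset$control_broods$brood))
  purrr::map_dfr(seq_len(nrow(dataset$lines)), function(i) {
    meta <- dataset$lines[i, ]
    rec <- dataset$phenotypes[dataset$phenotypes$strain == meta$strain, ]
    br <- dataset$broods[dataset$broods$strain == meta$strain, ]
    rec$brood <- NA_real_
    rec <- dplyr::bind_rows(rec, tibble(brood = br$brood))
    call <- classify_line(rec, control, scheme = meta$scheme,
                          male_cross_progeny = meta$male_cross_progeny,
                          reciprocal_progeny = sum(rec$adults, na.rm = TRUE))
    dplyr::mutate(tidy(call), strain = meta$strain, .before = 1)
  })
}
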