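UNIT_CLASSES <- c("snoRNA", "CUT", "SUT", "XUT", "NAPC", "PC")
KNOWN_FACTORS <- c("PolII_total", "PolII_Ser2P", "PolII_Ser5P", "Nrd1",
                   "Pcf11", "RNADNA_hybrid")

#' Default genotype modifier table
#'
#' Per-genotype multipliers applied to the planted terminator hazards and
#' CTD state of responsive units. Columns: `prox_mult` (proximal NBS-element
#' hazard), `distal_mult` (distal terminator-element hazard), `pas_mult`
#' (poly(A)-site hazard), `pause_mult` (dwell-time multiplier applied in the
#' pause zone downstream of the proximal NBS), `ser2_mult` (CTD Ser2-P
#' amplitude). Wild type is all ones. The mutant rows encode the qualitative
#' phenotypes of the classic termination mutants: CID-compromised pcf11
#' alleles lose most distal NNS-terminator activity and Ser2-P, the
#' cleavage-defective allele loses PAS activity only, sen1-1 combines a
#' terminator defect with strong downstream pausing, and nrd1-102 weakens
#' the proximal element.
#'
#' @return Data frame with one row per genotype.
#' @export
default_genotypes <- function() {
  data.frame(
    genotype    = c("WT", "pcf11-9", "pcf11-13", "pcf11-2", "sen1-1",
                    "nrd1-102", "nab3-11"),
    prox_mult   = c(1, 0.5, 0.7, 1, 0.6, 0.3, 0.35),
    distal_mult = c(1, 0.2, 0.15, 1, 0.2, 0.6, 0.6),
    pas_mult    = c(1, 0.3, 1, 0.1, 1, 1, 1),
    pause_mult  = c(1, 1, 2, 1, 5, 1, 1),
    ser2_mult   = c(1, 0.5, 0.2, 1, 0.8, 1, 1),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Describes the stated world of the synthetic genome: chromosome sizes,
#' per-class unit counts and geometry, the elongation-termination hazard
#' model, genotype modifiers, factor recruitment kernels, and the Poisson
#' sequencing model. Hazards are per-nt probabilities in `[0, 1)` at the
#' base elongation speed; growth at 37 degrees scales speed by
#' `temp37_speed_mult`, and per-nt hazards are re-derived as
#' `1 - (1 - h)^(1/mult)` (hazard per unit time, less exposure per nt at
#' higher speed), which shifts termination downstream at 37 degrees.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (nt).
#' @param n_units Named integer vector of unit counts per class
#'   (snoRNA, CUT, SUT, XUT, NAPC, PC).
#' @param unit_length Named list of length-2 ranges (nt) per class.
#' @param spacing Range of inter-unit gaps (nt); must clear the downstream
#'   flank so neighbouring signals do not collide.
#' @param strand_prob Probability that a unit is placed on the plus strand.
#' @param init_rate Range of per-unit initiation rates (events per unit
#'   time); drawn uniformly per unit.
#' @param speed Base elongation speed (nt per unit time) at 25 degrees.
#' @param temp37_speed_mult Speed multiplier at 37 degrees (>= 1).
#' @param flank Downstream flank (nt) simulated past each unit end.
#' @param elements Hazard element geometry, each a list
#'   `(offset, width, hazard)` with offsets in nt relative to the unit's
#'   terminator anchor (snoRNA mature 3' end; a point ~350 nt before the
#'   annotated end for CUT/SUT/XUT; ~150 nt past the TSS for NAPC genes).
#'   Defaults: proximal NBS window `[-20, +40)` (so the NBS center sits at
#'   +10, matching Nrd1's observed -20..+40 recruitment), distal window
#'   `[+150, +350)`, PAS `[+430, +460)`.
#' @param pause Pause zone `(offset, width)` relative to the terminator
#'   anchor; dwell time is multiplied by the genotype's `pause_mult` there.
#' @param distal_prob,pas_prob Named per-class probabilities that a unit
#'   carries a distal element / a PAS.
#' @param defect_prob Named per-class fractions of units whose terminator is
#'   mutant-responsive; exactly `round(p * n)` units per class are planted
#'   responsive so the planted rate is deterministic.
#' @param genotypes Genotype modifier table, see [default_genotypes()].
#' @param kernels Factor recruitment kernels: named list of
#'   `(offset, sd, gain)` Gaussians. Offsets are relative to the unit's NBS
#'   center (Nrd1 at the NBS, Pcf11 ~140 nt downstream).
#' @param ser5_tau,ser2_tau Exponential length scales (nt from TSS) of the
#'   Ser5-P decay and Ser2-P rise.
#' @param depth Sequencing depth scale (expected counts per nt at a
#'   plateau-occupancy position for a unit of initiation rate 1).
#' @param background Uniform background rate (expected counts per nt).
#' @param defect_fraction A unit is planted defective for a genotype when
#'   its modified terminator-zone cumulative hazard falls below this
#'   fraction of the wild-type value (default 0.5).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    chrom_lengths = c(chrI = 350000L, chrII = 350000L),
    n_units = c(snoRNA = 50L, CUT = 50L, SUT = 50L, XUT = 50L,
                NAPC = 0L, PC = 0L),
    unit_length = list(snoRNA = c(500L, 700L), CUT = c(600L, 1200L),
                       SUT = c(600L, 1200L), XUT = c(600L, 1200L),
                       NAPC = c(1000L, 2000L), PC = c(1000L, 2500L)),
    spacing = c(1800L, 2600L),
    strand_prob = 0.5,
    init_rate = c(0.5, 1.5),
    speed = 1,
    temp37_speed_mult = 1.5,
    flank = 1000L,
    elements = list(prox = list(offset = -20L, width = 60L, hazard = 0.008),
                    distal = list(offset = 150L, width = 200L,
                                  hazard = 0.006),
                    pas = list(offset = 430L, width = 30L, hazard = 0.03)),
    pause = list(offset = 60L, width = 400L),
    distal_prob = c(snoRNA = 1, CUT = 0.8, SUT = 0.8, XUT = 0.8,
                    NAPC = 1, PC = 0),
    pas_prob = c(snoRNA = 0.5, CUT = 0.7, SUT = 0.9, XUT = 0.9,
                 NAPC = 0.8, PC = 1),
    defect_prob = c(snoRNA = 0.75, CUT = 0.65, SUT = 0.70, XUT = 0.70,
                    NAPC = 0.73, PC = 0),
    genotypes = default_genotypes(),
    kernels = list(Nrd1 = list(offset = 0L, sd = 60, gain = 1),
                   Pcf11 = list(offset = 140L, sd = 80, gain = 1)),
    ser5_tau = 500, ser2_tau = 800,
    depth = 30, background = 0.2,
    defect_fraction = 0.5,
    seed = 1L) {
  # tolerate JSON-deserialized inputs (named lists in place of vectors)
  chrom_lengths <- unlist(chrom_lengths)
  n_units <- unlist(n_units)
  spacing <- unlist(spacing)
  init_rate <- unlist(init_rate)
  distal_prob <- unlist(distal_prob)
  pas_prob <- unlist(pas_prob)
  defect_prob <- unlist(defect_prob)
  genotypes <- as.data.frame(genotypes)
  unit_length <- lapply(unit_length, unlist)
  cfg <- list(chrom_lengths = chrom_lengths,
              n_units = n_units[UNIT_CLASSES[UNIT_CLASSES %in% names(n_units)]],
              unit_length = unit_length, spacing = spacing,
              strand_prob = strand_prob, init_rate = init_rate,
              speed = speed, temp37_speed_mult = temp37_speed_mult,
              flank = as.integer(flank), elements = elements, pause = pause,
              distal_prob = distal_prob, pas_prob = pas_prob,
              defect_prob = defect_prob, genotypes = genotypes,
              kernels = kernels, ser5_tau = ser5_tau, ser2_tau = ser2_tau,
              depth = depth, background = background,
              defect_fraction = defect_fraction, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (any(cfg$chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(cfg$n_units < 0)) stop("unit counts must be >= 0")
  if (cfg$speed <= 0) stop("speed must be > 0")
  if (cfg$temp37_speed_mult < 1) stop("temp37_speed_mult must be >= 1")
  if (cfg$depth < 0 || cfg$background < 0)
    stop("depth and background must be >= 0")
  for (nm in names(cfg$elements)) {
    h <- cfg$elements[[nm]]$hazard
    if (h < 0 || h >= 1)
      stop("per-nt hazards must lie in [0, 1): ", nm)
    if (cfg$elements[[nm]]$width < 1) stop("element width must be >= 1")
  }
  mult_cols <- c("prox_mult", "distal_mult", "pas_mult", "pause_mult",
                 "ser2_mult")
  if (!all(c("genotype", mult_cols) %in% names(cfg$genotypes)))
    stop("genotype table must have columns genotype, ",
         paste(mult_cols, collapse = ", "))
  if (any(as.matrix(cfg$genotypes[mult_cols]) < 0))
    stop("genotype multipliers must be >= 0")
  if (cfg$defect_fraction <= 0 || cfg$defect_fraction >= 1)
    stop("defect_fraction must lie in (0, 1)")
  invisible(cfg)
}

genotype_row <- function(cfg, genotype) {
  i <- match(genotype, cfg$genotypes$genotype)
  if (is.na(i))
    stop(sprintf("genotype '%s' missing from the modifier table (known: %s)",
                 genotype, paste(cfg$genotypes$genotype, collapse = ", ")))
  cfg$genotypes[i, ]
}

# Terminator-anchor position relative to the TSS, given class and length.
# snoRNA anchor at the mature 3' end; CUT/SUT/XUT terminator zone ends at
# the annotated 3' end; NAPC attenuator sits just past the TSS.
term_anchor_rel <- function(unit_class, length, mature_rel = NA_integer_) {
  switch(unit_class,
         snoRNA = mature_rel,
         CUT = , SUT = , XUT = length - 351L,
         NAPC = 150L,
         PC = NA_integer_,
         stop("unknown unit class: ", unit_class))
}

#' Generate a toy annotation with planted ground truth
#'
#' Places the requested number of units per class on the configured
#' chromosomes with random strands, lengths and inter-unit gaps, all drawn
#' deterministically from `config$seed`. Non-overlapping placement with a
#' full downstream flank of clearance is guaranteed; a chromosome set too
#' short for the request raises an error naming the unit class that failed.
#'
#' Besides the public annotation fields (coordinates, TSS, snoRNA mature 3'
#' end, NBS center, optional PAS) the returned frame carries the planted
#' generator state used by [simulation_truth()]: element presence
#' (`has_distal`, `has_pas`), mutant responsiveness (`responsive`; exactly
#' `round(defect_prob * n)` per class) and the per-unit initiation rate.
#'
#' @param config A [simulation_config()].
#' @return List with `units` (data frame, one row per unit) and
#'   `chrom_sizes`.
#' @export
make_toy_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  classes <- rep(names(config$n_units), times = config$n_units)
  sizes <- config$chrom_lengths
  empty <- data.frame(id = character(), unit_class = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      tss = integer(), mature_end = integer(),
                      nbs_center = integer(), pas_position = integer(),
                      term_anchor = integer(), has_distal = logical(),
                      has_pas = logical(), responsive = logical(),
                      init_rate = numeric())
  if (!length(classes))
    return(list(units = empty, chrom_sizes = sizes))
  classes <- sample(classes)
  margin <- config$flank + 700L

  responsive_pool <- lapply(names(config$n_units), function(cl) {
    n <- config$n_units[[cl]]
    k <- round((config$defect_prob[[cl]] %||% 0) * n)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  })
  names(responsive_pool) <- names(config$n_units)
  taken <- stats::setNames(rep(0L, length(config$n_units)),
                           names(config$n_units))

  rows <- vector("list", length(classes))
  chrom_i <- 1L
  cursor <- 400L
  for (i in seq_along(classes)) {
    cl <- classes[i]
    L <- as.integer(round(stats::runif(1, config$unit_length[[cl]][1],
                                       config$unit_length[[cl]][2])))
    if (cl == "snoRNA") {
      mature_rel <- as.integer(round(stats::runif(1, 100, 300)))
      L <- mature_rel + 400L
    } else mature_rel <- NA_integer_
    gap <- as.integer(round(stats::runif(1, config$spacing[1],
                                         config$spacing[2])))
    repeat {
      start <- cursor + gap
      if (start + L + margin <= sizes[[chrom_i]]) break
      chrom_i <- chrom_i + 1L
      cursor <- 400L
      if (chrom_i > length(sizes))
        stop(sprintf(
          "chromosomes too short: could not place unit %d (class %s)",
          i, cl))
    }
    strand <- if (stats::runif(1) < config$strand_prob) "+" else "-"
    end <- start + L
    tss <- if (strand == "+") start else end - 1L
    rel2gen <- function(r) {
      if (is.na(r)) return(NA_integer_)
      as.integer(if (strand == "+") tss + r else tss - r)
    }
    ta_rel <- term_anchor_rel(cl, L, mature_rel)
    nbs_rel <- if (is.na(ta_rel)) NA_integer_ else ta_rel + 10L
    has_distal <- !is.na(ta_rel) &&
      stats::runif(1) < (config$distal_prob[[cl]] %||% 0)
    has_pas <- stats::runif(1) < (config$pas_prob[[cl]] %||% 0)
    pas_rel <- if (!has_pas) NA_integer_
               else if (cl == "PC") L - 30L
               else ta_rel + config$elements$pas$offset
    taken[cl] <- taken[cl] + 1L
    rows[[i]] <- data.frame(
      id = sprintf("%s_%03d", cl, taken[cl]), unit_class = cl,
      chrom = names(sizes)[chrom_i], start = start, end = end,
      strand = strand, tss = tss,
      mature_end = rel2gen(if (cl == "snoRNA") mature_rel else NA_integer_),
      nbs_center = rel2gen(nbs_rel),
      pas_position = rel2gen(pas_rel),
      term_anchor = rel2gen(ta_rel),
      has_distal = has_distal, has_pas = has_pas,
      responsive = responsive_pool[[cl]][taken[cl]],
      init_rate = stats::runif(1, config$init_rate[1], config$init_rate[2]))
    cursor <- end
  }
  units <- do.call(rbind, rows)
  rownames(units) <- NULL
  list(units = units, chrom_sizes = sizes)
}

# Per-nt hazard and dwell profiles over the transcript window
# [0, L + flank) for one unit under one genotype/temperature.
hazard_dwell <- function(unit, config, genotype = "WT", temperature = 25) {
  g <- genotype_row(config, genotype)
  L <- unit$end - unit$start
  n <- L + config$flank
  h <- numeric(n)
  dwell_mult <- rep(1, n)
  resp <- isTRUE(unit$responsive)
  eff <- function(mult) if (resp) mult else 1
  ta <- unit_rel(unit, unit$term_anchor)
  put_hazard <- function(offset_abs, width, hz) {
    if (is.na(offset_abs) || hz <= 0) return()
    idx <- seq.int(offset_abs, length.out = width) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    h[idx] <<- h[idx] + hz
  }
  el <- config$elements
  if (!is.na(ta)) {
    put_hazard(ta + el$prox$offset, el$prox$width,
               el$prox$hazard * eff(g$prox_mult))
    if (isTRUE(unit$has_distal))
      put_hazard(ta + el$distal$offset, el$distal$width,
                 el$distal$hazard * eff(g$distal_mult))
    pm <- eff(g$pause_mult)
    if (pm != 1) {
      idx <- seq.int(ta + config$pause$offset,
                     length.out = config$pause$width) + 1L
      idx <- idx[idx >= 1L & idx <= n]
      dwell_mult[idx] <- pm
    }
  }
  if (isTRUE(unit$has_pas)) {
    pas_rel <- unit_rel(unit, unit$pas_position)
    put_hazard(pas_rel, el$pas$width, el$pas$hazard * eff(g$pas_mult))
  }
  h <- pmin(h, 1 - 1e-12)
  speed <- config$speed *
    (if (temperature >= 37) config$temp37_speed_mult else 1)
  # hazards are per unit time at base speed: faster Pol II sees less
  # exposure per nt, so the per-nt hazard drops and termination shifts 3'
  h <- 1 - (1 - h)^(config$speed / speed)
  dwell <- dwell_mult / speed
  list(hazard = h, dwell = dwell, length = L, n = n)
}

# Transcript-orientation coordinate of a genomic base relative to the TSS.
unit_rel <- function(unit, genomic) {
  if (is.null(genomic) || is.na(genomic)) return(NA_integer_)
  as.integer(if (identical(unit$strand, "-")) unit$tss - genomic
             else genomic - unit$tss)
}

#' Expected occupancy from per-nt hazards and dwell times
#'
#' The closed-form occupancy model: a polymerase initiates at position 1,
#' terminates at position i with per-nt probability `hazard[i]`, and while
#' present contributes its local dwell time. Expected density at x is
#' `init_rate * S(x) * dwell(x)` with survival
#' `S(x) = prod_{i < x} (1 - hazard[i])`. Density is flat upstream of the
#' first hazard element and non-increasing wherever dwell is constant.
#'
#' @param hazard Per-nt termination probabilities in `[0, 1)`.
#' @param dwell Per-nt dwell times (> 0), same length as `hazard`.
#' @param init_rate Initiation rate (scales the whole profile).
#' @return Numeric vector of expected densities.
#' @export
expected_occupancy <- function(hazard, dwell, init_rate = 1) {
  if (length(hazard) != length(dwell))
    stop("hazard and dwell must have equal length")
  if (any(hazard < 0) || any(hazard >= 1))
    stop("hazards must lie in [0, 1)")
  if (any(dwell <= 0)) stop("dwell times must be > 0")
  if (init_rate < 0) stop("init_rate must be >= 0")
  surv <- exp(c(0, cumsum(log1p(-hazard)))[seq_along(hazard)])
  init_rate * surv * dwell
}

#' Expected occupancy profile for one annotated unit
#'
#' Convenience wrapper around [expected_occupancy()] that builds the hazard
#' and dwell profiles of a unit under a genotype/temperature from the
#' configuration (element geometry, genotype modifiers, temperature speed
#' scaling) and returns the profile in transcript orientation over
#' `[TSS, unit end + flank)`.
#'
#' @param unit One annotation row.
#' @param config A [simulation_config()].
#' @param genotype Genotype label present in the modifier table.
#' @param temperature 25 or 37.
#' @return Data frame with `rel` (nt from TSS), `genomic` (0-based base)
#'   and `density`.
#' @export
unit_expected_occupancy <- function(unit, config, genotype = "WT",
                                    temperature = 25) {
  hd <- hazard_dwell(unit, config, genotype, temperature)
  dens <- expected_occupancy(hd$hazard, hd$dwell, unit$init_rate %||% 1)
  rel <- seq_len(hd$n) - 1L
  genomic <- if (identical(unit$strand, "-")) unit$tss - rel else
    unit$tss + rel
  data.frame(rel = rel, genomic = genomic, density = dens)
}

#' Monte-Carlo occupancy oracle
#'
#' Simulates individual polymerase trajectories through a hazard profile:
#' each trajectory advances base by base, stopping at position i with
#' probability `hazard[i]`, and deposits its dwell time at every position it
#' reaches. The average over trajectories converges to
#' [expected_occupancy()]; it is kept as an independent stochastic check of
#' the closed form (and is the substrate for kinetics experiments).
#'
#' @inheritParams expected_occupancy
#' @param n_traj Number of trajectories.
#' @param seed Optional seed.
#' @return List with `occupancy` (mean deposited dwell per position) and
#'   `reach` (number of trajectories reaching each position).
#' @export
mc_occupancy <- function(hazard, dwell, n_traj = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(hazard < 0) || any(hazard >= 1)) stop("hazards must lie in [0, 1)")
  n <- length(hazard)
  # survival *before* x: S_prev[x] = prod_{i<x}(1-h_i); trajectory with
  # uniform u reaches exactly the positions x with u < S_prev[x]
  cl <- cumsum(log1p(-hazard))
  u <- stats::runif(n_traj)
  v <- log(u)
  if (n > 1L) {
    rc <- rev(cl[seq_len(n - 1L)])          # increasing
    cnt <- (n - 1L) - findInterval(v, rc)   # #{j < n : cl_j > v}
    m <- 1L + cnt
  } else m <- rep(1L, n_traj)
  tab <- tabulate(m, nbins = n)
  reach <- n_traj - c(0L, cumsum(tab)[-n])
  list(occupancy = reach / n_traj * dwell, reach = reach)
}

#' Planted simulation truth
#'
#' For every unit x genotype x temperature combination, reports the
#' modified cumulative hazards of the terminator elements, the pause-dwell
#' multiplier, the closed-form expected readthrough fraction (survival past
#' the distal terminator window), and the planted defect flag: a unit is
#' planted defective when its terminator-zone cumulative hazard under the
#' mutant drops below `defect_fraction` of the wild-type value at the same
#' temperature. All quantities are deterministic functions of the
#' configuration and annotation.
#'
#' @param config A [simulation_config()].
#' @param units Annotation frame from [make_toy_annotation()].
#' @param genotypes Character vector of genotype labels.
#' @param temperatures Numeric vector (subset of 25, 37).
#' @return Data frame, one row per unit x genotype x temperature.
#' @export
simulation_truth <- function(config, units, genotypes = "WT",
                             temperatures = 25) {
  grid <- expand.grid(gi = seq_along(genotypes), ti =
                        seq_along(temperatures),
                      ui = seq_len(nrow(units)))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    u <- units[grid$ui[r], ]
    gt <- genotypes[grid$gi[r]]
    tp <- temperatures[grid$ti[r]]
    hd <- hazard_dwell(u, config, gt, tp)
    hd_wt <- hazard_dwell(u, config, "WT", tp)
    cum <- function(x) -sum(log1p(-x))       # cumulative hazard
    ta <- unit_rel(u, u$term_anchor)
    zone <- terminator_zone(u, config)
    cz <- function(h) if (is.null(zone)) 0 else
      cum(h[seq.int(zone[1], zone[2]) + 1L])
    ch_mut <- cz(hd$hazard)
    ch_wt <- cz(hd_wt$hazard)
    dist_end <- if (!is.na(ta))
      min(ta + config$elements$distal$offset + config$elements$distal$width,
          hd$n) else hd$n
    surv_past <- function(h) exp(sum(log1p(-h[seq_len(dist_end)])))
    data.frame(
      id = u$id, unit_class = u$unit_class, genotype = gt,
      temperature = tp, responsive = u$responsive,
      cum_hazard = ch_mut, cum_hazard_wt = ch_wt,
      pause_mult = if (isTRUE(u$responsive))
        genotype_row(config, gt)$pause_mult else 1,
      expected_readthrough = surv_past(hd$hazard),
      expected_readthrough_wt = surv_past(hd_wt$hazard),
      planted_defect = ch_wt > 0 &&
        ch_mut < config$defect_fraction * ch_wt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Transcript-relative [start, end] (inclusive) of the terminator zone:
# proximal element through distal element / PAS, whichever extends furthest.
terminator_zone <- function(unit, config) {
  ta <- unit_rel(unit, unit$term_anchor)
  el <- config$elements
  pas_rel <- if (isTRUE(unit$has_pas)) unit_rel(unit, unit$pas_position)
             else NA_integer_
  if (is.na(ta)) {
    if (is.na(pas_rel)) return(NULL)
    return(c(pas_rel, pas_rel + el$pas$width - 1L))
  }
  zstart <- ta + el$prox$offset
  zend <- ta + el$prox$offset + el$prox$width - 1L
  if (isTRUE(unit$has_distal))
    zend <- max(zend, ta + el$distal$offset + el$distal$width - 1L)
  if (!is.na(pas_rel)) zend <- max(zend, pas_rel + el$pas$width - 1L)
  n <- unit$end - unit$start + config$flank
  c(max(zstart, 0L), min(zend, n - 1L))
}

factor_mean_profile <- function(unit, config, genotype, temperature,
                                factor, pol_density) {
  g <- genotype_row(config, genotype)
  n <- length(pol_density)
  rel <- seq_len(n) - 1L
  amp <- config$depth * (unit$init_rate %||% 1)
  switch(factor,
    PolII_total = config$depth * pol_density * config$speed,
    PolII_Ser5P = config$depth * pol_density * config$speed *
      exp(-rel / config$ser5_tau),
    PolII_Ser2P = config$depth * pol_density * config$speed *
      (1 - exp(-rel / config$ser2_tau)) *
      (if (isTRUE(unit$responsive)) g$ser2_mult else 1),
    RNADNA_hybrid = {
      hd <- hazard_dwell(unit, config, genotype, temperature)
      config$depth * pol_density * config$speed *
        (hd$dwell * config$speed *
           (if (temperature >= 37) config$temp37_speed_mult else 1))
    },
    Nrd1 = , Pcf11 = {
      k <- config$kernels[[factor]]
      if (is.null(k)) stop("no kernel configured for factor ", factor)
      center <- if (factor == "Pcf11" && unit$unit_class == "PC" &&
                    !is.na(unit$pas_position))
        unit_rel(unit, unit$pas_position)
      else unit_rel(unit, unit$nbs_center)
      if (is.na(center)) return(numeric(n))
      amp * k$gain * exp(-(rel - (center + k$offset))^2 / (2 * k$sd^2))
    },
    stop(sprintf("unknown factor '%s' (supported: %s)", factor,
                 paste(KNOWN_FACTORS, collapse = ", "))))
}

#' Simulate coverage tracks with Poisson noise
#'
#' For each requested sample (factor, genotype, temperature, replicate),
#' builds the deterministic expected-signal track from the hazard model —
#' Pol II-type tracks are `depth * init_rate * survival * dwell`, factor
#' tracks are Gaussian recruitment kernels, CTD-mark tracks modulate the
#' Pol II profile — adds the uniform background, and draws per-base Poisson
#' counts. Deterministic under a fixed `config$seed` (each sample uses an
#' independent derived seed, so track content does not depend on which other
#' samples are requested).
#'
#' @param config A [simulation_config()].
#' @param annotation Result of [make_toy_annotation()].
#' @param sample_specs Data frame with columns `factor`, `genotype`,
#'   `temperature` and optionally `replicate`.
#' @return List with `tracks` (list of [coverage_track()]s, named
#'   `factor_genotype_temp_rep`) and `truth` (see [simulation_truth()]).
#' @export
simulate_tracks <- function(config, annotation, sample_specs) {
  stopifnot(inherits(config, "simulation_config"))
  units <- annotation$units
  sizes <- annotation$chrom_sizes
  if (is.null(sample_specs$replicate)) sample_specs$replicate <- 1L
  bad <- setdiff(unique(sample_specs$factor), KNOWN_FACTORS)
  if (length(bad))
    stop(sprintf("unknown factor(s): %s (supported: %s)",
                 paste(bad, collapse = ", "),
                 paste(KNOWN_FACTORS, collapse = ", ")))
  for (gt in unique(sample_specs$genotype)) genotype_row(config, gt)

  tracks <- vector("list", nrow(sample_specs))
  pol_cache <- new.env(parent = emptyenv())
  for (s in seq_len(nrow(sample_specs))) {
    sp <- sample_specs[s, ]
    mean_vals <- lapply(sizes, function(n) rep(config$background, n))
    names(mean_vals) <- names(sizes)
    for (ui in seq_len(nrow(units))) {
      u <- units[ui, ]
      key <- paste(ui, sp$genotype, sp$temperature, sep = "|")
      dens <- if (!is.null(pol_cache[[key]])) pol_cache[[key]] else {
        hd <- hazard_dwell(u, config, sp$genotype, sp$temperature)
        d <- expected_occupancy(hd$hazard, hd$dwell, u$init_rate)
        pol_cache[[key]] <- d
        d
      }
      prof <- factor_mean_profile(u, config, sp$genotype, sp$temperature,
                                  sp$factor, dens)
      n <- length(prof)
      rel <- seq_len(n) - 1L
      g <- if (u$strand == "-") u$tss - rel else u$tss + rel
      ok <- g >= 0L & g < sizes[[u$chrom]]
      idx <- g[ok] + 1L
      mean_vals[[u$chrom]][idx] <- mean_vals[[u$chrom]][idx] + prof[ok]
    }
    set.seed((config$seed + 7919L * s) %% .Machine$integer.max)
    counts <- lapply(mean_vals, function(mu) as.numeric(stats::rpois(
      length(mu), mu)))
    tracks[[s]] <- coverage_track(counts, factor = sp$factor,
                                  genotype = sp$genotype,
                                  temperature = sp$temperature,
                                  replicate = sp$replicate)
    names(tracks)[s] <- sprintf("%s_%s_%g_r%d", sp$factor, sp$genotype,
                                sp$temperature, sp$replicate)
  }
  truth <- simulation_truth(config, units,
                            genotypes = unique(sample_specs$genotype),
                            temperatures = unique(sample_specs$temperature))
  list(tracks = tracks, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Emits the plain-text bundle a downstream analysis consumes: BED6 + TSV
#' sidecar annotation, one bedGraph per track, the truth TSV, chrom.sizes,
#' and a JSON snapshot of the configuration. Everything round-trips through
#' the package readers losslessly.
#'
#' @param annotation Result of [make_toy_annotation()].
#' @param tracks Named list of [coverage_track()]s.
#' @param truth Truth data frame.
#' @param config The generating [simulation_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture <- function(annotation, tracks, truth, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    bed = file.path(dir, "units.bed"),
    tsv = file.path(dir, "units.tsv"),
    truth = file.path(dir, "truth.tsv"),
    sizes = file.path(dir, "chrom.sizes"),
    config = file.path(dir, "config.json"))
  write_units(annotation$units, paths$bed, paths$tsv)
  utils::write.table(annotation$units, file.path(dir, "units_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_chrom_sizes(annotation$chrom_sizes, paths$sizes)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(tracks)) {
    p <- file.path(dir, paste0(nm, ".bedGraph"))
    tryCatch(write_bedgraph(tracks[[nm]], p),
             error = function(e) stop(sprintf("failed writing '%s': %s",
                                              p, conditionMessage(e))))
    paths[[nm]] <- p
  }
  invisible(paths)
}

#' Read back a fixture written by [write_fixture()]
#' @param dir Fixture directory.
#' @return List with `units` (full annotation incl. generator state),
#'   `chrom_sizes`, `truth`, and `tracks`.
#' @export
read_fixture <- function(dir) {
  sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  units <- utils::read.table(file.path(dir, "units_full.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  bgs <- list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE)
  tracks <- list()
  for (p in bgs) {
    nm <- sub("\\.bedGraph$", "", basename(p))
    parts <- strsplit(nm, "_")[[1]]
    np <- length(parts)
    tracks[[nm]] <- read_bedgraph(
      p, sizes,
      factor = paste(parts[seq_len(np - 3L)], collapse = "_"),
      genotype = parts[np - 2L],
      temperature = as.numeric(parts[np - 1L]),
      replicate = as.integer(sub("^r", "", parts[np])))
  }
  list(units = units, chrom_sizes = sizes, truth = truth, tracks = tracks)
}
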