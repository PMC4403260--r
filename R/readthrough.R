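#' Default per-class contrast windows
#'
#' Relative windows (transcript orientation, nt from the class anchor) used
#' by the readthrough index. The reference window runs from the unit 5' end
#' to the anchor (encoded as NA start); the downstream window sits past the
#' terminator zone and the factor-recruitment maximum. NAPC downstream
#' windows are clipped to the gene end because attenuation is intragenic.
#'
#' @return Data frame with one row per unit class.
#' @export
contrast_windows <- function() {
  data.frame(
    unit_class = c("snoRNA", "CUT", "SUT", "XUT", "NAPC", "PC"),
    anchor_kind = c("mature_3p_end", rep("annotated_3p_end", 3), "nbs",
                    "annotated_3p_end"),
    ref_start = NA_integer_,   # NA = unit 5' end
    ref_end = 0L,
    down_start = c(150L, 100L, 100L, 100L, 100L, 100L),
    down_end = c(650L, 600L, 600L, 600L, 600L, 600L),
    clip_to_unit = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Resolve the reference and downstream windows of one unit to genomic
# half-open intervals. Returns list(anchor_kind, ref=c(s,e), down=c(s,e)).
unit_contrast_regions <- function(unit, windows) {
  w <- windows[windows$unit_class == unit$unit_class, ]
  if (!nrow(w)) stop("no contrast window for class ", unit$unit_class)
  anchor <- anchor_coord(unit, w$anchor_kind)
  dist5 <- abs(anchor - unit$tss)   # transcript distance TSS -> anchor
  rs <- if (is.na(w$ref_start)) -dist5 else w$ref_start
  re <- w$ref_end
  if (rs >= re) stop(sprintf("degenerate reference window for unit '%s'",
                             unit$id))
  ds <- w$down_start; de <- w$down_end
  if (w$clip_to_unit) {
    rel_end <- if (identical(unit$strand, "-")) anchor - unit$start + 1L
               else unit$end - anchor
    de <- min(de, rel_end)
    if (ds >= de)
      stop(sprintf("downstream window empty after clipping for unit '%s'",
                   unit$id))
  }
  list(anchor_kind = w$anchor_kind,
       ref = rel_to_genomic(anchor, unit$strand, rs, re),
       down = rel_to_genomic(anchor, unit$strand, ds, de))
}

window_mean <- function(values, g) {
  if (g[1] < 0L || g[2] > length(values))
    stop("contrast window outside chromosome bounds")
  mean(values[(g[1] + 1L):g[2]])
}

#' Readthrough index for one unit
#'
#' Ratio-of-ratios contrast of mutant vs wild-type Pol II signal downstream
#' of a terminator:
#' `RI = (D_mut / R_mut) / (D_wt / R_wt)`,
#' where D is the mean smoothed signal in the class's downstream window and
#' R in its reference (body) window. Normalizing each strain's downstream
#' signal by its own body signal controls for expression-level differences;
#' denominators are floored at a pseudocount. `RI = 1` for identical tracks.
#' When the reference signal is below the pseudocount in both tracks the
#' call is flagged `low_signal` and the index left undefined.
#'
#' @param wt,mut Wild-type and mutant [coverage_track()]s (same
#'   temperature).
#' @param unit One annotation row.
#' @param windows Window table from [contrast_windows()].
#' @param smooth Moving-average width (nt) applied before window means.
#' @param pseudocount Denominator floor; `NULL` for 1e-6 of each track's
#'   mean.
#' @return One-row data frame (a readthrough call).
#' @export
readthrough_index <- function(wt, mut, unit, windows = contrast_windows(),
                              smooth = 220L, pseudocount = NULL) {
  if (!identical(wt$temperature, mut$temperature))
    stop("wt and mut tracks must share a temperature label")
  sw <- moving_average(track_chrom(wt, unit$chrom), smooth)
  sm <- moving_average(track_chrom(mut, unit$chrom), smooth)
  build_call(unit, sw, sm, wt, mut, windows, pseudocount)
}

build_call <- function(unit, smooth_wt, smooth_mut, wt, mut, windows,
                       pseudocount) {
  reg <- unit_contrast_regions(unit, windows)
  pc_wt <- pseudocount %||% (1e-6 * track_mean(wt))
  pc_mut <- pseudocount %||% (1e-6 * track_mean(mut))
  r_wt <- window_mean(smooth_wt, reg$ref)
  r_mut <- window_mean(smooth_mut, reg$ref)
  d_wt <- window_mean(smooth_wt, reg$down)
  d_mut <- window_mean(smooth_mut, reg$down)
  low <- r_wt < pc_wt && r_mut < pc_mut
  ri <- if (low) NA_real_ else
    (max(d_mut, pc_mut) / max(r_mut, pc_mut)) /
    (max(d_wt, pc_wt) / max(r_wt, pc_wt))
  data.frame(id = unit$id, unit_class = unit$unit_class,
             genotype = mut$genotype, temperature = mut$temperature,
             r_wt = r_wt, r_mut = r_mut, d_wt = d_wt, d_mut = d_mut,
             readthrough_index = ri, low_signal = low,
             is_defective = NA)
}

#' Readthrough calls for a cohort
#'
#' Vectorized [readthrough_index()]: smooths each chromosome once and
#' evaluates every unit of the cohort against one mutant-vs-WT contrast.
#'
#' @inheritParams readthrough_index
#' @param units Annotation data frame.
#' @return Data frame of calls, one row per unit.
#' @export
readthrough_calls <- function(wt, mut, units, windows = contrast_windows(),
                              smooth = 220L, pseudocount = NULL) {
  if (!nrow(units)) stop("empty cohort")
  if (!identical(wt$temperature, mut$temperature))
    stop("wt and mut tracks must share a temperature label")
  sw <- lapply(wt$values, moving_average, window = smooth)
  sm <- lapply(mut$values, moving_average, window = smooth)
  calls <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    build_call(u, sw[[u$chrom]], sm[[u$chrom]], wt, mut, windows,
               pseudocount)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Flag low-signal units
#'
#' Units whose wild-type reference signal falls below a floor are flagged
#' `low_signal` and excluded from classification and fraction denominators.
#' The floor is either an absolute value (`min_reference`) or, by default,
#' the `quantile` (0.25) of the cohort's wild-type reference means. For
#' cohorts known to be uniformly expressed (e.g. simulated ones) an absolute
#' floor is the appropriate choice; the cohort-quantile default mimics the
#' practice of discarding the weakest units of a genome-wide cohort.
#'
#' @param calls Data frame from [readthrough_calls()].
#' @param min_reference Absolute floor overriding the quantile rule.
#' @param quantile Cohort quantile used when no absolute floor is given.
#' @return `calls` with `low_signal` set (and `is_defective` forced FALSE
#'   for flagged units).
#' @export
low_signal_filter <- function(calls, min_reference = NULL, quantile = 0.25) {
  if (!nrow(calls)) stop("empty cohort")
  floor_val <- min_reference %||%
    stats::quantile(calls$r_wt, probs = quantile, names = FALSE)
  if (floor_val < 0) stop("floor must be >= 0")
  calls$low_signal <- calls$low_signal | calls$r_wt < floor_val
  calls$is_defective[calls$low_signal] <- FALSE
  attr(calls, "low_signal_floor") <- floor_val
  calls
}

#' Classify units as termination-defective
#'
#' A unit is called defective when its readthrough index exceeds
#' `ri_threshold` and the absolute downstream increase `D_mut - D_wt`
#' reaches `min_abs_increase` (by default twice the background rate
#' estimate, guarding against large ratios of near-zero signals).
#' Low-signal units are never defective. Classification is monotone in RI
#' at a fixed absolute increase.
#'
#' @param calls Data frame of readthrough calls.
#' @param ri_threshold Readthrough-index threshold (default 1.5).
#' @param min_abs_increase Minimum absolute downstream increase; `NULL`
#'   uses `2 * background`.
#' @param background Background rate estimate used for the default
#'   `min_abs_increase` (default 0).
#' @return `calls` with `is_defective` filled in.
#' @export
classify_defective <- function(calls, ri_threshold = 1.5,
                               min_abs_increase = NULL, background = 0) {
  min_abs <- min_abs_increase %||% (2 * background)
  ok <- !calls$low_signal & !is.na(calls$readthrough_index)
  calls$is_defective <- ok &
    calls$readthrough_index >= ri_threshold &
    (calls$d_mut - calls$d_wt) >= min_abs
  calls$is_defective[calls$low_signal] <- FALSE
  calls
}

#' Per-class defective fractions
#'
#' @param calls Classified calls (after [classify_defective()]).
#' @return Data frame per unit class: `n_total`, `n_low_signal`,
#'   `n_analyzed`, `n_defective`, `fraction` (NA when no unit analyzed).
#'   `n_analyzed + n_low_signal = n_total` in every class.
#' @export
class_fractions <- function(calls) {
  if (anyNA(calls$is_defective))
    stop("calls must be classified first (run classify_defective)")
  cl <- unique(calls$unit_class)
  out <- do.call(rbind, lapply(cl, function(k) {
    x <- calls[calls$unit_class == k, ]
    n_low <- sum(x$low_signal)
    n_an <- nrow(x) - n_low
    n_def <- sum(x$is_defective & !x$low_signal)
    data.frame(unit_class = k, n_total = nrow(x), n_low_signal = n_low,
               n_analyzed = n_an, n_defective = n_def,
               fraction = if (n_an > 0) n_def / n_an else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Termination-pathway assignment
#'
#' Crosses the defect flags of a CID-mutant contrast and a cleavage-mutant
#' contrast into the four pathway categories: `CID-only` (defective in the
#' CID mutant only), `cleavage-only`, `both`, `neither`. Every unit must be
#' classified in both contrasts; counts sum to the cohort size.
#'
#' @param calls_cid,calls_cleavage Classified call frames for the two
#'   contrasts.
#' @return List with `assignments` (id, class, flags, category) and
#'   `counts` (category counts).
#' @export
pathway_assignment <- function(calls_cid, calls_cleavage) {
  m <- match(calls_cid$id, calls_cleavage$id)
  if (anyNA(m)) {
    missing <- calls_cid$id[is.na(m)]
    stop("unit(s) missing from the cleavage-mutant contrast: ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(calls_cid$is_defective) ||
      anyNA(calls_cleavage$is_defective[m]))
    stop("calls must be classified in every contrast")
  cid <- calls_cid$is_defective
  clv <- calls_cleavage$is_defective[m]
  category <- ifelse(cid & clv, "both",
              ifelse(cid, "CID-only",
              ifelse(clv, "cleavage-only", "neither")))
  assignments <- data.frame(id = calls_cid$id,
                            unit_class = calls_cid$unit_class,
                            defective_cid = cid, defective_cleavage = clv,
                            category = category)
  counts <- table(factor(category, levels = c("CID-only", "cleavage-only",
                                              "both", "neither")))
  list(assignments = assignments, counts = counts)
}
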