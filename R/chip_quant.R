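#' Amplicon panel
#'
#' Validates a panel of qPCR-style amplicons: a data frame with columns
#' `id`, `chrom`, `start`, `end` (0-based half-open) and `role`
#' (`"query"` or `"background"`). Exactly one background amplicon — a
#' nontranscribed control region — is required per panel.
#'
#' @param panel Data frame as above.
#' @return The validated panel (class `amplicon_panel`).
#' @export
amplicon_panel <- function(panel) {
  need <- c("id", "chrom", "start", "end", "role")
  if (!all(need %in% names(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (!all(panel$role %in% c("query", "background")))
    stop("amplicon role must be 'query' or 'background'")
  if (sum(panel$role == "background") != 1L)
    stop("panel must contain exactly one background amplicon")
  if (any(panel$start < 0) || any(panel$start >= panel$end))
    stop("invalid amplicon coordinates")
  if (anyDuplicated(panel$id)) stop("duplicate amplicon ids")
  class(panel) <- c("amplicon_panel", "data.frame")
  panel
}

amplicon_region <- function(row)
  genomic_region(row$chrom, row$start, row$end)

#' Amplicon-level fold-enrichment quantification
#'
#' For each replicate track, computes the fold enrichment of every query
#' amplicon over the panel's background amplicon, then aggregates across
#' replicates: the contract is ratio-then-average (per-replicate fold
#' enrichments are computed first and their mean reported), matching how
#' replicate ChIP-qPCR experiments are averaged. SD is the sample SD
#' (n - 1); single-replicate panels report SD 0 with `n = 1`.
#'
#' @param tracks List of replicate [coverage_track()]s (>= 1).
#' @param panel An [amplicon_panel()].
#' @param pseudocount Background floor passed to [fold_enrichment()].
#' @return List with `summary` (id, mean, sd, n) and `replicates` (matrix,
#'   amplicons x replicates).
#' @export
amplicon_quant <- function(tracks, panel, pseudocount = NULL) {
  panel <- amplicon_panel(panel)
  if (!length(tracks)) stop("need at least one replicate track")
  bg <- panel[panel$role == "background", ][1, ]
  queries <- panel[panel$role == "query", ]
  reps <- vapply(tracks, function(tr)
    vapply(seq_len(nrow(queries)), function(i)
      as.numeric(fold_enrichment(tr, amplicon_region(queries[i, ]),
                                 amplicon_region(bg),
                                 pseudocount = pseudocount)),
      numeric(1)),
    numeric(nrow(queries)))
  reps <- matrix(reps, nrow = nrow(queries),
                 dimnames = list(queries$id, NULL))
  n <- length(tracks)
  summary <- data.frame(
    id = queries$id,
    mean = rowMeans(reps),
    sd = if (n > 1) apply(reps, 1, stats::sd) else rep(0, nrow(queries)),
    n = n)
  list(summary = summary, replicates = reps)
}

#' Normalize phospho-CTD signal to total Pol II
#'
#' Per amplicon, the ratio of the mean phospho-CTD fold enrichment to the
#' mean total-Pol II fold enrichment, with the standard error propagated in
#' quadrature from the replicate SDs. Ratios whose total-Pol II denominator
#' sits at the pseudocount floor are flagged unreliable.
#'
#' @param phospho,total Results of [amplicon_quant()] over matching panels.
#' @param floor Denominator reliability floor.
#' @return Data frame: id, ratio, se, unreliable.
#' @export
phospho_normalize <- function(phospho, total, floor = 1e-6) {
  ps <- phospho$summary; ts <- total$summary
  m <- match(ps$id, ts$id)
  if (anyNA(m)) stop("amplicon panels do not match")
  ts <- ts[m, ]
  ratio <- ps$mean / ts$mean
  se <- abs(ratio) * sqrt((ps$sd^2 / pmax(ps$n, 1)) / ps$mean^2 +
                          (ts$sd^2 / pmax(ts$n, 1)) / ts$mean^2)
  data.frame(id = ps$id, ratio = ratio, se = se,
             unreliable = ts$mean <= floor)
}

#' Time-course amplicon ratio
#'
#' Ratio of mean Pol II density over two amplicons at each time point of a
#' (promoter shutoff) time course — the readout used to follow the last
#' transcribing wave clearing a gene.
#'
#' @param timecourse List of `list(time =, track =)` entries (>= 2 time
#'   points, unique times).
#' @param amp_a,amp_b Single-row amplicon data frames or
#'   [genomic_region()]s.
#' @param pseudocount Denominator floor.
#' @return Data frame ordered by time: `time`, `ratio`.
#' @export
kinetics_ratio <- function(timecourse, amp_a, amp_b, pseudocount = 1e-9) {
  if (length(timecourse) < 2L) stop("need at least two time points")
  times <- vapply(timecourse, function(tp) as.numeric(tp$time), numeric(1))
  if (anyDuplicated(times)) stop("duplicate time labels in time course")
  as_region <- function(a) if (inherits(a, "genomic_region")) a else
    amplicon_region(a)
  ra <- as_region(amp_a); rb <- as_region(amp_b)
  ratio <- vapply(timecourse, function(tp)
    region_mean(tp$track, ra) / max(region_mean(tp$track, rb), pseudocount),
    numeric(1))
  out <- data.frame(time = times, ratio = ratio)
  out[order(out$time), , drop = FALSE]
}
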