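#' Build an anchored unit x position matrix
#'
#' Extracts [anchored_vector()]s for a cohort of units into a matrix whose
#' rows are units and whose columns are relative-position bins (5' to 3' in
#' transcript orientation, 0 = anchor). With `normalize = TRUE` (the
#' default) each row is divided by its unmasked mean so high-occupancy units
#' do not dominate downstream averages; rows with zero mean are masked
#' entirely.
#'
#' @param track A [coverage_track()].
#' @param units Annotation data frame; every unit must possess the anchor.
#' @param anchor_kind Anchor to align on (see [anchored_vector()]).
#' @param upstream,downstream Extents in nt.
#' @param bin Bin width in nt.
#' @param normalize Per-row mean normalization flag.
#' @return An `anchored_matrix`: list with `values`, `mask`, `positions`,
#'   `unit_ids`, window metadata and the `normalized` flag.
#' @export
build_matrix <- function(track, units, anchor_kind, upstream, downstream,
                         bin = 10L, normalize = TRUE) {
  if (!nrow(units)) stop("`units` is empty")
  anchor_field <- switch(anchor_kind, mature_3p_end = "mature_end",
                         tss = "tss", nbs = "nbs_center",
                         annotated_3p_end = NULL,
                         stop("unknown anchor kind: ", anchor_kind))
  if (!is.null(anchor_field)) {
    missing <- units$id[is.na(units[[anchor_field]])]
    if (length(missing))
      stop(sprintf("unit(s) without a '%s' anchor: %s", anchor_kind,
                   paste(missing, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(units)), function(i)
    anchored_vector(track, units[i, ], anchor_kind, upstream, downstream,
                    bin))
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  mask <- do.call(rbind, lapply(rows, `[[`, "mask"))
  if (normalize) {
    for (i in seq_len(nrow(values))) {
      m <- mean(values[i, mask[i, ]])
      if (!is.finite(m) || m == 0) {
        mask[i, ] <- FALSE
        values[i, ] <- NA_real_
      } else values[i, ] <- values[i, ] / m
    }
  }
  structure(list(values = values, mask = mask,
                 positions = rows[[1]]$positions, unit_ids = units$id,
                 anchor_kind = anchor_kind, upstream = upstream,
                 downstream = downstream, bin = bin,
                 normalized = normalize),
            class = "anchored_matrix")
}

#' @export
print.anchored_matrix <- function(x, ...) {
  cat(sprintf("<anchored_matrix> %d units x %d bins (bin %d nt), anchor %s, %s\n",
              nrow(x$values), ncol(x$values), x$bin, x$anchor_kind,
              if (x$normalized) "row-normalized" else "raw"))
  invisible(x)
}

#' Cohort metagene profile
#'
#' Column-wise mean over unmasked cells of an anchored matrix, then a
#' centered moving average (default 220 nt, converted to bins). Columns with
#' no contributing unit are recorded as gaps (NA), never interpolated.
#'
#' @param matrix An `anchored_matrix` from [build_matrix()].
#' @param smooth_window Smoothing window in nt.
#' @return A `metagene_profile`: data frame with `position`, `mean`,
#'   `n_units`, plus attribute `smooth_window`.
#' @export
metagene_profile <- function(matrix, smooth_window = 220L) {
  stopifnot(inherits(matrix, "anchored_matrix"))
  if (!nrow(matrix$values)) stop("empty matrix")
  v <- matrix$values
  v[!matrix$mask] <- NA_real_
  n_units <- colSums(matrix$mask)
  colmean <- colMeans(v, na.rm = TRUE)
  colmean[n_units == 0] <- NA_real_
  w_bins <- max(1L, as.integer(round(smooth_window / matrix$bin)))
  smoothed <- moving_average_masked(colmean, w_bins)
  out <- data.frame(position = matrix$positions, mean = smoothed,
                    n_units = n_units)
  attr(out, "smooth_window") <- smooth_window
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Heat-map matrix over snoRNA units
#'
#' Anchored matrix for the classic terminator heat map: signal from
#' `upstream` nt 5' to `downstream` nt 3' of snoRNA mature 3' ends, rows
#' sorted by unit length (ascending), with the bin containing each unit's 5'
#' end exported as a marker so the plot can draw the 5'-end spacer.
#'
#' @param track A [coverage_track()].
#' @param units snoRNA annotation rows (all must carry `mature_end`).
#' @param upstream,downstream Extents in nt (defaults 500 / 1000).
#' @param bin Bin width in nt.
#' @param normalize Per-row normalization flag.
#' @return List with `matrix` (an `anchored_matrix`, rows in sorted order),
#'   `row_order` (unit ids), `marker_bin` (1-based column index of each
#'   unit's 5' end, NA when outside the window) and `marker_rel` (relative
#'   position of the 5' end).
#' @export
heatmap_matrix <- function(track, units, upstream = 500L, downstream = 1000L,
                           bin = 10L, normalize = TRUE) {
  if (any(units$unit_class != "snoRNA"))
    stop("heatmap_matrix expects snoRNA units only")
  if (anyNA(units$mature_end)) stop("snoRNA unit without mature_end")
  units <- units[order(units$end - units$start), ]
  mat <- build_matrix(track, units, "mature_3p_end", upstream, downstream,
                      bin, normalize)
  marker_rel <- -abs(units$mature_end - units$tss)
  marker_bin <- floor((marker_rel + upstream) / bin) + 1L
  marker_bin[marker_bin < 1L | marker_bin > ncol(mat$values)] <- NA_integer_
  list(matrix = mat, row_order = units$id, marker_bin = marker_bin,
       marker_rel = marker_rel)
}

#' Position of the signal maximum in a search window
#'
#' Argmax of a (smoothed) anchored signal within a relative-position window.
#' Ties break toward the smallest (most 5') position. Invariant under
#' positive scaling and constant offsets of the signal.
#'
#' @param x A numeric vector, an [anchored_vector()] result, or a
#'   `metagene_profile`.
#' @param positions Relative positions (required when `x` is a bare vector).
#' @param search Length-2 relative interval to search, e.g. `c(-200, 400)`.
#' @param smooth_window Optional moving-average width (in positions) applied
#'   before the argmax; `NULL` for none.
#' @return Relative position of the maximum.
#' @export
peak_position <- function(x, positions = NULL, search = c(-Inf, Inf),
                          smooth_window = NULL) {
  if (inherits(x, "metagene_profile")) {
    positions <- x$position
    x <- x$mean
  } else if (is.list(x) && !is.null(x$values)) {
    positions <- x$positions
    x <- x$values
  }
  if (is.null(positions) || length(positions) != length(x))
    stop("`positions` must accompany the signal vector")
  if (!is.null(smooth_window)) x <- moving_average_masked(x, smooth_window)
  sel <- which(positions >= search[1] & positions <= search[2] & !is.na(x))
  if (!length(sel)) stop("no unmasked positions in the search window")
  sel <- sel[order(positions[sel])]
  positions[sel[which.max(x[sel])]]
}

#' Paired sign-flip permutation test for a positional shift
#'
#' Tests whether factor B peaks 3' of factor A across a cohort: the
#' statistic is the mean paired difference `B - A` of per-unit peak
#' positions, and the null distribution is generated by flipping the sign of
#' each unit's difference. All `2^n` sign assignments are enumerated exactly
#' for `n <= 20`; larger cohorts use Monte-Carlo sampling with
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`. The identity assignment is
#' always counted, so p is never 0. All-zero differences return p = 1.
#'
#' @param peaks_a,peaks_b Paired per-unit peak positions (equal length,
#'   n >= 2).
#' @param n_perm Monte-Carlo permutation count (used when `n > 20`).
#' @param seed Optional seed for the Monte-Carlo path.
#' @param alternative `"greater"` (B 3' of A; default), `"less"`, or
#'   `"two.sided"`.
#' @param method `"auto"` (exact for `n <= 20`), or force `"exact"` /
#'   `"monte_carlo"`.
#' @return A `peak_shift_result`: list with `statistic` (mean difference),
#'   `p_value`, `exact` flag, `n`, `n_perm`.
#' @export
peak_shift_test <- function(peaks_a, peaks_b, n_perm = 10000L, seed = NULL,
                            alternative = c("greater", "less", "two.sided"),
                            method = c("auto", "exact", "monte_carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(peaks_a) != length(peaks_b))
    stop("paired peak vectors must have equal length")
  n <- length(peaks_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- as.numeric(peaks_b) - as.numeric(peaks_a)
  res <- list(peaks_a = peaks_a, peaks_b = peaks_b, statistic = mean(d),
              n = n, alternative = alternative)
  if (all(d == 0)) {
    res$p_value <- 1
    res$exact <- TRUE
    res$n_perm <- NA_integer_
    class(res) <- "peak_shift_result"
    return(res)
  }
  obs <- sum(d)
  tol <- 1e-8 * max(1, abs(obs))
  score <- switch(alternative,
                  greater = function(s) s >= obs - tol,
                  less = function(s) s <= obs + tol,
                  two.sided = function(s) abs(s) >= abs(obs) - tol)
  exact <- switch(method, auto = n <= 20L, exact = TRUE,
                  monte_carlo = FALSE)
  if (exact && n > 25L) stop("exact enumeration limited to n <= 25")
  if (exact) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    res$p_value <- mean(score(sums))
    res$exact <- TRUE
    res$n_perm <- NA_integer_
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    perm <- colSums(signs * d)
    res$p_value <- (1 + sum(score(perm))) / (n_perm + 1)
    res$exact <- FALSE
    res$n_perm <- as.integer(n_perm)
  }
  class(res) <- "peak_shift_result"
  res
}

#' @export
print.peak_shift_result <- function(x, ...) {
  cat(sprintf("Paired sign-flip permutation test (%s)\n",
              if (x$exact) "exact enumeration" else
                sprintf("Monte-Carlo, %d permutations", x$n_perm)))
  cat(sprintf("  n = %d pairs, mean shift = %.2f nt, %s p = %.3g\n",
              x$n, x$statistic, x$alternative, x$p_value))
  invisible(x)
}

#' Per-unit peak table for two factors
#'
#' Convenience wrapper: extracts per-unit anchored vectors for two factor
#' tracks, smooths, localizes each unit's maximum in a search window, and
#' runs [peak_shift_test()] on the paired positions.
#'
#' @param track_a,track_b Factor tracks (e.g. Nrd1 and Pcf11).
#' @param units Cohort annotation.
#' @param anchor_kind Anchor for the windows.
#' @param upstream,downstream Window extents (nt).
#' @param search_a,search_b Per-factor peak search windows (relative nt);
#'   defaults follow anchor-proximal vs downstream factors.
#' @param smooth_window Smoothing in nt before the argmax.
#' @param n_perm,seed Passed to [peak_shift_test()].
#' @return List with `peaks` (data frame id, peak_a, peak_b) and `test`.
#' @export
peak_shift_analysis <- function(track_a, track_b, units, anchor_kind,
                                upstream = 400L, downstream = 800L,
                                search_a = c(-200, 400),
                                search_b = c(0, 600),
                                smooth_window = 220L, n_perm = 10000L,
                                seed = NULL) {
  pk <- function(track, search) vapply(seq_len(nrow(units)), function(i) {
    av <- anchored_vector(track, units[i, ], anchor_kind, upstream,
                          downstream, bin = 1L)
    peak_position(av, search = search, smooth_window = smooth_window)
  }, numeric(1))
  pa <- pk(track_a, search_a)
  pb <- pk(track_b, search_b)
  list(peaks = data.frame(id = units$id, peak_a = pa, peak_b = pb),
       test = peak_shift_test(pa, pb, n_perm = n_perm, seed = seed))
}
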