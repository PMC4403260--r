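`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coverage track container
#'
#' A coverage track holds per-base, non-negative signal at 1-nt resolution
#' for one sample, together with its metadata (assayed factor, genotype,
#' growth temperature, replicate index). All genomic coordinates in the
#' package are 0-based, half-open.
#'
#' @param values Named list of per-chromosome numeric vectors (one value per
#'   base). Names are chromosome names; lengths define chromosome lengths.
#' @param factor Assayed factor, e.g. `"PolII_total"`, `"PolII_Ser2P"`,
#'   `"PolII_Ser5P"`, `"Nrd1"`, `"Pcf11"`, `"RNADNA_hybrid"`.
#' @param genotype Free-text genotype label (e.g. `"WT"`, `"pcf11-9"`).
#' @param temperature Growth temperature in degrees C (25 or 37).
#' @param replicate Replicate index (integer, >= 1).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, factor = "PolII_total", genotype = "WT",
                           temperature = 25, replicate = 1L) {
  if (!is.list(values) || is.null(names(values)) ||
      any(!nzchar(names(values))))
    stop("`values` must be a named list of per-chromosome numeric vectors")
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    if (anyNA(v) || any(!is.finite(v)))
      stop("coverage values must be finite")
    if (any(v < 0)) stop("coverage values must be >= 0")
    v
  })
  structure(
    list(values = values, factor = as.character(factor),
         genotype = as.character(genotype),
         temperature = as.numeric(temperature),
         replicate = as.integer(replicate)),
    class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s / %s / %g C / rep %d\n",
              x$factor, x$genotype, x$temperature, x$replicate))
  cat(sprintf("  %d chromosome(s), %s bases, total signal %.4g\n",
              length(x$values),
              format(sum(lengths(x$values)), big.mark = ","),
              sum(vapply(x$values, sum, numeric(1)))))
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track A `coverage_track`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  vapply(track$values, length, integer(1))
}

#' Genomic region
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param strand `"+"`, `"-"` or `NA`.
#' @return A `genomic_region` object.
#' @export
genomic_region <- function(chrom, start, end, strand = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid region: need 0 <= start < end")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_region")
}

track_chrom <- function(track, chrom) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop(sprintf("unknown chromosome '%s' in track", chrom))
  v
}

#' Read a chrom.sizes file
#' @param path Two-column TSV: chromosome name, length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "integer"))
  stats::setNames(d$size, d$chrom)
}

#' Write a chrom.sizes file
#' @param sizes Named integer vector.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Intervals are expanded to per-base values over zero-initialised arrays.
#' Overlapping intervals with conflicting values are an error.
#'
#' @param path bedGraph path (4 columns: chrom, start, end, value;
#'   0-based half-open; no header required, `track`/`#` lines skipped).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @inheritParams coverage_track
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_sizes, factor = "PolII_total",
                          genotype = "WT", temperature = 25, replicate = 1L) {
  vals <- lapply(chrom_sizes, function(n) numeric(n))
  names(vals) <- names(chrom_sizes)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines)) {
    d <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
    bad <- setdiff(unique(d$chrom), names(chrom_sizes))
    if (length(bad))
      stop("unknown chromosome(s) in bedGraph: ", paste(bad, collapse = ", "))
    if (any(d$start < 0) ||
        any(d$end > chrom_sizes[d$chrom]) || any(d$start >= d$end))
      stop("bedGraph interval outside chromosome bounds in ", path)
    d <- d[order(d$chrom, d$start), ]
    for (ch in unique(d$chrom)) {
      di <- d[d$chrom == ch, ]
      if (nrow(di) > 1L) {
        ov <- which(di$start[-1] < di$end[-nrow(di)])
        if (length(ov)) {
          conflict <- di$value[ov] != di$value[ov + 1L]
          if (any(conflict))
            stop(sprintf("overlapping bedGraph intervals with conflicting values on %s near position %d",
                         ch, di$start[ov[which(conflict)[1]] + 1L]))
        }
      }
      v <- vals[[ch]]
      for (i in seq_len(nrow(di)))
        v[(di$start[i] + 1L):di$end[i]] <- di$value[i]
      vals[[ch]] <- v
    }
  }
  coverage_track(vals, factor = factor, genotype = genotype,
                 temperature = temperature, replicate = replicate)
}

#' Write a coverage track as bedGraph
#'
#' Values are run-length encoded; zero runs are omitted (bedGraph's implicit
#' zero), so `read_bedgraph(write_bedgraph(x))` reproduces the value arrays
#' exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       format(r$values[keep], scientific = FALSE, trim = TRUE,
                              digits = 17)),
               con)
  }
  invisible(path)
}

#' Read a bigWig file into a coverage track (optional)
#'
#' Requires the `rtracklayer` package; feature-gated because bedGraph is the
#' package's native format.
#' @inheritParams read_bedgraph
#' @export
read_bigwig <- function(path, chrom_sizes, factor = "PolII_total",
                        genotype = "WT", temperature = 25, replicate = 1L) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_bigwig() needs the 'rtracklayer' package")
  gr <- rtracklayer::import.bw(path)
  vals <- lapply(chrom_sizes, function(n) numeric(n))
  names(vals) <- names(chrom_sizes)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    if (is.null(vals[[ch]])) stop("unknown chromosome in bigWig: ", ch)
    vals[[ch]][(df$start[i] + 1L):df$end[i]] <- df$value[i]
  }
  coverage_track(vals, factor, genotype, temperature, replicate)
}

#' Centered moving average with truncated edges
#'
#' Smooths a per-base signal with a centered window of `window` positions
#' (the field-standard smoothing for terminator metagenes uses 220 nt). At
#' the array edges the window shrinks to the available span, so the output
#' has the same length as the input and no positions are lost.
#'
#' @param x Numeric vector.
#' @param window Window width in positions (>= 1). Even widths place the
#'   extra position downstream of the center.
#' @return Numeric vector, `length(x)`.
#' @export
moving_average <- function(x, window = 220L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(c(0, as.numeric(x)))
  i <- seq_len(n)
  lo <- pmax(i - (window - 1L) %/% 2L, 1L)
  hi <- pmin(i + window %/% 2L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Moving average that ignores NA cells; positions whose window holds no
# valid cell come back NA.
moving_average_masked <- function(x, window = 220L) {
  ok <- !is.na(x)
  if (all(ok)) return(moving_average(x, window))
  x0 <- ifelse(ok, x, 0)
  s <- moving_average(x0, window)
  cnt <- moving_average(as.numeric(ok), window)
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Resolve an anchor kind to a 0-based genomic base coordinate.
anchor_coord <- function(unit, anchor_kind) {
  a <- switch(anchor_kind,
    mature_3p_end = unit$mature_end,
    tss = unit$tss,
    nbs = unit$nbs_center,
    annotated_3p_end = if (identical(unit$strand, "-")) unit$start
                       else unit$end - 1L,
    stop("unknown anchor kind: ", anchor_kind))
  if (is.null(a) || is.na(a))
    stop(sprintf("unit '%s' (%s) has no '%s' anchor",
                 unit$id, unit$unit_class, anchor_kind))
  as.integer(a)
}

# Map a relative (transcript-orientation) half-open interval [rs, re) around
# a genomic anchor base to a genomic half-open interval.
rel_to_genomic <- function(anchor, strand, rs, re) {
  if (identical(strand, "-")) c(anchor - re + 1L, anchor - rs + 1L)
  else c(anchor + rs, anchor + re)
}

#' Extract an anchored, strand-aware signal window
#'
#' Returns the track signal around a unit anchor, ordered 5' to 3' in
#' transcript orientation (reversed for minus-strand units). Relative
#' position 0 is the anchor base itself; "downstream" means 3' of the
#' anchor. Bases beyond the chromosome ends are masked; a bin is valid only
#' when all of its constituent bases lie inside the chromosome.
#'
#' @param track A `coverage_track`.
#' @param unit A unit (one row of an annotation data frame, or a list) with
#'   fields `id`, `unit_class`, `chrom`, `start`, `end`, `strand`, `tss` and
#'   the anchor field required by `anchor_kind`.
#' @param anchor_kind One of `"mature_3p_end"`, `"tss"`, `"nbs"`,
#'   `"annotated_3p_end"`.
#' @param upstream,downstream Extents in nt (relative positions
#'   `-upstream ... downstream - 1`).
#' @param bin Bin width in nt; must divide `upstream + downstream`. Bin
#'   values are means of constituent bases.
#' @return List with `values` (length `(upstream+downstream)/bin`), `mask`
#'   (TRUE = valid), and `positions` (relative coordinate of each bin
#'   center; for `bin = 1` simply `-upstream ... downstream - 1`).
#' @export
anchored_vector <- function(track, unit, anchor_kind, upstream, downstream,
                            bin = 1L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  bin <- as.integer(bin)
  width <- upstream + downstream
  if (width < 1L) stop("window must span at least one base")
  if (width %% bin != 0L)
    stop("`bin` must divide upstream + downstream")
  anchor <- anchor_coord(unit, anchor_kind)
  v <- track_chrom(track, unit$chrom)
  rel <- seq.int(-upstream, downstream - 1L)
  g <- if (identical(unit$strand, "-")) anchor - rel else anchor + rel
  ok <- g >= 0L & g < length(v)
  base_vals <- rep(NA_real_, width)
  base_vals[ok] <- v[g[ok] + 1L]
  nb <- width %/% bin
  if (bin == 1L) {
    vals <- base_vals
    mask <- ok
    pos <- rel
  } else {
    m <- matrix(base_vals, nrow = bin)
    mk <- matrix(ok, nrow = bin)
    mask <- colSums(mk) == bin
    vals <- colMeans(m)
    vals[!mask] <- NA_real_
    pos <- rel[seq(1L, width, by = bin)] + (bin - 1) / 2
  }
  list(values = vals, mask = mask, positions = pos)
}

#' Mean signal over a genomic region
#' @param track A `coverage_track`.
#' @param region A `genomic_region` (half-open).
#' @return Arithmetic mean of per-base values.
#' @export
region_mean <- function(track, region) {
  v <- track_chrom(track, region$chrom)
  if (region$end > length(v)) stop("region beyond chromosome end")
  mean(v[(region$start + 1L):region$end])
}

track_mean <- function(track) {
  tot <- sum(vapply(track$values, sum, numeric(1)))
  tot / sum(lengths(track$values))
}

#' Fold enrichment over a background region
#'
#' Ratio of mean signal in a query region to mean signal in a nontranscribed
#' background region, the standard ChIP-qPCR readout. The background mean is
#' floored at a pseudocount (default 1e-6 of the track-wide mean) to guard
#' against empty backgrounds; the pseudocount used is attached as an
#' attribute. Scale-invariant: multiplying the whole track by k > 0 leaves
#' the ratio unchanged.
#'
#' @param track A `coverage_track`.
#' @param region,background_region `genomic_region`s.
#' @param pseudocount Background floor; `NULL` for the default.
#' @return Numeric ratio with attribute `"pseudocount"`.
#' @export
fold_enrichment <- function(track, region, background_region,
                            pseudocount = NULL) {
  pc <- pseudocount %||% (1e-6 * track_mean(track))
  bm <- region_mean(track, background_region)
  if (bm <= 0 && pc <= 0)
    stop("background mean is zero and pseudocount is zero")
  structure(region_mean(track, region) / max(bm, pc), pseudocount = pc)
}

#' Write unit annotation as BED6 + TSV sidecar
#'
#' @param units Annotation data frame (see [make_toy_annotation()]).
#' @param bed_path BED6 output (name = unit id, score 0, strand).
#' @param tsv_path Sidecar TSV (id, unit_class, tss, mature_end, nbs_center,
#'   pas_position).
#' @export
write_units <- function(units, bed_path, tsv_path) {
  bed <- data.frame(chrom = units$chrom, start = units$start,
                    end = units$end, name = units$id,
                    score = rep(0L, nrow(units)), strand = units$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- units[, c("id", "unit_class", "tss", "mature_end", "nbs_center",
                    "pas_position")]
  utils::write.table(side, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Read unit annotation from BED6 + TSV sidecar
#' @param bed_path,tsv_path Paths written by [write_units()].
#' @return Annotation data frame.
#' @export
read_units <- function(bed_path, tsv_path) {
  side <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character",
                                           "integer", "integer", "integer",
                                           "integer"))
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    units <- data.frame(id = character(), unit_class = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        tss = integer(), mature_end = integer(),
                        nbs_center = integer(), pas_position = integer())
    return(units)
  }
  bed <- utils::read.table(text = lines, sep = "\t",
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "integer",
                                          "character"))
  m <- match(bed$name, side$id)
  if (anyNA(m)) stop("BED units missing from sidecar TSV")
  data.frame(id = bed$name, unit_class = side$unit_class[m],
             chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, tss = side$tss[m],
             mature_end = side$mature_end[m],
             nbs_center = side$nbs_center[m],
             pas_position = side$pas_position[m])
}

#' Read regions from a GFF3 file (read-only convenience)
#'
#' GFF3 is 1-based closed; coordinates are converted to the package's
#' 0-based half-open convention on read.
#' @param path GFF3 path.
#' @return Data frame with chrom, start, end, strand, type, id.
#' @export
read_gff3_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      type = character(), id = character()))
  d <- utils::read.table(text = lines, sep = "\t", quote = "",
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"),
                         colClasses = "character")
  id <- sub(".*ID=([^;]+).*", "\\1", d$attributes)
  id[!grepl("ID=", d$attributes)] <- NA_character_
  data.frame(chrom = d$seqid, start = as.integer(d$start) - 1L,
             end = as.integer(d$end), strand = d$strand, type = d$type,
             id = id)
}
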