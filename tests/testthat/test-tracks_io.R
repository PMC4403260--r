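test_that("bedGraph read expands intervals and handles edge cases", {
  sizes <- c(chrI = 20L, chrII = 10L)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines("chrI\t0\t10\t2", p)
  tr <- read_bedgraph(p, sizes)
  expect_equal(tr$values$chrI, c(rep(2, 10), rep(0, 10)))
  expect_equal(tr$values$chrII, rep(0, 10))

  writeLines(character(), p)
  expect_equal(sum(read_bedgraph(p, sizes)$values$chrI), 0)

  writeLines(c("chrI\t0\t5\t1", "chrI\t3\t8\t2"), p)
  expect_error(read_bedgraph(p, sizes), "conflicting")
  writeLines("chrX\t0\t5\t1", p)
  expect_error(read_bedgraph(p, sizes), "unknown chromosome")
  writeLines("chrI\t0\t50\t1", p)
  expect_error(read_bedgraph(p, sizes), "bounds")
})

test_that("bedGraph write-then-read is the identity on value arrays", {
  set.seed(11)
  vals <- list(chrI = as.numeric(rpois(1000, 3)) + rep(c(0, 0.25), 500),
               chrII = numeric(200))
  tr <- coverage_track(vals, factor = "Nrd1", genotype = "pcf11-9",
                       temperature = 37, replicate = 2L)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, lengths(vals), factor = "Nrd1",
                        genotype = "pcf11-9", temperature = 37,
                        replicate = 2L)
  expect_identical(back$values, tr$values)
  expect_identical(back$genotype, "pcf11-9")
})

test_that("coverage_track validates inputs", {
  expect_error(coverage_track(list(chrI = c(1, -2))), ">= 0")
  expect_error(coverage_track(list(chrI = c(1, NA))), "finite")
  expect_error(coverage_track(list(c(1, 2))), "named")
})

test_that("moving_average matches the definition and the brute-force oracle", {
  expect_equal(moving_average(rep(7, 50), 13), rep(7, 50))
  expect_equal(moving_average(c(0, 0, 0, 9, 0, 0, 0), 3),
               c(0, 0, 3, 3, 3, 0, 0))
  expect_error(moving_average(1:5, 0), ">= 1")

  brute <- function(x, w) {
    n <- length(x)
    vapply(seq_len(n), function(i) {
      lo <- max(i - (w - 1) %/% 2, 1); hi <- min(i + w %/% 2, n)
      mean(x[lo:hi])
    }, numeric(1))
  }
  set.seed(2)
  x <- runif(2000) * 100
  for (w in c(1L, 7L, 220L))
    expect_equal(moving_average(x, w), brute(x, w), tolerance = 1e-12)
  # never outside [min, max] of the input
  expect_true(all(moving_average(x, 220) >= min(x)))
  expect_true(all(moving_average(x, 220) <= max(x)))
})

test_that("anchored_vector is strand-aware and matches direct indexing", {
  ramp <- manual_track(0:9999)
  u_plus <- manual_unit("+")
  u_minus <- manual_unit("-")
  # + strand: anchor at mature_end = 1199; window -2/+2 ascends through it
  av <- anchored_vector(ramp, u_plus, "mature_3p_end", 2, 2)
  expect_equal(av$values, c(1197, 1198, 1199, 1200))
  expect_equal(av$positions, -2:1)
  # - strand: same relative window descends in genomic coordinates
  avm <- anchored_vector(ramp, u_minus, "mature_3p_end", 2, 2)
  anchor_m <- u_minus$mature_end
  expect_equal(avm$values, c(anchor_m + 2, anchor_m + 1, anchor_m,
                             anchor_m - 1))
  # masked out-of-bounds bases + direct-index oracle
  u_edge <- manual_unit("+", start = 0L, mature_rel = 6L)
  av2 <- anchored_vector(ramp, u_edge, "mature_3p_end", 10, 5)
  expect_equal(sum(!av2$mask), 5)   # anchor at 5, 10 upstream -> 5 invalid
  oracle <- vapply(-10:4, function(r) {
    g <- 5 + r
    if (g < 0) NA_real_ else ramp$values$chrI[g + 1]
  }, numeric(1))
  expect_equal(av2$values, oracle)
  # binning averages constituent bases; strand-symmetric track is invariant
  avb <- anchored_vector(ramp, u_plus, "mature_3p_end", 10, 10, bin = 5)
  expect_equal(avb$values[1], mean(1189:1193))
  flat <- manual_track(rep(4, 10000))
  expect_equal(anchored_vector(flat, u_plus, "mature_3p_end", 50, 50)$values,
               anchored_vector(flat, u_minus, "mature_3p_end", 50, 50)$values)
  # missing anchor errors with the unit name
  u_cut <- u_plus; u_cut$mature_end <- NA_integer_; u_cut$id <- "CUT_x"
  expect_error(anchored_vector(ramp, u_cut, "mature_3p_end", 5, 5), "CUT_x")
})

test_that("region_mean and fold_enrichment follow their contracts", {
  tr <- manual_track(c(rep(7, 100), rep(0, 100)))
  expect_equal(region_mean(tr, genomic_region("chrI", 10, 60)), 7)
  expect_equal(region_mean(tr, genomic_region("chrI", 100, 200)), 0)
  set.seed(3)
  rtr <- manual_track(runif(500))
  reg <- genomic_region("chrI", 37, 129)
  expect_equal(region_mean(rtr, reg),
               sum(rtr$values$chrI[38:129]) / 92, tolerance = 1e-12)

  t2 <- manual_track(c(rep(50, 100), rep(10, 100)))
  fe <- fold_enrichment(t2, genomic_region("chrI", 0, 100),
                        genomic_region("chrI", 100, 200))
  expect_equal(as.numeric(fe), 5)
  expect_equal(as.numeric(fold_enrichment(t2, genomic_region("chrI", 0, 50),
                                          genomic_region("chrI", 50, 100))),
               1)
  # scale invariance
  t3 <- manual_track(t2$values$chrI * 17.3)
  expect_equal(as.numeric(fold_enrichment(t3, genomic_region("chrI", 0, 100),
                                          genomic_region("chrI", 100, 200))),
               5)
  zero <- manual_track(numeric(100))
  expect_error(fold_enrichment(zero, genomic_region("chrI", 0, 10),
                               genomic_region("chrI", 50, 60)),
               "pseudocount")
})

test_that("fold_enrichment recovers a planted enrichment under Poisson noise", {
  set.seed(4)
  depth <- 100
  mu <- c(rep(4 * depth, 300), rep(depth, 300))
  tr <- manual_track(rpois(600, mu))
  fe <- as.numeric(fold_enrichment(tr, genomic_region("chrI", 0, 300),
                                   genomic_region("chrI", 300, 600)))
  se <- 4 * sqrt(1 / (4 * depth * 300) + 1 / (depth * 300))
  expect_lt(abs(fe - 4), 3 * se)
})

test_that("unit annotation round-trips through BED6 + sidecar", {
  ann <- make_toy_annotation(tiny_config())
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_units(ann$units, bed, tsv)
  back <- read_units(bed, tsv)
  pub <- c("id", "unit_class", "chrom", "start", "end", "strand", "tss",
           "mature_end", "nbs_center", "pas_position")
  expect_equal(back[pub], ann$units[pub], ignore_attr = TRUE)
  # empty annotation gives valid, readable files
  empty <- ann$units[0, ]
  write_units(empty, bed, tsv)
  expect_equal(nrow(read_units(bed, tsv)), 0)
})

test_that("GFF3 regions convert to 0-based half-open", {
  p <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=x"), p)
  g <- read_gff3_regions(p)
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(g$id, "g1")
})
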