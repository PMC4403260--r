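test_that("make_toy_annotation respects counts, emptiness and determinism", {
  cfg <- simulation_config(n_units = c(snoRNA = 1L, CUT = 0L, SUT = 0L,
                                       XUT = 0L),
                           chrom_lengths = c(chrI = 10000L))
  ann <- make_toy_annotation(cfg)
  expect_equal(nrow(ann$units), 1)
  expect_equal(ann$units$unit_class, "snoRNA")
  u <- ann$units[1, ]
  # mature end strictly inside the annotated unit, NBS present
  rel_mature <- abs(u$mature_end - u$tss)
  expect_lt(rel_mature, u$end - u$start)
  expect_false(is.na(u$nbs_center))

  ann0 <- make_toy_annotation(
    simulation_config(n_units = c(snoRNA = 0L, CUT = 0L, SUT = 0L,
                                  XUT = 0L)))
  expect_equal(nrow(ann0$units), 0)
  bed <- withr::local_tempfile(); tsv <- withr::local_tempfile()
  write_units(ann0$units, bed, tsv)   # valid empty files
  expect_equal(nrow(read_units(bed, tsv)), 0)

  # determinism: identical frames and byte-identical annotation files
  cfg50 <- simulation_config(seed = 1L)
  a1 <- make_toy_annotation(cfg50)
  a2 <- make_toy_annotation(cfg50)
  expect_identical(a1, a2)
  b1 <- withr::local_tempfile(); t1 <- withr::local_tempfile()
  b2 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_units(a1$units, b1, t1)
  write_units(a2$units, b2, t2)
  expect_identical(readLines(b1), readLines(b2))
  expect_identical(readLines(t1), readLines(t2))

  # units on the same strand never overlap
  for (ch in unique(a1$units$chrom)) for (s in c("+", "-")) {
    x <- a1$units[a1$units$chrom == ch & a1$units$strand == s, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
})

test_that("placement failure names the offending class", {
  cfg <- simulation_config(n_units = c(snoRNA = 40L, CUT = 0L, SUT = 0L,
                                       XUT = 0L),
                           chrom_lengths = c(chrI = 20000L))
  expect_error(make_toy_annotation(cfg), "snoRNA")
})

test_that("expected_occupancy follows the survival x dwell closed form", {
  # zero hazard, constant dwell -> flat
  expect_equal(expected_occupancy(rep(0, 100), rep(2, 100)), rep(2, 100))
  # constant hazard 0.01 from the start: density after 100 hazard bases
  h <- c(rep(0, 100), rep(0.01, 400))
  dens <- expected_occupancy(h, rep(1, 500))
  expect_equal(dens[201] / dens[100], 0.99^100, tolerance = 1e-12)
  # non-increasing where dwell is constant; flat upstream of first element
  expect_true(all(diff(dens) <= 1e-14))
  expect_equal(dens[1:100], rep(1, 100))
  expect_error(expected_occupancy(c(-0.1, 0), c(1, 1)), "hazards")
  expect_error(expected_occupancy(c(0, 0), c(1, 0)), "dwell")
})

test_that("Monte-Carlo trajectories agree with the closed form", {
  h <- c(rep(0, 100), rep(0.01, 400))
  d <- rep(1, 500)
  dens <- expected_occupancy(h, d)
  mc <- mc_occupancy(h, d, n_traj = 1e4, seed = 42)
  for (i in c(150, 201, 300)) {
    s <- dens[i]
    se <- sqrt(s * (1 - s) / 1e4)
    expect_lt(abs(mc$occupancy[i] - s), 3 * se)
  }
  # convergence: sup-norm error shrinks from 1e3 to 1e5 trajectories
  sup3 <- max(abs(mc_occupancy(h, d, 1e3, seed = 7)$occupancy - dens))
  sup5 <- max(abs(mc_occupancy(h, d, 1e5, seed = 7)$occupancy - dens))
  expect_lt(sup5, sup3)
})

test_that("pause dwell produces the downstream pile-up phenotype", {
  # pause x5 over [+50, +300] past the anchor with weak distal hazard:
  # density downstream of the NBS exceeds the upstream plateau
  anchor <- 500L
  n <- 1500L
  h <- numeric(n)
  h[(anchor + 150):(anchor + 350)] <- 0.006 * 0.2
  d <- rep(1, n)
  d[(anchor + 50):(anchor + 300)] <- 5
  dens <- expected_occupancy(h, d)
  expect_gt(mean(dens[(anchor + 100):(anchor + 300)]),
            mean(dens[(anchor - 100):anchor]))
  mc <- mc_occupancy(h, d, n_traj = 2e4, seed = 5)
  expect_gt(mean(mc$occupancy[(anchor + 100):(anchor + 300)]),
            mean(mc$occupancy[(anchor - 100):anchor]))
})

test_that("simulate_tracks: degenerate depth, determinism, factor checks", {
  cfg <- tiny_config(n_units = c(snoRNA = 3L, CUT = 0L, SUT = 0L, XUT = 0L),
                     chrom_lengths = c(chrI = 30000L),
                     depth = 0, background = 0)
  ann <- make_toy_annotation(cfg)
  spec <- data.frame(factor = "PolII_total", genotype = "WT",
                     temperature = 25)
  sim <- simulate_tracks(cfg, ann, spec)
  expect_equal(sum(sim$tracks[[1]]$values$chrI), 0)

  cfg2 <- tiny_config(n_units = c(snoRNA = 3L, CUT = 3L, SUT = 0L,
                                  XUT = 0L),
                      chrom_lengths = c(chrI = 40000L))
  ann2 <- make_toy_annotation(cfg2)
  specs <- data.frame(factor = c("PolII_total", "Nrd1"),
                      genotype = "WT", temperature = 25)
  s1 <- simulate_tracks(cfg2, ann2, specs)
  s2 <- simulate_tracks(cfg2, ann2, specs)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)
  # all emitted signal finite and >= 0
  expect_true(all(vapply(s1$tracks, function(t)
    all(is.finite(t$values$chrI)) && all(t$values$chrI >= 0), logical(1))))

  expect_error(simulate_tracks(cfg2, ann2,
                               data.frame(factor = "H3K4me3",
                                          genotype = "WT",
                                          temperature = 25)),
               "supported")
  expect_error(simulate_tracks(cfg2, ann2,
                               data.frame(factor = "Nrd1",
                                          genotype = "rpb1-1",
                                          temperature = 25)),
               "modifier table")
})

test_that("mutant downstream signal matches the closed-form ratio", {
  cfg <- tiny_config(n_units = c(snoRNA = 1L, CUT = 0L, SUT = 0L, XUT = 0L),
                     chrom_lengths = c(chrI = 20000L),
                     depth = 200, background = 0,
                     pas_prob = c(snoRNA = 0, CUT = 0, SUT = 0, XUT = 0,
                                  NAPC = 0, PC = 1),
                     defect_prob = c(snoRNA = 1, CUT = 0, SUT = 0, XUT = 0,
                                     NAPC = 0, PC = 0))
  ann <- make_toy_annotation(cfg)
  u <- ann$units[1, ]
  specs <- data.frame(factor = "PolII_total", genotype = c("WT", "pcf11-9"),
                      temperature = 25)
  sim <- simulate_tracks(cfg, ann, specs)
  g <- termwindow:::rel_to_genomic(u$mature_end, u$strand, 150L, 650L)
  win <- (g[1] + 1):g[2]
  s_wt <- sum(sim$tracks[[1]]$values$chrI[win])
  s_mut <- sum(sim$tracks[[2]]$values$chrI[win])
  # closed-form expectation over the same window (anchor-relative [150, 650))
  ta_rel <- abs(u$mature_end - u$tss)
  e_wt <- unit_expected_occupancy(u, cfg, "WT", 25)
  e_mut <- unit_expected_occupancy(u, cfg, "pcf11-9", 25)
  pick <- e_wt$rel >= ta_rel + 150 & e_wt$rel < ta_rel + 650
  true_ratio <- sum(e_mut$density[pick]) / sum(e_wt$density[pick])
  obs_ratio <- s_mut / s_wt
  se <- obs_ratio * sqrt(1 / s_mut + 1 / s_wt)
  expect_gt(obs_ratio, 1)
  expect_lt(abs(obs_ratio - true_ratio), 3 * se)
})

test_that("planted defect flag is monotone in the distal-hazard multiplier", {
  cfg <- tiny_config(n_units = c(snoRNA = 6L, CUT = 6L, SUT = 0L, XUT = 0L),
                     chrom_lengths = c(chrI = 60000L))
  ann <- make_toy_annotation(cfg)
  mults <- c(0.5, 0.3, 0.2, 0.1, 0.02)
  flags <- sapply(mults, function(m) {
    cfg$genotypes$distal_mult[cfg$genotypes$genotype == "pcf11-9"] <- m
    tr <- simulation_truth(cfg, ann$units, "pcf11-9", 25)
    tr$planted_defect
  })
  # once defective, lowering the multiplier never reverts a unit
  for (i in seq_len(nrow(flags)))
    expect_true(all(diff(as.integer(flags[i, ])) >= 0))
})

test_that("the 37C speed multiplier shifts the survival midpoint downstream", {
  cfg <- tiny_config(n_units = c(snoRNA = 5L, CUT = 5L, SUT = 5L, XUT = 5L),
                     chrom_lengths = c(chrI = 100000L))
  ann <- make_toy_annotation(cfg)
  for (i in seq_len(nrow(ann$units))) {
    u <- ann$units[i, ]
    midpoint <- function(temp) {
      d <- unit_expected_occupancy(u, cfg, "WT", temp)
      s <- d$density / d$density[1]      # dwell constant for WT
      which(s < 0.5)[1]
    }
    m25 <- midpoint(25); m37 <- midpoint(37)
    if (!is.na(m25) && !is.na(m37)) expect_gt(m37, m25)
  }
})

test_that("fixtures round-trip through the readers", {
  cfg <- tiny_config(n_units = c(snoRNA = 5L, CUT = 5L, SUT = 0L, XUT = 0L),
                     chrom_lengths = c(chrI = 50000L))
  ann <- make_toy_annotation(cfg)
  specs <- data.frame(factor = c("PolII_total", "Pcf11"),
                      genotype = "WT", temperature = 25)
  sim <- simulate_tracks(cfg, ann, specs)
  dir <- withr::local_tempdir()
  write_fixture(ann, sim$tracks, sim$truth, cfg, dir)
  fx <- read_fixture(dir)
  expect_equal(nrow(fx$units), 10)
  expect_equal(fx$units$start, ann$units$start)
  expect_equal(fx$units$end, ann$units$end)
  expect_identical(fx$chrom_sizes, ann$chrom_sizes)
  # bedGraph sums equal the in-memory sums (direct-summation oracle)
  for (nm in names(sim$tracks))
    expect_equal(sum(fx$tracks[[nm]]$values$chrI),
                 sum(sim$tracks[[nm]]$values$chrI))
  expect_identical(fx$tracks[["Pcf11_WT_25_r1"]]$factor, "Pcf11")
})
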