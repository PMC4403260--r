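test_that("readthrough index: identity, stated arithmetic, invariances", {
  n <- 5000L
  u <- manual_unit("+", start = 1000L, mature_rel = 200L)
  # identical tracks -> RI = 1
  set.seed(20)
  v <- as.numeric(rpois(n, 8)) + 1
  wt <- manual_track(v); mut <- manual_track(v, genotype = "pcf11-9")
  call <- readthrough_index(wt, mut, u)
  expect_equal(call$readthrough_index, 1)
  expect_false(call$low_signal)

  # constant windows R_wt = R_mut = 10, D_wt = 2, D_mut = 6 -> RI = 3
  mk <- function(refv, downv) {
    x <- numeric(n)
    x[1001:1199] <- refv       # ref window [tss, anchor) = [1000, 1199)
    x[(1199 + 151):(1199 + 650)] <- downv  # downstream [+150, +650)
    manual_track(x)
  }
  call2 <- readthrough_index(mk(10, 2), mk(10, 6), u, smooth = 1L)
  expect_equal(call2$readthrough_index, 3)

  # invariance under common scaling; equivariance under mutant downstream x k
  call3 <- readthrough_index(mk(10 * 7, 2 * 7), mk(10 * 7, 6 * 7), u,
                             smooth = 1L)
  expect_equal(call3$readthrough_index, 3)
  call4 <- readthrough_index(mk(10, 2), mk(10, 12), u, smooth = 1L)
  expect_equal(call4$readthrough_index, 6)

  # temperature labels must match
  hot <- manual_track(v, temperature = 37)
  expect_error(readthrough_index(wt, hot, u), "temperature")
  # windows outside the chromosome bounds error
  u_edge <- manual_unit("+", start = 4000L, L = 900L, mature_rel = 500L)
  expect_error(readthrough_index(wt, mut, u_edge), "bounds")
})

test_that("low-signal filter follows quantile and absolute-floor contracts", {
  calls <- manual_calls(sprintf("u%d", 1:4), r_wt = c(1, 2, 3, 4))
  # floor 0 flags nothing
  f0 <- low_signal_filter(calls, min_reference = 0)
  expect_false(any(f0$low_signal))
  # default 0.25 quantile flags exactly the weakest of {1,2,3,4}
  fq <- low_signal_filter(calls)
  expect_identical(fq$low_signal, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(fq$is_defective[1], FALSE)
  # absolute override: zero-expression units and only those
  calls2 <- manual_calls(sprintf("u%d", 1:20),
                         r_wt = c(rep(0, 2), rpois(18, 50) + 20))
  f2 <- low_signal_filter(calls2, min_reference = 1)
  expect_identical(which(f2$low_signal), 1:2)
  expect_error(low_signal_filter(calls[0, ]), "empty")
})

test_that("classification thresholds and monotonicity", {
  calls <- manual_calls(c("a", "b", "c"), d_wt = c(2, 2, 2),
                        d_mut = c(2, 30, 30), ri = c(1, 10, 1.4))
  out <- classify_defective(calls)
  expect_identical(out$is_defective, c(FALSE, TRUE, FALSE))
  # monotone in RI at fixed absolute increase
  ri_grid <- seq(0.5, 5, by = 0.25)
  flags <- vapply(ri_grid, function(r)
    classify_defective(manual_calls("x", d_wt = 1, d_mut = 10,
                                    ri = r))$is_defective, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
  # the absolute-increase guard suppresses large ratios of tiny signals
  tiny <- manual_calls("t", d_wt = 0.001, d_mut = 0.01, ri = 10)
  expect_false(classify_defective(tiny, background = 0.2)$is_defective)
})

test_that("class fractions conserve counts", {
  calls <- rbind(
    manual_calls(sprintf("s%d", 1:4), unit_class = "snoRNA",
                 low = c(FALSE, FALSE, FALSE, TRUE),
                 defective = c(TRUE, TRUE, FALSE, FALSE)),
    manual_calls(sprintf("c%d", 1:2), unit_class = "CUT",
                 defective = c(TRUE, TRUE)))
  fr <- class_fractions(calls)
  sn <- fr[fr$unit_class == "snoRNA", ]
  expect_equal(sn$n_analyzed + sn$n_low_signal, sn$n_total)
  expect_equal(sn$fraction, 2 / 3)
  expect_equal(fr$fraction[fr$unit_class == "CUT"], 1)
  none <- class_fractions(manual_calls("z", defective = FALSE))
  expect_equal(none$fraction, 0)
  expect_error(class_fractions(manual_calls("z")), "classified")
})

test_that("pathway assignment crosses the two contrasts", {
  cid <- manual_calls(c("a", "b", "c", "d"),
                      defective = c(TRUE, FALSE, TRUE, FALSE))
  clv <- manual_calls(c("a", "b", "c", "d"),
                      defective = c(FALSE, TRUE, TRUE, FALSE))
  pw <- pathway_assignment(cid, clv)
  expect_equal(pw$assignments$category,
               c("CID-only", "cleavage-only", "both", "neither"))
  expect_equal(sum(pw$counts), 4)
  expect_error(pathway_assignment(cid, clv[1:3, ]), "missing")
})

test_that("null contrasts stay under the false-positive budget", {
  # mutant re-simulated from WT parameters: defective calls are noise only
  cfg <- tiny_config(n_units = c(snoRNA = 15L, CUT = 15L, SUT = 0L,
                                 XUT = 0L),
                     chrom_lengths = c(chrI = 100000L), seed = 3L)
  ann <- make_toy_annotation(cfg)
  specs <- data.frame(factor = "PolII_total", genotype = "WT",
                      temperature = 25, replicate = 1:6)
  sim <- simulate_tracks(cfg, ann, specs)
  fp <- 0L; n <- 0L
  for (i in seq(1, 5, by = 2)) {
    calls <- readthrough_calls(sim$tracks[[i]], sim$tracks[[i + 1]],
                               ann$units)
    calls <- classify_defective(low_signal_filter(calls,
                                                  min_reference = 0.5),
                                background = cfg$background)
    fp <- fp + sum(calls$is_defective)
    n <- n + sum(!calls$low_signal)
  }
  expect_lte(fp / n, 0.05)
})
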