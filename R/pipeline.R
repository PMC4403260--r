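#' Demo run configuration
#'
#' A complete, fast end-to-end configuration: a 200-unit cohort (50 each of
#' snoRNA, CUTs, SUTs, XUTs), Pol II contrasts for two mutant genotypes at
#' 25 and 37 degrees, Nrd1/Pcf11 recruitment analysis over the snoRNA
#' cohort, and an amplicon panel over the first snoRNA locus. Completes on
#' one CPU in well under five minutes.
#'
#' @param seed Global seed.
#' @return A run-config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      chrom_lengths = c(chrI = 350000L, chrII = 350000L),
      n_units = c(snoRNA = 50L, CUT = 50L, SUT = 50L, XUT = 50L)),
    wt_genotype = "WT",
    contrasts = data.frame(
      mutant = c("pcf11-9", "pcf11-9", "nrd1-102", "nrd1-102"),
      temperature = c(25, 37, 25, 37)),
    thresholds = list(ri = 1.5, quantile = 0.25, min_reference = NULL),
    metagene = list(classes = c("snoRNA", "CUT"), upstream = 500L,
                    downstream = 1000L, bin = 10L, smooth = 220L),
    heatmap = list(upstream = 500L, downstream = 1000L, bin = 10L),
    peaks = list(cohort_class = "snoRNA", upstream = 400L,
                 downstream = 800L, search_a = c(-200, 400),
                 search_b = c(0, 600), smooth = 220L, n_perm = 2000L),
    overlap = list(set_a = "pcf11-9", set_b = "nrd1-102", temperature = 25),
    pathway = NULL,
    amplicons = "auto",
    make_plots = FALSE)
}

#' Validate a run configuration
#'
#' Runs every referential and numeric check without touching the
#' filesystem. An empty return value means the configuration is runnable.
#'
#' @param config Run-config list (see [demo_config()]).
#' @return Character vector of findings (empty when valid).
#' @export
validate_run_config <- function(config) {
  findings <- character()
  say <- function(...) findings <<- c(findings, sprintf(...))
  if (is.null(config$seed)) say("missing global seed")
  scfg <- NULL
  if (is.null(config$simulate)) {
    say("missing 'simulate' block (external track input is not configured here)")
  } else {
    scfg <- tryCatch(do.call(simulation_config, config$simulate),
                     error = function(e) {
                       say("invalid simulate block: %s", conditionMessage(e))
                       NULL
                     })
  }
  wt <- config$wt_genotype %||% "WT"
  known <- if (!is.null(scfg)) scfg$genotypes$genotype else character()
  if (!is.null(scfg) && !(wt %in% known))
    say("wild-type genotype '%s' missing from the modifier table", wt)
  ctr <- config$contrasts
  if (!is.null(ctr) && nrow(ctr)) {
    for (i in seq_len(nrow(ctr))) {
      if (!is.null(scfg) && !(ctr$mutant[i] %in% known))
        say("contrast %d: unknown genotype '%s'", i, ctr$mutant[i])
      if (!ctr$temperature[i] %in% c(25, 37))
        say("contrast %d: temperature must be 25 or 37", i)
      if (identical(ctr$mutant[i], wt))
        say("contrast %d pairs the wild type against itself", i)
    }
  }
  for (role in c("set_a", "set_b")) {
    g <- config$overlap[[role]]
    if (!is.null(g) && !is.null(ctr) &&
        !(g %in% ctr$mutant))
      say("overlap %s genotype '%s' has no contrast", role, g)
  }
  if (has_block(config$pathway)) {
    for (role in c("cid", "cleavage")) {
      g <- config$pathway[[role]]
      if (is.null(g)) say("pathway block missing '%s' genotype", role)
      else if (!is.null(ctr) && !(g %in% ctr$mutant))
        say("pathway %s genotype '%s' has no contrast", role, g)
    }
  }
  findings
}

has_block <- function(x) !is.null(x) && length(x) > 0

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

config_hash <- function(path) unname(tools::md5sum(path))

# Build a 5-amplicon panel tiling the first snoRNA locus plus a background
# amplicon in the inter-unit gap well past the downstream flank.
auto_amplicon_panel <- function(units, chrom_sizes, flank) {
  sn <- units[units$unit_class == "snoRNA", ]
  if (!nrow(sn)) return(NULL)
  u <- sn[1, ]
  anchor <- u$mature_end
  offs <- list(c(-200L, -50L), c(-20L, 130L), c(160L, 310L), c(340L, 490L),
               c(520L, 670L))
  rows <- lapply(seq_along(offs), function(i) {
    g <- rel_to_genomic(anchor, u$strand, offs[[i]][1], offs[[i]][2])
    data.frame(id = as.character(i), chrom = u$chrom, start = g[1],
               end = g[2], role = "query")
  })
  bg_start <- if (u$strand == "-") u$end + flank + 200L
              else max(0L, u$start - flank - 400L)
  rows[[length(rows) + 1L]] <- data.frame(
    id = "bg", chrom = u$chrom, start = bg_start, end = bg_start + 200L,
    role = "background")
  amplicon_panel(do.call(rbind, rows))
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> quantify -> classify -> test -> report from a
#' single configuration: emits per-unit readthrough calls and class
#' fractions for every contrast, overlap/Venn statistics between two
#' defective sets, optional pathway assignment, metagene profiles per
#' genotype/temperature, the snoRNA heat-map matrix, the Nrd1/Pcf11 peak
#' table with its shift test, amplicon quantifications, and a
#' machine-readable manifest (config hash, seed, stage counts). All outputs
#' are deterministic under a fixed seed.
#'
#' @param config Run-config list (see [demo_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  findings <- validate_run_config(config)
  if (length(findings))
    stop("invalid configuration:\n  - ", paste(findings, collapse = "\n  - "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  emit <- function(d, name) {
    outputs <<- c(outputs, name)
    write_tsv(d, file.path(out_dir, name))
  }
  pvals <- list()

  config$simulate$seed <- config$seed
  scfg <- do.call(simulation_config, config$simulate)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  hash <- config_hash(cfg_path)

  ann <- run_stage("simulate", make_toy_annotation(scfg))
  units <- ann$units
  emit(units, "units_full.tsv")
  write_units(units, file.path(out_dir, "units.bed"),
              file.path(out_dir, "units.tsv"))
  write_chrom_sizes(ann$chrom_sizes, file.path(out_dir, "chrom.sizes"))
  outputs <- c(outputs, "units.bed", "units.tsv", "chrom.sizes")

  wt <- config$wt_genotype %||% "WT"
  ctr <- config$contrasts
  have_contrasts <- !is.null(ctr) && nrow(ctr) > 0
  specs <- data.frame(factor = character(), genotype = character(),
                      temperature = numeric())
  if (have_contrasts) {
    pol <- unique(rbind(
      data.frame(factor = "PolII_total", genotype = wt,
                 temperature = unique(ctr$temperature)),
      data.frame(factor = "PolII_total", genotype = ctr$mutant,
                 temperature = ctr$temperature)))
    specs <- rbind(specs, pol)
  }
  if (has_block(config$peaks))
    specs <- rbind(specs, data.frame(factor = c("Nrd1", "Pcf11"),
                                     genotype = wt, temperature = 25))
  sim <- NULL
  n_filtered <- list()
  calls_by <- list()
  if (nrow(specs)) {
    sim <- run_stage("simulate", simulate_tracks(scfg, ann, specs))
    emit(sim$truth, "truth.tsv")
    get_track <- function(factor, genotype, temperature) {
      nm <- sprintf("%s_%s_%g_r1", factor, genotype, temperature)
      tr <- sim$tracks[[nm]]
      if (is.null(tr)) stop("missing simulated track ", nm)
      tr
    }
    if (have_contrasts) {
      thr <- config$thresholds %||% list()
      for (i in seq_len(nrow(ctr))) {
        gt <- ctr$mutant[i]; tp <- ctr$temperature[i]
        label <- sprintf("%s_%g", gt, tp)
        calls <- run_stage(paste0("readthrough:", label), {
          calls <- readthrough_calls(get_track("PolII_total", wt, tp),
                                     get_track("PolII_total", gt, tp),
                                     units)
          calls <- low_signal_filter(calls,
                                     min_reference = thr$min_reference,
                                     quantile = thr$quantile %||% 0.25)
          classify_defective(calls, ri_threshold = thr$ri %||% 1.5,
                             background = scfg$background)
        })
        n_filtered[[label]] <- sum(calls$low_signal)
        calls_by[[label]] <- calls
        emit(calls, sprintf("calls_%s.tsv", label))
        emit(cbind(contrast = label, class_fractions(calls)),
             sprintf("class_fractions_%s.tsv", label))
      }
    }

    ov <- config$overlap
    if (has_block(ov) && have_contrasts) {
      run_stage("overlap", {
        tp <- ov$temperature %||% 25
        la <- sprintf("%s_%g", ov$set_a, tp)
        lb <- sprintf("%s_%g", ov$set_b, tp)
        ca <- calls_by[[la]]; cb <- calls_by[[lb]]
        if (is.null(ca) || is.null(cb))
          stop("overlap sets need contrasts ", la, " and ", lb)
        universe <- intersect(ca$id[!ca$low_signal], cb$id[!cb$low_signal])
        A <- intersect(ca$id[ca$is_defective], universe)
        B <- intersect(cb$id[cb$is_defective], universe)
        res <- overlap_test(A, B, universe)
        vn <- venn_counts(A, B, universe)
        pvals[["overlap_enrichment"]] <- res$p_enrichment
        jsonlite::write_json(
          list(set_a = la, set_b = lb,
               universe_size = res$universe_size, size_a = res$size_a,
               size_b = res$size_b, overlap = res$overlap,
               fraction_of_a = res$fraction,
               p_enrichment = res$p_enrichment,
               p_depletion = res$p_depletion, venn = as.list(vn)),
          file.path(out_dir, "overlap.json"), auto_unbox = TRUE,
          digits = NA)
        outputs <- c(outputs, "overlap.json")
      })
    }

    if (has_block(config$pathway)) {
      run_stage("pathway", {
        tp <- config$pathway$temperature %||% 25
        la <- sprintf("%s_%g", config$pathway$cid, tp)
        lb <- sprintf("%s_%g", config$pathway$cleavage, tp)
        pw <- pathway_assignment(calls_by[[la]], calls_by[[lb]])
        emit(pw$assignments, "pathway.tsv")
        emit(data.frame(category = names(pw$counts),
                        count = as.integer(pw$counts)),
             "pathway_counts.tsv")
      })
    }

    mg <- config$metagene
    if (has_block(mg) && have_contrasts) {
      run_stage("metagene", {
        wtab <- contrast_windows()
        combos <- unique(rbind(data.frame(genotype = wt,
                                          temperature =
                                            unique(ctr$temperature)),
                               data.frame(genotype = ctr$mutant,
                                          temperature = ctr$temperature)))
        for (cl in mg$classes) {
          cohort <- units[units$unit_class == cl, ]
          if (!nrow(cohort)) next
          anchor <- wtab$anchor_kind[wtab$unit_class == cl]
          for (j in seq_len(nrow(combos))) {
            tr <- get_track("PolII_total", combos$genotype[j],
                            combos$temperature[j])
            m <- build_matrix(tr, cohort, anchor, mg$upstream,
                              mg$downstream, mg$bin)
            prof <- metagene_profile(m, mg$smooth %||% 220L)
            emit(as.data.frame(prof),
                 sprintf("metagene_%s_%s_%g.tsv", cl, combos$genotype[j],
                         combos$temperature[j]))
          }
        }
      })
    }

    hm <- config$heatmap
    sn <- units[units$unit_class == "snoRNA", ]
    if (has_block(hm) && nrow(sn) && have_contrasts) {
      run_stage("heatmap", {
        tr <- get_track("PolII_total", wt, ctr$temperature[1])
        h <- heatmap_matrix(tr, sn, hm$upstream, hm$downstream, hm$bin)
        m <- as.data.frame(h$matrix$values)
        names(m) <- sprintf("bin_%d", seq_len(ncol(m)))
        emit(cbind(data.frame(id = h$row_order,
                              marker_bin = h$marker_bin), m),
             "heatmap_matrix.tsv")
      })
    }

    pk <- config$peaks
    if (has_block(pk)) {
      run_stage("peaks", {
        cohort <- units[units$unit_class == (pk$cohort_class %||% "snoRNA"), ]
        if (nrow(cohort) >= 2) {
          anchor <- contrast_windows()
          anchor <- anchor$anchor_kind[anchor$unit_class ==
                                         (pk$cohort_class %||% "snoRNA")]
          res <- peak_shift_analysis(
            get_track("Nrd1", wt, 25), get_track("Pcf11", wt, 25), cohort,
            anchor, pk$upstream %||% 400L, pk$downstream %||% 800L,
            pk$search_a %||% c(-200, 400), pk$search_b %||% c(0, 600),
            pk$smooth %||% 220L, pk$n_perm %||% 2000L,
            seed = config$seed)
          pvals[["peak_shift"]] <- res$test$p_value
          emit(res$peaks, "peaks.tsv")
          jsonlite::write_json(
            list(n = res$test$n, mean_shift = res$test$statistic,
                 p_value = res$test$p_value, exact = res$test$exact,
                 n_perm = res$test$n_perm),
            file.path(out_dir, "peak_shift.json"), auto_unbox = TRUE,
            digits = NA)
          outputs <- c(outputs, "peak_shift.json")
        }
      })
    }

    if (has_block(config$amplicons) && have_contrasts) {
      run_stage("amplicons", {
        panel <- if (identical(config$amplicons, "auto"))
          auto_amplicon_panel(units, ann$chrom_sizes, scfg$flank)
        else amplicon_panel(config$amplicons)
        if (!is.null(panel)) {
          rows <- list()
          combos <- unique(rbind(
            data.frame(genotype = wt, temperature = unique(ctr$temperature)),
            data.frame(genotype = ctr$mutant,
                       temperature = ctr$temperature)))
          for (j in seq_len(nrow(combos))) {
            q <- amplicon_quant(list(get_track("PolII_total",
                                               combos$genotype[j],
                                               combos$temperature[j])),
                                panel)
            rows[[j]] <- cbind(genotype = combos$genotype[j],
                               temperature = combos$temperature[j],
                               q$summary)
          }
          emit(do.call(rbind, rows), "amplicons.tsv")
        }
      })
    }
  }

  # single multiple-testing pass over the emitted p-value battery
  if (length(pvals)) {
    battery <- data.frame(test = names(pvals),
                          p = unlist(pvals, use.names = FALSE))
    battery$p_bh <- stats::p.adjust(battery$p, method = "BH")
    emit(battery, "pvalue_battery.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("termwindow")),
    seed = config$seed,
    config_hash = hash,
    n_units = nrow(units),
    n_contrasts = if (have_contrasts) nrow(ctr) else 0L,
    n_low_signal = n_filtered,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
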