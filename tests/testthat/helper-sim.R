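# Shared fixture builders: everything is generated in code at test time.

# Small single-chromosome configuration for fast unit tests.
tiny_config <- function(n_units = c(snoRNA = 10L, CUT = 10L, SUT = 0L,
                                    XUT = 0L),
                        chrom_lengths = c(chrI = 120000L), seed = 1L, ...) {
  simulation_config(n_units = n_units, chrom_lengths = chrom_lengths,
                    seed = seed, ...)
}

# A deterministic hand-built track: one chromosome, explicit values.
manual_track <- function(values, ..., chrom = "chrI") {
  coverage_track(stats::setNames(list(as.numeric(values)), chrom), ...)
}

# One hand-placed snoRNA-like unit on a plus or minus strand.
manual_unit <- function(strand = "+", chrom = "chrI", start = 1000L,
                        L = 600L, mature_rel = 200L, chrom_len = 10000L) {
  end <- start + L
  tss <- if (strand == "+") start else end - 1L
  rel2gen <- function(r) if (strand == "+") tss + r else tss - r
  list(id = "snoRNA_t01", unit_class = "snoRNA", chrom = chrom,
       start = start, end = end, strand = strand, tss = tss,
       mature_end = rel2gen(mature_rel - 1L),
       nbs_center = rel2gen(mature_rel + 9L),
       pas_position = NA_integer_,
       term_anchor = rel2gen(mature_rel - 1L),
       has_distal = TRUE, has_pas = FALSE, responsive = TRUE,
       init_rate = 1)
}

# Minimal classified-call frame for filter/fraction/pathway tests.
manual_calls <- function(id, unit_class = "snoRNA", r_wt = 10, r_mut = 10,
                         d_wt = 1, d_mut = 1, ri = 1, low = FALSE,
                         defective = NA) {
  data.frame(id = id, unit_class = unit_class, genotype = "mut",
             temperature = 25, r_wt = r_wt, r_mut = r_mut, d_wt = d_wt,
             d_mut = d_mut, readthrough_index = ri, low_signal = low,
             is_defective = defective)
}
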