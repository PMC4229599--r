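# Shared builders for small in-code fixtures.

# Probe table with one probe per gene and exact channel ratios 2^m.
# `m` is a genes x arrays matrix of true log2 ratios.
probe_table_from_m <- function(m, baseline = 10) {
  genes <- rownames(m)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  out <- lapply(seq_len(ncol(m)), function(j) {
    data.frame(
      array_id = j,
      probe_id = paste0(genes, "_p1"),
      orf_id = genes,
      channel_sample = 2^(baseline + m[, j]),
      channel_reference = 2^baseline
    )
  })
  do.call(rbind, out)
}

# Gene models laid head-to-tail with given intergenic spacings and strands.
gene_models_from_spacings <- function(spacings, strands,
                                      lengths = NULL, contig = "c1") {
  n <- length(spacings) + 1
  stopifnot(length(strands) == n)
  if (is.null(lengths)) lengths <- rep(500, n)
  start <- numeric(n); start[1] <- 1
  for (i in seq_len(n - 1)) {
    start[i + 1] <- start[i] + lengths[i] - 1 + spacings[i] + 1
  }
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), contig = contig,
    start = start, end = start + lengths - 1, strand = strands
  )
}

# One CFU record.
cfu_record <- function(n0, nt, fermentation_id = 1, stress = "heat",
                       time_min = 30, replicate = 1) {
  data.frame(fermentation_id = fermentation_id, stress = stress,
             time_min = time_min, replicate = replicate,
             n0_cfu_per_ml = n0, nt_cfu_per_ml = nt)
}
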