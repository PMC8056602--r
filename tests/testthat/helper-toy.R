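# Shared toy-data builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

toy_genome <- function(L = 100000L, seed = 11, name = "chrT",
                       gc = 0.5) {
  make_reference(stats::setNames(as.integer(L), name), gc_fraction = gc,
                 seed = seed)
}

toy_peaks <- function(L = 100000L, n = 10, len = c(1000, 2000),
                      scores = "constant", seed = 12, name = "chrT") {
  make_peaks(stats::setNames(as.integer(L), name), n_peaks = n,
             len_range = len, scores = scores, seed = seed)
}

# A small complete simulation used by several tests.
toy_sim <- function(numreads = 20000, s = 0.5, pcr_p = 1, paired = FALSE,
                    readlen = 36, L = 200000L, seed = 5,
                    frag_shape = 4, frag_scale = 50, n_peaks = 10,
                    peak_len = c(2000, 3000), numcopies = NULL) {
  ref <- toy_genome(L, seed = 101)
  pks <- toy_peaks(L, n = n_peaks, len = peak_len, seed = 102)
  m <- chip_model(frag_shape, frag_scale,
                  f = estimate_f(pks, L), s = s, pcr_p = pcr_p)
  if (is.null(numcopies))
    numcopies <- suggest_numcopies(m, pks, chrom_lengths(ref), numreads)
  p <- experiment_params(numreads = numreads, readlen = readlen,
                         paired = paired, numcopies = numcopies,
                         seed = seed)
  list(sim = suppressWarnings(simreads(ref, pks, m, p)),
       ref = ref, peaks = pks, model = m, params = p)
}
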