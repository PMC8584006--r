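# Shared fixture builders; all data is generated in code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# random 13-mer windows centred on `central`; optional fixed (offset, residue)
# positions planted into every window
make_windows <- function(n, central = "S", fixed = NULL, prob = NULL) {
  m <- matrix(sample(AA20, n * 13, replace = TRUE, prob = prob), n, 13)
  m[, 7] <- central
  if (!is.null(fixed)) {
    for (off in names(fixed)) m[, as.integer(off) + 7] <- fixed[[off]]
  }
  apply(m, 1, paste, collapse = "")
}

# a quant table with explicit per-condition replicate values for one or more
# sites: `values` is a list site_id -> list(condition -> numeric replicates)
make_quant <- function(values) {
  conds <- names(values[[1]])
  reps <- length(values[[1]][[1]])
  samples <- as.vector(t(outer(conds, seq_len(reps), paste, sep = "_R")))
  m <- t(vapply(values, function(v) unlist(v[conds], use.names = FALSE),
                numeric(length(samples))))
  dimnames(m) <- list(names(values), samples)
  quant_table(m, setNames(rep(conds, each = reps), samples))
}

# small default-structure study used by several integration tests
small_study <- function(seed = 7, n_proteins = 250, ...) {
  simulate_phospho_study(sim_config(seed = seed, n_proteins = n_proteins,
                                    substrates_per_kinase = 8, ...))
}
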