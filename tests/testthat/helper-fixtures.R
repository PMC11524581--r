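# shared fixtures: parameter sets, random records, and the brute-force
# oracle used to cross-check the vectorized forward model

AA <- idpr2_amino_acids()

flat_params <- function(b = 0.04) {
  model_params(setNames(rep(1, 20), AA), b = b)
}

# params with one amino acid's factor raised
spiked_params <- function(aa = "A", q = 2, b = 1) {
  qv <- setNames(rep(1, 20), AA)
  qv[aa] <- q
  model_params(qv, b = b)
}

random_params <- function(b = runif(1, 0.01, 0.5)) {
  model_params(setNames(runif(20, 0.6, 1.6), AA), b = b)
}

# independent double-loop product over all residue pairs; deliberately
# naive so it cannot share a bug with the vectorized implementation
oracle_predict <- function(sequence, params) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  out <- numeric(n)
  for (pos in seq_len(n)) {
    v <- 1
    for (i in seq_len(n)) {
      s <- abs(i - pos)
      v <- v * (1 + (params$q[[aa[i]]] - 1) / (1 + params$b * s^2))
    }
    out[pos] <- v
  }
  out
}

random_record <- function(id = "rec", n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sq <- generate_sequence(n)
  vals <- runif(n, 1, 8)
  protein_record(id, sq, measured_r2 = vals)
}

# a tiny noiseless model-generated dataset for trainer unit tests
tiny_dataset <- function(n_proteins = 6, len = c(40, 60), noise = 0, seed = 7) {
  generate_dataset(synthetic_spec(n_proteins = n_proteins, length_range = len,
                                  noise_sd = noise, seed = seed))
}
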