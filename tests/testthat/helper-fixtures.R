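# shared fixture builders; everything is generated in code at test time

# deterministic toy expression matrix with named genes/samples
toy_matrix <- function(n_genes = 20, n_samples = 8, seed = 1, base = 100) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, base), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

# sample sheet for a single-timepoint responder/nonresponder design
toy_meta <- function(sample_ids, n_resp = 3, timepoint = "surgical") {
  data.frame(sample_id = sample_ids,
             patient_id = paste0("P", seq_along(sample_ids)),
             timepoint = timepoint,
             group = rep(c("responder", "nonresponder"),
                         c(n_resp, length(sample_ids) - n_resp)),
             stringsAsFactors = FALSE)
}

# clinical table scaffold for hand-constructed paired values
toy_clinical <- function(ids, bx, sx, measure = "ror") {
  n <- length(ids)
  df <- data.frame(patient_id = ids, age = 60, tumour_size = 1, histology = 1L,
                   grade = 1L, interval_days = 30, e2_baseline = 30,
                   e2_below_detection = FALSE, e2_post = 500,
                   ki67_bx = 5, ki67_sx = 5,
                   ror_bx = NA_real_, ror_sx = NA_real_,
                   stringsAsFactors = FALSE)
  df[[paste0(measure, "_bx")]] <- bx
  df[[paste0(measure, "_sx")]] <- sx
  df
}

# brute-force Cohen's kappa from two logical vectors (increase indicators)
kappa_bruteforce <- function(a, b) {
  n <- length(a)
  tab <- matrix(0, 2, 2)
  for (i in seq_len(n)) tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

with_seed_sample <- function(x, size, seed) {
  set.seed(seed)
  sample(x, size)
}

# exhaustive hypergeometric upper tail by enumerating all n-subsets
hyper_enum <- function(k, n, K, N) {
  universe <- seq_len(N)
  ref <- seq_len(K)
  draws <- utils::combn(universe, n)
  mean(apply(draws, 2, function(d) sum(d %in% ref) >= k))
}
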