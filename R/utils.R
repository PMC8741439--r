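# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# Derive an independent substream seed from a master seed and a stream index.
# Keeps results for one output object stable when other objects are added.
# Always returns a positive integer < 2^31.
substream_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(stream) * 2246822519) %% 2147483647
  as.integer(x %% 2147483646 + 1)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Shortest decimal representation that survives a read/write round trip.
num_to_string <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g")
  }, character(1))
}

# resolve gene symbols to matrix rownames, case-insensitively, keeping
# matrix row order out of it: result follows the order of `genes`
match_gene_rows <- function(genes, mat) {
  rn <- rownames(mat)
  idx <- match(toupper(as.character(genes)), toupper(rn))
  rn[idx[!is.na(idx)]]
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
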