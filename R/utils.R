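# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a parent seed and a unit id (stage name,
# subject index, ...). Stays within 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# Center a vector (average reference) and scale it to unit L2 norm.
# Zero-variance input comes back as all zeros.
normalize_topography <- function(v) {
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) return(v)
  v / nrm
}

# Row-wise center + unit-norm for a maps-in-rows matrix; zero-variance rows
# become zero rows.
normalize_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}
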