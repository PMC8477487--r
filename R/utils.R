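# RNG scoping: run code under a given seed without clobbering the caller's
# RNG stream, so training/simulation are pure functions of their seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based sub-seed derivation: stable, collision-poor, < 2^31.
derive_seed <- function(seed, counter) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in c(counter, 104729)) {
    x <- (x * 48271 + as.double(k) * 16807) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.dup_names <- function(x) unique(x[duplicated(x)])

.accuracy <- function(predicted, truth) mean(predicted == truth)
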