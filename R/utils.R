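# Seed hygiene: statistics functions take an explicit seed and must not
# disturb the caller's RNG stream.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# derive a reproducible 31-bit sub-seed from a master seed and a stream tag
sub_seed <- function(seed, tag) {
  x <- (as.double(seed) * 2654435761 + as.double(tag) * 40503) %% 2147483647
  as.integer(max(1, x))
}
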