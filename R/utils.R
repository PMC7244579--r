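# RNG bracketing: seed a computation without clobbering the caller's stream.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Benjamini-Hochberg, with the same validation contract as by_adjust().
.bh_adjust <- function(p) {
  if (anyNA(p)) stop("p must not contain missing values")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
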