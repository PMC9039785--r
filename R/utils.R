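# internal helpers shared across modules

# population SD (divisor N); the package-wide convention
popSD <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# deterministic stream of child seeds below 2^31 from one master seed
spawnSeeds <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# run an expression under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# truncated normal draws: mean 0, given sd, truncated at +/- trunc*sd
rtruncnorm0 <- function(n, sd = 0.05, trunc = 2) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- stats::rnorm(2L * (n - length(out)))
    out <- c(out, z[abs(z) <= trunc])
  }
  out[seq_len(n)] * sd
}

# softmax over rows of a 2-column matrix, numerically stabilised
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
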