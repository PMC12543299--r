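# Internal numerical helpers.

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

# Truncated-normal draws by inverse CDF; side = "pos" truncates to (0, Inf),
# side = "neg" to (-Inf, 0).
rtruncnorm_sign <- function(n, loc, scale, side = c("pos", "neg")) {
  side <- match.arg(side)
  p0 <- stats::pnorm(0, mean = loc, sd = scale)
  u <- if (side == "pos") stats::runif(n, p0, 1) else stats::runif(n, 0, p0)
  stats::qnorm(u, mean = loc, sd = scale)
}

# Deterministic per-component RNG substreams (L'Ecuyer-CMRG).  Returns a
# list of n .Random.seed values derived from a master seed; used so that
# per-participant updates consume independent streams and results do not
# depend on update scheduling.
make_streams <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  streams <- vector("list", n)
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Run expr with the RNG state in stream (a .Random.seed value); returns
# list(value, stream = advanced state).
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream, envir = globalenv())
  value <- expr
  new_stream <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  list(value = value, stream = new_stream)
}
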