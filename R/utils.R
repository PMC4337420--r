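# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
# If `seed` is NULL a seed is drawn from the current stream (and returned via
# attribute so results stay reproducible after the fact).
with_seed <- function(seed, expr) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  val <- force(expr)
  attr(val, "seed_used") <- seed
  val
}

stop_cw <- function(msg, class, ...) {
  stop(structure(class = c(class, "critweight_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

warn_cw <- function(msg, class) {
  warning(structure(class = c(class, "critweight_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

# Gaussian draw truncated at > lower, by rejection; means here sit many SDs
# above zero so rejection is cheap.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) {
    x <- rep(mean, length.out = n)
    if (any(x <= lower)) stop_cw("degenerate truncation: mean below bound", "cw_config_error")
    return(x)
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- which(x <= lower)
    guard <- guard + 1L
    if (guard > 10000L) stop_cw("truncated sampler failed to converge", "cw_config_error")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
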