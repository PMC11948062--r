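## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## seed the RNG for the calling function only; global RNG state is restored
## when the caller exits
set_local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(seed)
}

## deterministic per-stage seed from a global seed and a stage name,
## kept inside 32-bit integer range
derive_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 1013904223
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

## trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
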