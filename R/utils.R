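#' @keywords internal
"_PACKAGE"

# Deterministic sub-seeding: every stochastic stage draws from its own stream
# derived from (master seed, label), so adding a stage never perturbs another.
# The hash stays below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer((abs(master) %% m * 2654435761 %% m + h) %% m)
}

# Evaluate expr under a local RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

log_msg <- function(..., level = "INFO") {
  if (isTRUE(getOption("evmirnet.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
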