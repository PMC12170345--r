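# Internal helpers shared across modules.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic fan-out of one master seed into per-stage child seeds.
# Keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mtdyn <- function(...) stop(..., call. = FALSE)

# µm/min -> µm/s
um_min_to_um_s <- function(v) v / 60

deg <- function(rad) rad * 180 / pi
rad <- function(degree) degree * pi / 180

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop_mtdyn("zero-length vector cannot be normalized")
  v / n
}
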