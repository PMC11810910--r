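# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's RNG stream is untouched.  seed = NULL means "use the
# current stream" (no save/restore), so pipelines can thread one stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps all
# derived seeds below 2^31.  Deterministic, cheap FNV-style mix.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Luminance quantization used everywhere an 8-bit plane is produced:
# round half away from zero, then clip to [0, 255].
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

clip255 <- function(x) {
  pmin(pmax(x, 0), 255)
}

quantize_luminance <- function(x) {
  storage.mode(x) <- "double"
  out <- clip255(round_half_up(x))
  storage.mode(out) <- "integer"
  out
}

# 31-bit FNV-1a over a deparsed object, used to stamp pipeline outputs.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.double(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
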