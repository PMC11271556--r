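# Internal helpers: seed derivation, seeded evaluation, small validators.

#' Derive a reproducible child seed from a master seed and labels
#'
#' Stable 32-bit FNV-1a hash of the master seed plus any number of labels,
#' folded into the positive signed-integer range. Used so that per-patient and
#' per-operator seeds are a pure function of the master seed and the entity's
#' label: adding patients to a simulation never reshuffles earlier ones.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the child stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- paste(c(format(seed, scientific = FALSE), vapply(list(...), as.character, "")),
               collapse = "/")
  bytes <- utf8ToInt(key)
  # FNV-1a over bytes, arithmetic kept exact in doubles (< 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483645 + 1)
}

# xor for doubles holding 32-bit values
bitwXor64 <- function(a, b) {
  bitwXor(as.integer(a %% 2147483648) , as.integer(b)) +
    (a >= 2147483648) * 2147483648
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort_input <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "mfrkit_input_error")

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
    abort_input("`%s` must be a single finite number in [%s, %s]", name,
                format(lo), format(hi))
  invisible(x)
}
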