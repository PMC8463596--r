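#' @keywords internal
"_PACKAGE"

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# All package randomness flows through explicit seeds; no hidden global RNG.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, staying < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

# Rebuild a nested list of arrays from a flat numeric vector, restoring all
# attributes (dims, names, class) from the skeleton. utils::relist drops dim
# attributes, so parameter tensors need this instead.
relist_like_ <- function(flesh, skeleton) {
  pos <- 0L
  rec <- function(sk) {
    if (is.list(sk)) {
      out <- lapply(sk, rec)
      attributes(out) <- attributes(sk)
      return(out)
    }
    n <- length(sk)
    v <- flesh[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(v) <- attributes(sk)
    v
  }
  rec(skeleton)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}
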