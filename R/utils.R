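#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: counter-based so that independent
# stages (threshold permutations, ATPM permutations, outer permutations,
# data simulation) never share a stream. Kept below 2^31 - 1.
derive_seed <- function(master_seed, counter) {
  master_seed <- as.double(master_seed)
  counter <- as.double(counter)
  as.integer((master_seed * 1009 + counter * 9973 + 1) %% 2147483647)
}

# Smallest positive double; p-values are clamped here, never 0.
.p_min <- .Machine$double.xmin

clamp_p <- function(p) {
  p[!is.na(p) & p <= 0] <- .p_min
  p
}

stop_netepi <- function(type, msg, ...) {
  stop(structure(
    class = c(paste0("netepi_", type), "netepi_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
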