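# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Reflect an out-of-range 1-based index into [1, n] (mirror boundary, edge
# pixel not duplicated), folding as many times as needed.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j < n, j + 1L, period - j + 1L)
}

# Mirror-pad a matrix or H x W x C array on the bottom/right so that both
# spatial dimensions reach at least `k`.
reflect_pad_to <- function(x, k) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h >= k && w >= k) return(x)
  ri <- reflect_index(seq_len(max(h, k)), h)
  ci <- reflect_index(seq_len(max(w, k)), w)
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

is_binary <- function(x) all(x %in% c(0, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("maunet_input_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("maunet_validation_error", "error")))
}
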