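#' Derive a substream seed from a master seed
#'
#' Each generator and pipeline stage draws from its own seed derived
#' deterministically from the master seed and a stage label, so adding a stage
#' never perturbs the random stream of another.
#'
#' @param seed Master seed (single finite number).
#' @param stream Character label of the substream.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h * 7919) %% 2147483629)
}

invlogit <- stats::plogis

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared-distance pairs within radius between two point sets; returns
# data.table(i, j) with i indexing `a`, j indexing `b`
points_within <- function(ax, ay, bx, by, radius) {
  r2 <- radius^2
  out <- vector("list", length(ax))
  for (i in seq_along(ax)) {
    d2 <- (bx - ax[i])^2 + (by - ay[i])^2
    j <- which(d2 <= r2)
    if (length(j)) out[[i]] <- data.table(i = i, j = j)
  }
  rbindlist(out)
}

stop_config <- function(...) stop(..., call. = FALSE)
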