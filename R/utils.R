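# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random
#' stream afterwards, so seeded helpers never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic per-unit seed derived from a master seed and a unit id.
# Keeps per-tree streams independent while the whole simulation stays
# reproducible from one integer.  Result always fits in a 32-bit integer.
derive_seed <- function(master, id) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.double(master) * 7919 + as.double(id) * 104729 + 13) %%
               .Machine$integer.max)
}

# Pearson correlation that fails loudly on degenerate input.
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

stop_ringtruth <- function(msg, class) {
  stop(structure(class = c(class, "ringtruth_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
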