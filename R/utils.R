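#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. All user-facing errors funnel through these so
# messages stay consistent across modules.

abort_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_arg("`%s` must be a single finite number", name)
  if (positive && x <= 0) abort_arg("`%s` must be > 0", name)
  if (nonneg && x < 0) abort_arg("`%s` must be >= 0", name)
  invisible(as.numeric(x))
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed) ||
      seed != round(seed))
    abort_arg("`seed` must be a single integer")
  invisible(as.integer(seed))
}

check_points3 <- function(points, name = "points") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) abort_arg("`%s` must be an n x 3 matrix", name)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) abort_arg("`%s` must contain finite coordinates", name)
  points
}

#' Derive a per-stage child seed from a master seed
#'
#' Deterministically combines a master seed with a stage name so that each
#' pipeline stage draws from its own reproducible stream. The result is always
#' a valid 32-bit non-negative integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "sample_icns")
derive_seed <- function(master, stage) {
  master <- check_seed(master)
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(master)) * 2654435761 + h) %% 2147483646)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library users' streams are not disturbed.
with_seed <- function(seed, expr) {
  seed <- check_seed(seed)
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

# Squared euclidean cross-distances between rows of a (n x d) and b (m x d).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
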