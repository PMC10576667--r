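# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Shift a date backwards by whole years
#'
#' Moves each date to the same calendar day `k` years earlier. February 29 in
#' a non-leap target year maps to February 28.
#'
#' @param date a `Date` vector.
#' @param k integer number of years to go back (may be negative to go
#'   forward).
#' @return a `Date` vector of the same length.
#' @export
shift_years <- function(date, k) {
  stopifnot(inherits(date, "Date"))
  k <- as.integer(k)
  lt <- as.POSIXlt(date)
  n <- if (length(date) == 0 || length(k) == 0) 0L else
    max(length(date), length(k))
  y <- rep_len(lt$year + 1900L, n) - rep_len(k, n)
  m <- rep_len(lt$mon + 1L, n)
  d <- rep_len(lt$mday, n)
  fix <- m == 2L & d == 29L & !.is_leap(y)
  d[fix] <- 28L
  as.Date(sprintf("%04d-%02d-%02d", y, m, d))
}

# Apportion `total` (a non-negative integer) proportionally to weights `w`
# using the largest-remainder rule, so the result is integer and sums to
# `total` exactly. Ties are resolved by position, which keeps the result
# deterministic.
.integerize <- function(w, total) {
  stopifnot(length(w) >= 1, all(is.finite(w)), all(w >= 0), sum(w) > 0,
            total >= 0)
  x <- w / sum(w) * total
  f <- floor(x)
  r <- as.integer(round(total - sum(f)))
  if (r > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(r)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

# Largest-remainder apportionment applied row-wise to a matrix: each row of
# the result is integer and sums to round(rowSums of the target shares).
.integerize_rows <- function(totals, shares) {
  stopifnot(all(shares >= 0), abs(sum(shares) - 1) < 1e-8)
  t(vapply(totals, function(tt) .integerize(shares, tt),
           integer(length(shares))))
}

# Euclidean distance matrix between planar points; great-circle (via
# geosphere) when mode is "lonlat".
.distance_matrix <- function(x, y, mode = c("planar", "lonlat")) {
  mode <- match.arg(mode)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite")
  }
  if (mode == "planar") {
    as.matrix(stats::dist(cbind(x, y)))
  } else {
    if (!requireNamespace("geosphere", quietly = TRUE)) {
      stop("the 'geosphere' package is required for lon/lat coordinates")
    }
    geosphere::distm(cbind(x, y))
  }
}

# Derive a deterministic stream of child seeds from a master seed without
# disturbing the caller's RNG state more than once.
.spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
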