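#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are bit-reproducible without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  code
}

# derive a reproducible sub-seed < 2^31 from a master seed and a stream index
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

stop_config <- function(...) stop("invalid-config: ", sprintf(...), call. = FALSE)
stop_data   <- function(...) stop(sprintf(...), call. = FALSE)

#' Centered running mean with truncated windows at the edges
#' @param x numeric vector.
#' @param w window length in samples (>= 1).
#' @keywords internal
run_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centered sliding variance (population, divisor = window length), truncated
# windows at the edges
run_var <- function(x, w) {
  w <- max(2L, as.integer(w))
  n <- length(x)
  cs1 <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  m <- hi - lo + 1L
  mu <- (cs1[hi + 1L] - cs1[lo]) / m
  v <- (cs2[hi + 1L] - cs2[lo]) / m - mu^2
  pmax(v, 0)
}

# --- interval (start, end) helpers; intervals are 2-column matrices in s ----

empty_intervals <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start_s", "end_s")))
}

as_intervals <- function(start, end) {
  m <- cbind(start_s = as.numeric(start), end_s = as.numeric(end))
  if (any(m[, 2] < m[, 1])) stop_data("interval end before start")
  m
}

interval_lengths <- function(iv) if (nrow(iv) == 0) numeric(0) else iv[, 2] - iv[, 1]

# total length of the intersection of one interval with a set of intervals
interval_overlap <- function(a_start, a_end, iv) {
  if (nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(a_end, iv[, 2]) - pmax(a_start, iv[, 1])))
}

# Jaccard index between two single intervals
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) return(0)
  inter / uni
}

# complement of intervals within [0, total_s]
interval_complement <- function(iv, total_s) {
  if (nrow(iv) == 0) return(as_intervals(0, total_s))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  starts <- c(0, iv[, 2])
  ends <- c(iv[, 1], total_s)
  keep <- ends > starts
  as_intervals(starts[keep], ends[keep])
}

# runs of TRUE in a logical vector -> index intervals (first, last)
logical_runs <- function(mask) {
  if (!any(mask)) return(matrix(integer(0), ncol = 2))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# --- local extrema ----------------------------------------------------------

#' Indices of strict local maxima and minima, plateaus resolved to their
#' center sample.
#' @keywords internal
local_extrema <- function(x) {
  r <- rle(as.numeric(x))          # collapse equal-value plateaus
  v <- r$values
  m <- length(v)
  if (m < 3) return(list(max_idx = integer(0), min_idx = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- (starts + ends) %/% 2L
  mid <- 2:(m - 1)
  is_max <- c(FALSE, v[mid] > v[mid - 1] & v[mid] > v[mid + 1], FALSE)
  is_min <- c(FALSE, v[mid] < v[mid - 1] & v[mid] < v[mid + 1], FALSE)
  list(max_idx = centers[is_max], min_idx = centers[is_min])
}

# prominence of a peak at index i: height above the higher of the two valley
# floors reached before a taller sample is met on each side
peak_prominence <- function(x, i) {
  n <- length(x)
  lmin <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
  rmin <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
  x[i] - max(lmin, rmin)
}

# polynomial rolling hash of a serialized R object, reported as 8 hex digits;
# used to stamp outputs with the configuration that produced them
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
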