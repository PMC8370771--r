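# Internal helpers shared across modules.

# Run code with a private RNG stream, restoring the caller's state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Otsu threshold on a numeric vector (between-class variance maximisation,
# delegated to EBImage on a 1-row image).
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  EBImage::otsu(EBImage::Image(matrix(x, nrow = 1L)), range = r, levels = levels)
}

# Local maxima of a density curve with topographic prominence.
# Returns a data frame ordered by decreasing prominence.
find_peaks <- function(x, y) {
  n <- length(y)
  if (n < 3) return(data.frame(x = numeric(), y = numeric(), prominence = numeric()))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_peak)) return(data.frame(x = numeric(), y = numeric(), prominence = numeric()))
  prom <- vapply(is_peak, function(i) {
    # walk outwards to the nearest higher ground on each side
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    higher_l <- which(left > y[i])
    higher_r <- which(right > y[i])
    base_l <- if (length(higher_l)) min(y[seq(max(higher_l), i - 1)]) else min(left)
    base_r <- if (length(higher_r)) min(y[seq(i + 1, i + min(higher_r))]) else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
  out <- data.frame(x = x[is_peak], y = y[is_peak], prominence = prom)
  out[order(-out$prominence), , drop = FALSE]
}

# Point-in-polygon via mgcv's in.out (boundary closed automatically).
points_in_polygon <- function(px, py, polygon) {
  bnd <- as.matrix(polygon[, 1:2])
  if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
  out <- rep(FALSE, length(px))
  ok <- is.finite(px) & is.finite(py)
  if (any(ok)) out[ok] <- mgcv::in.out(bnd, cbind(px[ok], py[ok]))
  out
}

# Deterministic per-stage seed fan-out from a single global seed.
#' Derive a reproducible per-stage seed
#'
#' Hashes a stage name into an offset so that each pipeline stage draws from
#' an independent, reproducible stream while the user supplies one seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) + h * 7919) %% 2147483629 + 1)
}

assert_columns <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
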