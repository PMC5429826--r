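#' Per-position cohort median depth profile
#'
#' @param region_mat integer matrix of depths, L_R rows by n_samples columns.
#' @return Numeric vector of length L_R: position-wise median across samples
#'   (midpoint convention for an even cohort, so half-integers can occur).
#' @export
median_profile <- function(region_mat) {
  if (is.null(dim(region_mat)) || ncol(region_mat) == 0L) {
    stop("median_profile requires at least one sample")
  }
  if (ncol(region_mat) == 1L) return(as.numeric(region_mat[, 1L]))
  apply(region_mat, 1L, stats::median)
}

#' LOWESS smoothing with a proportional span
#'
#' Locally weighted degree-1 regression at every base position. The span is
#' the proportion of the region's base positions contributing to each locally
#' fitted value, so the effective bandwidth scales with region length: short
#' exons keep small bumps, long exons smooth them away. The window at each
#' position is the \code{max(ceiling(span * L), 4)} nearest positions
#' (distance ties broken toward the lower index), weighted by the tricube
#' kernel; no robustness iterations are applied.
#'
#' @param values numeric vector (the median profile), length >= 2.
#' @param span fraction of positions per local fit (default 0.03).
#' @return Numeric vector of smoothed values, same length as the input.
#' @export
smooth_profile <- function(values, span = 0.03) {
  L <- length(values)
  if (L < 2L) stop("smoothing requires a region of at least 2 bp")
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  k <- min(max(ceiling(span * L), 4L), L)
  out <- numeric(L)
  x <- seq_len(L)
  for (i in x) {
    idx <- nearest_window(i, L, k)
    d <- abs(idx - i)
    dmax <- max(d)
    w <- if (dmax == 0) rep(1, length(idx)) else (1 - (d / dmax)^3)^3
    out[i] <- wls_fit(idx, values[idx], w, i)
  }
  out
}

# k nearest positions to i in 1..L, ties toward the lower index
nearest_window <- function(i, L, k) {
  lo <- i
  hi <- i
  while (hi - lo + 1L < k) {
    left_d <- if (lo > 1L) i - (lo - 1L) else Inf
    right_d <- if (hi < L) (hi + 1L) - i else Inf
    if (left_d <= right_d) lo <- lo - 1L else hi <- hi + 1L
  }
  lo:hi
}

# weighted degree-1 least squares, evaluated at x0
wls_fit <- function(x, y, w, x0) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= .Machine$double.eps * sum(w * x^2)) return(yb)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  yb + slope * (x0 - xb)
}

#' Detect peaks and troughs on a smoothed profile by hill climbing
#'
#' Scans all base positions for local optima: a position whose neighbors on
#' both sides are lower is a peak, higher a trough. Plateaus (maximal runs of
#' equal values) collapse to a single candidate at the floor of their center
#' and classify by the values flanking the run. The region endpoints
#' themselves are eligible as troughs only, never as peaks, so a strictly
#' monotone edge is not scored as unevenness; an endpoint-touching plateau
#' still counts as a peak when its collapsed center is an interior position
#' (a coverage shelf that then collapses is real unevenness). Peaks and
#' troughs alternate, with exactly one trough between consecutive peaks.
#'
#' @param values numeric vector of smoothed values.
#' @return List with integer vectors \code{peaks} and \code{troughs} (1-based
#'   positions); a flat profile yields both empty.
#' @export
detect_extrema <- function(values) {
  L <- length(values)
  if (L < 3L) return(list(peaks = integer(), troughs = integer()))
  # group near-equal neighbors into plateau runs: locally fitted values on an
  # exactly flat stretch carry ~1e-14 arithmetic jitter that must not split a
  # plateau into spurious micro-extrema
  eps <- 1e-8 * max(1, max(abs(values)))
  run_id <- cumsum(c(TRUE, abs(diff(values)) > eps))
  r <- list(lengths = as.integer(tabulate(run_id)),
            values = values[!duplicated(run_id)])
  n <- length(r$values)
  if (n == 1L) return(list(peaks = integer(), troughs = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  centers <- as.integer(floor((starts + ends) / 2))
  peaks <- integer()
  troughs <- integer()
  for (j in seq_len(n)) {
    left <- if (j > 1L) r$values[j - 1L] else NA_real_
    right <- if (j < n) r$values[j + 1L] else NA_real_
    v <- r$values[j]
    lower <- c(if (j > 1L) left < v else TRUE,
               if (j < n) right < v else TRUE)
    higher <- c(if (j > 1L) left > v else TRUE,
                if (j < n) right > v else TRUE)
    if (all(higher)) {
      troughs <- c(troughs, centers[j])
    } else if (all(lower) && centers[j] > 1L && centers[j] < L) {
      # endpoint positions themselves are never peaks
      peaks <- c(peaks, centers[j])
    }
  }
  list(peaks = peaks, troughs = troughs)
}

#' Peak geometry on a smoothed profile
#'
#' For every detected peak: H is the smoothed coverage at the apex; the left
#' and right flanks are the nearest trough on each side, falling back to the
#' region endpoint when no trough intervenes; B is the mean of the two flank
#' values, floored at \code{b_floor} so that H/B stays finite when troughs
#' reach zero coverage; W is the distance in bp between the flanks.
#'
#' @param values smoothed profile.
#' @param extrema output of \code{\link{detect_extrema}}.
#' @param b_floor minimum peak base in reads (default 0.5, half the smallest
#'   countable depth).
#' @return \code{data.frame}: apex_pos, H, B, W, left_trough_pos,
#'   right_trough_pos — one row per peak.
#' @export
peak_geometry <- function(values, extrema, b_floor = 0.5) {
  L <- length(values)
  peaks <- extrema$peaks
  troughs <- sort(unique(c(extrema$troughs)))
  if (length(peaks) == 0L) {
    return(data.frame(apex_pos = integer(), H = numeric(), B = numeric(),
                      W = numeric(), left_trough_pos = integer(),
                      right_trough_pos = integer()))
  }
  rows <- lapply(peaks, function(p) {
    lt <- troughs[troughs < p]
    rt <- troughs[troughs > p]
    left <- if (length(lt)) max(lt) else 1L
    right <- if (length(rt)) min(rt) else L
    B <- max(mean(values[c(left, right)]), b_floor)
    data.frame(apex_pos = p, H = values[p], B = B, W = right - left,
               left_trough_pos = left, right_trough_pos = right)
  })
  do.call(rbind, rows)
}

#' Unevenness score from peak geometry
#'
#' U_E sums, over detected peaks, the relative peak height H/B divided by the
#' relative peak width W/L_R. A region with uniformly distributed coverage
#' has no peaks and scores exactly 1; uneven regions score above 1. Because
#' both H and B are absolute coverage levels, scaling every sample's depth by
#' a common factor (a library-size change) leaves the score unchanged.
#'
#' @param peaks \code{data.frame} from \code{\link{peak_geometry}}.
#' @param L region length L_R in bp.
#' @return List with \code{ue} (>= 1) and \code{n_peaks}.
#' @export
ue_score <- function(peaks, L) {
  stopifnot(L >= 1)
  if (nrow(peaks) == 0L) return(list(ue = 1, n_peaks = 0L))
  if (any(peaks$B <= 0)) stop("peak base must be positive after flooring")
  ue <- sum((peaks$H / peaks$B) / (peaks$W / L))
  list(ue = max(ue, 1), n_peaks = nrow(peaks))
}

#' Unevenness score for one region of a cohort
#'
#' Full pipeline: per-position cohort median, LOWESS smoothing, hill-climbing
#' extremum detection, peak geometry, U_E scoring.
#'
#' @param region_mat integer depth matrix, L_R rows by n_samples columns.
#' @param span LOWESS span (default 0.03).
#' @param b_floor peak-base floor in reads (default 0.5).
#' @return List: \code{ue}, \code{n_peaks}, \code{peaks} (geometry table),
#'   \code{median} and \code{smoothed} profiles.
#' @export
ue_region <- function(region_mat, span = 0.03, b_floor = 0.5) {
  med <- median_profile(region_mat)
  sm <- smooth_profile(med, span)
  ex <- detect_extrema(sm)
  pg <- peak_geometry(sm, ex, b_floor)
  sc <- ue_score(pg, length(sm))
  list(ue = sc$ue, n_peaks = sc$n_peaks, peaks = pg, median = med,
       smoothed = sm, extrema = ex)
}

#' Unevenness scores for every region of a cohort
#'
#' Regions shorter than \code{min_length} bp are skipped with a warning
#' (the smoothed curve is undefined there); they remain scoreable by CCS.
#'
#' @param matrix a \code{depth_matrix} (normally QC-filtered).
#' @param span LOWESS span (default 0.03).
#' @param b_floor peak-base floor in reads (default 0.5).
#' @param min_length minimum region length for U_E (default 4 bp).
#' @return \code{data.frame}: region_id, gene, length, n_peaks, ue.
#' @export
ue_for_matrix <- function(matrix, span = 0.03, b_floor = 0.5,
                          min_length = 4L) {
  stopifnot(inherits(matrix, "depth_matrix"))
  cat <- matrix$catalog
  keep <- cat$length >= min_length
  if (any(!keep)) {
    warning(sum(!keep), " region(s) shorter than ", min_length,
            " bp skipped for U_E")
  }
  rows <- lapply(which(keep), function(j) {
    res <- ue_region(matrix$depths[[j]], span, b_floor)
    data.frame(region_id = cat$region_id[j], gene = cat$gene[j],
               length = cat$length[j], n_peaks = res$n_peaks, ue = res$ue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(), gene = character(),
                      length = integer(), n_peaks = integer(),
                      ue = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Smoothed cohort median profiles for every region
#'
#' @param matrix a \code{depth_matrix}.
#' @param span LOWESS span (default 0.03).
#' @param min_length minimum region length (default 4 bp); shorter regions
#'   are omitted.
#' @return Named list over region ids of smoothed median profiles.
#' @export
smoothed_medians <- function(matrix, span = 0.03, min_length = 4L) {
  stopifnot(inherits(matrix, "depth_matrix"))
  keep <- matrix$catalog$length >= min_length
  out <- lapply(matrix$depths[keep],
                function(m) smooth_profile(median_profile(m), span))
  out
}
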