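#' Block-matching displacement fields (particle image velocimetry)
#'
#' For each analysed frame pair (t, t + lag) the stack is tiled into
#' interrogation blocks; each block of the earlier frame is matched against
#' a search window of the later frame by zero-normalised cross-correlation
#' (computed via FFT with integral-image local statistics), the integer
#' displacement is the correlation argmax, and it is refined to sub-pixel
#' precision by three-point parabolic interpolation along each axis.
#' Blocks whose correlation peak falls below \code{min_peak} are marked
#' invalid (NA) and excluded from averages downstream: blocks without
#' texture produce noise vectors otherwise.
#'
#' The block grid is inset from the frame edge by the search radius so every
#' search window lies inside the frame.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param lag time lag in s (an integer multiple of the frame interval);
#'   0.1 s at 50 Hz is the conventional mobility-map lag.
#' @param block_size interrogation block side, px (>= 8).
#' @param search_radius maximum displacement searched, px
#'   (< \code{block_size}).
#' @param overlap block overlap fraction (0 = disjoint, 0.5 = half-step).
#' @param max_pairs cap on analysed frame pairs, evenly spaced (default 20).
#' @param min_peak validity threshold on the correlation peak.
#' @return an object of class \code{"piv_fields"}: a list of per-pair
#'   data.frames (\code{block_x}, \code{block_y} block centres in px,
#'   \code{u_px}, \code{v_px}, \code{peak}, \code{valid}) plus grid and
#'   calibration metadata.
#' @export
displacement_field <- function(stack, lag, block_size = 32L,
                               search_radius = 8L, overlap = 0.5,
                               max_pairs = 20L, min_peak = 0.3) {
  .assert(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  .assert(.is_count(block_size) && block_size >= 8L,
          "'block_size' must be an integer >= 8 px")
  .assert(.is_count(search_radius), "'search_radius' must be a positive integer")
  if (search_radius >= block_size)
    stop("'search_radius' must be smaller than 'block_size'", call. = FALSE)
  .assert(overlap >= 0 && overlap < 1, "'overlap' must be in [0, 1)")
  d <- dim(stack$frames)
  nf <- d[1]
  k <- .lags_to_frames(lag, stack$frame_interval, nf)
  .assert(length(k) == 1L, "'lag' must be a single valid lag")

  bs <- as.integer(block_size); r <- as.integer(search_radius)
  step <- max(1L, as.integer(round(bs * (1 - overlap))))
  # top-left block corners, inset by r so the search window fits
  y0 <- seq(r + 1L, d[2] - bs - r + 1L, by = step)
  x0 <- seq(r + 1L, d[3] - bs - r + 1L, by = step)
  .assert(length(y0) >= 1L && length(x0) >= 1L,
          "frame too small for this block_size/search_radius")
  grid <- expand.grid(y0 = y0, x0 = x0)

  starts <- seq_len(nf - k)
  if (length(starts) > max_pairs)
    starts <- unique(round(seq(1, nf - k, length.out = max_pairs)))

  # FFT size for linear correlation of a bs block with a (bs+2r) window
  P <- 2^ceiling(log2(bs + 2L * r))
  fields <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    t0 <- starts[s]
    a_full <- stack$frames[t0, , ]
    b_full <- stack$frames[t0 + k, , ]
    res <- matrix(NA_real_, nrow(grid), 3L)
    for (g in seq_len(nrow(grid))) {
      iy <- grid$y0[g]; ix <- grid$x0[g]
      a <- a_full[iy:(iy + bs - 1L), ix:(ix + bs - 1L)]
      w <- b_full[(iy - r):(iy + bs + r - 1L), (ix - r):(ix + bs + r - 1L)]
      m <- .zncc_match(a, w, r, P)
      res[g, ] <- c(m$u, m$v, m$peak)
    }
    valid <- is.finite(res[, 3]) & res[, 3] >= min_peak
    fields[[s]] <- data.frame(
      block_x = grid$x0 + (bs - 1) / 2, block_y = grid$y0 + (bs - 1) / 2,
      u_px = ifelse(valid, res[, 1], NA_real_),
      v_px = ifelse(valid, res[, 2], NA_real_),
      peak = res[, 3], valid = valid)
  }
  structure(list(fields = fields, lag = k * stack$frame_interval,
                 block_size = bs, search_radius = r, overlap = overlap,
                 pixel_size = stack$pixel_size,
                 elapsed_time = stack$elapsed_time,
                 min_peak = min_peak),
            class = "piv_fields")
}

# Zero-normalised cross-correlation of template a (bs x bs) against window w
# ((bs+2r) x (bs+2r)); returns sub-pixel displacement (u = x, v = y) and peak.
.zncc_match <- function(a, w, r, P) {
  bs <- nrow(a)
  n <- bs * bs
  a0 <- a - mean(a)
  sa <- sqrt(sum(a0 * a0))
  if (sa < 1e-12) return(list(u = NA_real_, v = NA_real_, peak = NA_real_))
  # raw linear cross-correlation via zero-padded FFT
  pa <- matrix(0, P, P); pa[1:bs, 1:bs] <- a0
  pw <- matrix(0, P, P); pw[1:nrow(w), 1:ncol(w)] <- w
  cc <- Re(fft(fft(pw) * Conj(fft(pa)), inverse = TRUE)) / P^2
  # shift (dy, dx) in 0..2r corresponds to cc[dy+1, dx+1]
  cc <- cc[1:(2 * r + 1), 1:(2 * r + 1)]
  # local window sums/sumsq via integral images for per-shift normalisation
  S1 <- .box_sums(w, bs)[1:(2 * r + 1), 1:(2 * r + 1)]
  S2 <- .box_sums(w * w, bs)[1:(2 * r + 1), 1:(2 * r + 1)]
  sb <- sqrt(pmax(S2 - S1 * S1 / n, 0))
  zncc <- ifelse(sb > 1e-12, cc / (sa * sb), -Inf)
  ij <- which(zncc == max(zncc), arr.ind = TRUE)[1, ]
  peak <- zncc[ij[1], ij[2]]
  sub <- function(cvec, i) {
    if (i <= 1L || i >= length(cvec)) return(0)
    den <- cvec[i - 1L] - 2 * cvec[i] + cvec[i + 1L]
    if (abs(den) < 1e-12) return(0)
    off <- 0.5 * (cvec[i - 1L] - cvec[i + 1L]) / den
    max(min(off, 0.5), -0.5)
  }
  dv <- sub(zncc[, ij[2]], ij[1]) + (ij[1] - 1L) - r
  du <- sub(zncc[ij[1], ], ij[2]) + (ij[2] - 1L) - r
  list(u = du, v = dv, peak = peak)
}

# Sliding bs x bs box sums of m (valid positions), via an integral image.
.box_sums <- function(m, bs) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)      # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  ny <- nrow(m) - bs + 1L; nx <- ncol(m) - bs + 1L
  ii[(bs + 1L):(bs + ny), (bs + 1L):(bs + nx)] -
    ii[1:ny, (bs + 1L):(bs + nx)] -
    ii[(bs + 1L):(bs + ny), 1:nx] + ii[1:ny, 1:nx]
}

#' @export
print.piv_fields <- function(x, ...) {
  nb <- nrow(x$fields[[1]])
  nv <- mean(vapply(x$fields, function(f) mean(f$valid), 0))
  cat(sprintf("<piv_fields> %d pair(s) x %d blocks (%d px, lag %.3g s); %.0f%% valid, t = %s min\n",
              length(x$fields), nb, x$block_size, x$lag, 100 * nv,
              format(x$elapsed_time)))
  invisible(x)
}

#' Mean displacement magnitude of a PIV field set
#'
#' The operational "optical intensity" of a PIV mobility map: the mean
#' displacement magnitude (in um) over all valid blocks and analysed frame
#' pairs of one movie.
#'
#' @param pf a \code{"piv_fields"}.
#' @return mean displacement magnitude, um.
#' @export
mean_displacement <- function(pf) {
  .assert(inherits(pf, "piv_fields"), "'pf' must be piv_fields")
  mags <- unlist(lapply(pf$fields, function(f)
    sqrt(f$u_px[f$valid]^2 + f$v_px[f$valid]^2)))
  if (!length(mags)) return(NA_real_)
  mean(mags) * pf$pixel_size
}

#' Normalized mobility curve across a gelation run
#'
#' Collapses per-movie PIV field sets (all analysed at the same lag,
#' ordered by elapsed time) into the normalized mobility curve: per movie
#' the mean displacement magnitude over all valid blocks and frame pairs,
#' divided by the first movie's value (so the curve starts at 1 by
#' construction).  A sudden decay of this curve marks dynamical arrest; its
#' knee is located with \code{\link{detect_changepoint}}.
#'
#' @param field_sets list of \code{"piv_fields"}, one per movie.
#' @param elapsed_times optional elapsed-time labels, min (default: taken
#'   from the field sets).
#' @return an object of class \code{"mobility_curve"}:
#'   \code{elapsed_times}, \code{values} (normalized), \code{raw_um},
#'   \code{lag}.
#' @export
mobility_curve <- function(field_sets, elapsed_times = NULL) {
  .assert(is.list(field_sets) && length(field_sets) >= 1L &&
            all(vapply(field_sets, inherits, TRUE, "piv_fields")),
          "'field_sets' must be a non-empty list of piv_fields")
  lags <- vapply(field_sets, function(f) f$lag, 0)
  .assert(diff(range(lags)) < 1e-9, "all movies must share one PIV lag")
  et <- elapsed_times %||%
    vapply(field_sets, function(f) as.numeric(f$elapsed_time), 0)
  o <- order(et)
  raw <- vapply(field_sets, mean_displacement, 0)[o]
  .assert(is.finite(raw[1]) && raw[1] > 0,
          "first movie has no valid displacement estimate to normalize by")
  structure(list(elapsed_times = et[o], values = raw / raw[1],
                 raw_um = raw, lag = lags[1]),
            class = "mobility_curve")
}

#' @export
print.mobility_curve <- function(x, ...) {
  cat(sprintf("<mobility_curve> lag %.3g s; %d movies:\n", x$lag,
              length(x$values)))
  print(setNames(round(x$values, 4), paste0(x$elapsed_times, "min")))
  invisible(x)
}

#' @export
as.data.frame.mobility_curve <- function(x, ...) {
  data.frame(elapsed_min = x$elapsed_times, normalized_mobility = x$values,
             mean_displacement_um = x$raw_um, lag_s = x$lag)
}
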