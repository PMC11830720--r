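#' Dyadic box-size ladder for a raster
#'
#' Box edge lengths from `min(h, w) / 4` halving down to `min_size` pixels.
#'
#' @param h,w Raster dimensions.
#' @param min_size Smallest box edge (pixels).
#' @return Integer vector of box sizes, descending.
#' @export
default_box_sizes <- function(h, w, min_size = 4L) {
  top <- min(h, w) %/% 4L
  s <- min_size
  sizes <- integer(0)
  while (s <= top) { sizes <- c(sizes, s); s <- s * 2L }
  if (length(sizes) == 0L) stop("raster too small for box counting",
                                call. = FALSE)
  rev(sizes)
}

#' Per-box mass tables for box counting
#'
#' Sums raster values inside every cell of an origin-anchored grid of edge
#' `size`, for each size.  Works for binary rasters (masses = foreground
#' pixel counts) and for nonnegative count rasters (multifractal measures).
#'
#' @param raster Numeric matrix with nonnegative values.
#' @param sizes Box edge lengths (pixels), each at most `min(dim(raster))`.
#' @return Named list (one element per size) of numeric vectors holding every
#'   box mass, zeros included.
#' @export
box_counts <- function(raster, sizes = default_box_sizes(nrow(raster),
                                                         ncol(raster))) {
  stopifnot(is.matrix(raster))
  if (sum(raster) == 0) stop("no foreground", call. = FALSE)
  if (any(sizes > min(dim(raster))))
    stop("box size exceeds raster extent", call. = FALSE)
  out <- list()
  for (e in sizes) {
    nr <- ceiling(nrow(raster) / e) * e
    nc <- ceiling(ncol(raster) / e) * e
    m <- matrix(0, nr, nc)
    m[seq_len(nrow(raster)), seq_len(ncol(raster))] <- raster
    # fold rows then columns into e-blocks
    rowsum_idx <- rep(seq_len(nr / e), each = e)
    m2 <- rowsum(m, rowsum_idx)
    m3 <- t(rowsum(t(m2), rep(seq_len(nc / e), each = e)))
    out[[as.character(e)]] <- as.numeric(m3)
  }
  out
}

# mass exponent tau(q): slope of log sum(p^q) vs log(eps), empty boxes
# excluded; returns slope + R^2
tau_q <- function(occupancies, q) {
  sizes <- as.numeric(names(occupancies))
  ys <- vapply(seq_along(sizes), function(i) {
    cnt <- occupancies[[i]]
    p <- cnt[cnt > 0] / sum(cnt)
    log(sum(p^q))
  }, numeric(1))
  fit <- lm(ys ~ log(sizes))
  r2 <- summary(fit)$r.squared
  # q = 1 (and any exact-scaling measure) makes ys constant: perfect fit
  if (!is.finite(r2)) r2 <- if (var(ys) < 1e-12) 1 else 0
  list(slope = unname(coef(fit)[2]), r2 = r2)
}

# Shannon box entropy regression for the q -> 1 limit
entropy_slope <- function(occupancies) {
  sizes <- as.numeric(names(occupancies))
  ys <- vapply(seq_along(sizes), function(i) {
    cnt <- occupancies[[i]]
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log(p))
  }, numeric(1))
  fit <- lm(ys ~ log(1 / sizes))
  list(slope = unname(coef(fit)[2]), r2 = summary(fit)$r.squared)
}

#' Generalized box-counting dimension
#'
#' Least-squares slope estimates of the generalized (Renyi) dimensions:
#' `q = 0` capacity (log N(eps) vs log(1/eps)), `q = 1` entropy (Shannon box
#' entropy vs log(1/eps), the q -> 1 limit), `q = 2` correlation
#' (log sum p^2 vs log eps).
#'
#' @param occupancies Result of [box_counts()] over at least 4 sizes.
#' @param q Order: 0, 1 or 2.
#' @return List with `dimension`, regression `r2`, and `n_sizes`.
#' @export
generalized_dimension <- function(occupancies, q) {
  usable <- vapply(occupancies, function(cnt) any(cnt > 0), logical(1))
  if (sum(usable) < 4L)
    stop("need at least 4 box sizes with nonzero occupancy", call. = FALSE)
  occupancies <- occupancies[usable]
  res <- if (q == 0) {
    sizes <- as.numeric(names(occupancies))
    ys <- log(vapply(occupancies, function(cnt) sum(cnt > 0), numeric(1)))
    fit <- lm(ys ~ log(1 / sizes))
    list(slope = unname(coef(fit)[2]), r2 = summary(fit)$r.squared)
  } else if (q == 1) {
    entropy_slope(occupancies)
  } else if (q == 2) {
    tau_q(occupancies, 2)  # tau(2)/(2-1)
  } else stop("q must be 0, 1 or 2", call. = FALSE)
  list(dimension = res$slope, r2 = res$r2, n_sizes = length(occupancies))
}

#' Multifractal singularity length
#'
#' Width `alpha_max - alpha_min` of the singularity spectrum obtained by
#' Legendre transform of the mass exponents `tau(q)` estimated over a q-grid:
#' `alpha(q) = d tau / d q` by central differences.  Orders whose `tau(q)`
#' regression falls below the R^2 floor are dropped with a warning; if fewer
#' than two orders survive the result is missing.
#'
#' @param raster Numeric matrix (binary or counts).
#' @param q_range Orders q of the mass exponents.
#' @param sizes Box sizes; defaults to the dyadic ladder.
#' @param r2_floor Minimum regression R^2 for a q to be kept.
#' @return List with `sl`, and the `q`, `tau`, `alpha` tables used.
#' @export
singularity_length <- function(raster, q_range = seq(-3, 3, by = 0.5),
                               sizes = default_box_sizes(nrow(raster),
                                                         ncol(raster)),
                               r2_floor = 0.9) {
  occ <- box_counts(raster, sizes)
  tq <- lapply(q_range, function(q) tau_q(occ, q))
  tau <- vapply(tq, `[[`, numeric(1), "slope")
  r2 <- vapply(tq, `[[`, numeric(1), "r2")
  keep <- r2 >= r2_floor
  if (any(!keep))
    warning(sum(!keep), " q value(s) dropped (tau fit R^2 < ", r2_floor, ")")
  q <- q_range[keep]; tau <- tau[keep]
  if (length(q) < 3L)
    return(list(sl = NA_real_, q = q, tau = tau, alpha = numeric(0)))
  n <- length(q)
  alpha <- c((tau[2] - tau[1]) / (q[2] - q[1]),
             (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)]),
             (tau[n] - tau[n - 1]) / (q[n] - q[n - 1]))
  list(sl = max(alpha) - min(alpha), q = q, tau = tau, alpha = alpha)
}

#' Fractal spectrum of one centerline raster
#'
#' Capacity, entropy and correlation dimensions plus the singularity length,
#' with regression diagnostics.
#'
#' @param raster Binary centerline raster.
#' @param sizes Box sizes (defaults to the dyadic ladder).
#' @param q_range q-grid for the singularity length.
#' @return Object of class `fractal_spectrum`: `d0`, `d1`, `d2`, `sl` and a
#'   `diagnostics` data frame of (size, n_boxes, entropy, sum_p2).
#' @export
fractal_spectrum <- function(raster,
                             sizes = default_box_sizes(nrow(raster),
                                                       ncol(raster)),
                             q_range = seq(-3, 3, by = 0.5)) {
  occ <- box_counts(raster, sizes)
  d0 <- generalized_dimension(occ, 0)
  d1 <- generalized_dimension(occ, 1)
  d2 <- generalized_dimension(occ, 2)
  sl <- singularity_length(raster, q_range, sizes)
  diag <- data.frame(
    size = as.numeric(names(occ)),
    n_boxes = vapply(occ, function(cnt) sum(cnt > 0), numeric(1)),
    entropy = vapply(occ, function(cnt) {
      p <- cnt[cnt > 0] / sum(cnt); -sum(p * log(p))
    }, numeric(1)),
    sum_p2 = vapply(occ, function(cnt) {
      p <- cnt[cnt > 0] / sum(cnt); sum(p^2)
    }, numeric(1)))
  structure(list(d0 = d0$dimension, d1 = d1$dimension, d2 = d2$dimension,
                 sl = sl$sl,
                 r2 = c(d0 = d0$r2, d1 = d1$r2, d2 = d2$r2),
                 diagnostics = diag),
            class = "fractal_spectrum")
}

#' @export
print.fractal_spectrum <- function(x, ...) {
  cat(sprintf("fractal_spectrum: d0 = %.3f  d1 = %.3f  d2 = %.3f  sl = %.3f\n",
              x$d0, x$d1, x$d2, x$sl))
  cat(sprintf("  fit R^2: %.4f / %.4f / %.4f over %d box sizes\n",
              x$r2["d0"], x$r2["d1"], x$r2["d2"], nrow(x$diagnostics)))
  invisible(x)
}

#' Fractal panel for both vessel classes
#'
#' @param artery_centerline,vein_centerline Binary skeleton rasters; an empty
#'   class yields missing values for its four parameters.
#' @param ... Passed to [fractal_spectrum()].
#' @return Named list `d0_a`..`sl_a`, `d0_v`..`sl_v` plus the two spectra.
#' @export
fractal_panel <- function(artery_centerline, vein_centerline, ...) {
  one <- function(raster) {
    if (is.null(raster) || sum(raster != 0) == 0)
      return(list(d0 = NA_real_, d1 = NA_real_, d2 = NA_real_, sl = NA_real_))
    fractal_spectrum(raster, ...)
  }
  a <- one(artery_centerline); v <- one(vein_centerline)
  list(d0_a = a$d0, d1_a = a$d1, d2_a = a$d2, sl_a = a$sl,
       d0_v = v$d0, d1_v = v$d1, d2_v = v$d2, sl_v = v$sl,
       artery = a, vein = v)
}
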