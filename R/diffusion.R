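# Diffusion of the three CGFs and lactate is represented by per-factor
# kernels: square weight stencils whose total mass is conserved across the
# permeability models A/B/C. Concentration fields are the discrete
# convolution of producer occupancy with the kernel, with clipped
# (absorbing) grid edges.

#' Diffusible factor identifiers
#'
#' @return `c("GF1", "GF2", "GF3", "LACTATE")`, in the order used everywhere
#'   (GF production bits 0..2, lactate bit 3 of the genotype code).
#' @export
factor_ids <- function() c("GF1", "GF2", "GF3", "LACTATE")

#' Default kernel configuration
#'
#' Base radii honour the printed range ordering (GF1 shortest, GF3 longest,
#' lactate in between); model scale factors honour B < A < C (Model B has the
#' shortest, Model C the longest diffusion range). Per-factor mass is the
#' total concentration deposited by one producer, conserved across models:
#' higher permeability (a larger radius) lowers the average concentration
#' within the range.
#'
#' @return A list with `base_radius`, `mass` (named per factor), `scale`
#'   (named per model) and `lambda_frac` (decay length as a fraction of the
#'   radius; `Inf` gives a flat kernel).
#' @export
kernel_config <- function() {
  list(
    base_radius = c(GF1 = 2, GF2 = 4, GF3 = 6, LACTATE = 3),
    mass        = c(GF1 = 1, GF2 = 1, GF3 = 1, LACTATE = 1),
    scale       = c(A = 1, B = 0.5, C = 2),
    lambda_frac = 0.5
  )
}

#' Build a diffusion kernel
#'
#' The kernel is a `(2r+1) x (2r+1)` square stencil with
#' `radius = max(1, round(base_radius * scale(model)))`. Weights decay
#' exponentially with the Euclidean offset length `d`:
#' `w(d) proportional to exp(-d / lambda)` with `lambda = lambda_frac * r`
#' (`lambda_frac = Inf` yields a flat kernel), rescaled so that the weights
#' sum exactly to the factor's mass. Mass is therefore identical across
#' Models A, B and C for the same factor.
#'
#' @param factor One of [factor_ids()].
#' @param model `"A"`, `"B"` or `"C"`.
#' @param params Kernel configuration, see [kernel_config()].
#' @return An `acd_kernel`: list with `factor`, `model`, `radius`, `weights`
#'   (square matrix) and `mass`.
#' @export
build_kernel <- function(factor, model = "A", params = kernel_config()) {
  factor <- match.arg(factor, factor_ids())
  model <- match.arg(model, c("A", "B", "C"))
  base_r <- params$base_radius[[factor]]
  mass <- params$mass[[factor]]
  if (!is.numeric(base_r) || base_r <= 0) stop("base radius must be positive", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0) stop("kernel mass must be positive", call. = FALSE)
  r <- max(1L, as.integer(round(base_r * params$scale[[model]])))
  off <- seq(-r, r)
  d <- sqrt(outer(off^2, off^2, `+`))
  lambda <- params$lambda_frac * r
  w <- if (is.infinite(lambda)) matrix(1, 2 * r + 1, 2 * r + 1) else exp(-d / lambda)
  w <- w * (mass / sum(w))
  structure(list(factor = factor, model = model, radius = r, weights = w, mass = mass),
            class = "acd_kernel")
}

#' Build the full kernel set for one model
#'
#' @param model `"A"`, `"B"` or `"C"`.
#' @param params See [kernel_config()].
#' @return Named list of four `acd_kernel`s (one per factor).
#' @export
kernel_set <- function(model = "A", params = kernel_config()) {
  stats::setNames(lapply(factor_ids(), build_kernel, model = model, params = params),
                  factor_ids())
}

#' @export
print.acd_kernel <- function(x, ...) {
  cat("<kernel ", x$factor, " model ", x$model, " radius ", x$radius,
      " mass ", format(x$mass), ">\n", sep = "")
  invisible(x)
}

#' Compute concentration fields from producer occupancy
#'
#' Each factor's field is the discrete convolution of its boolean producer
#' mask with its kernel. Grid edges are clipped: contributions that would
#' fall outside the grid are lost (no wrap-around).
#'
#' @param producer_masks Named list (per factor id) of logical/0-1 matrices,
#'   all of the same dimension.
#' @param kernels Named list of `acd_kernel`s, as from [kernel_set()].
#' @return An `acd_fieldset`: named list of numeric concentration matrices.
#' @export
compute_fields <- function(producer_masks, kernels) {
  ids <- names(kernels)
  dims <- unique(lapply(producer_masks, dim))
  if (length(dims) != 1L)
    stop("producer masks must share one dimension", call. = FALSE)
  fields <- lapply(ids, function(id) {
    convolve_mask(producer_masks[[id]], kernels[[id]]$weights)
  })
  structure(stats::setNames(fields, ids), class = "acd_fieldset")
}

# clipped-edge convolution by shift-and-accumulate over kernel offsets
convolve_mask <- function(mask, weights) {
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  r <- (nrow(weights) - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(weights))) {
    dr <- i - r - 1L
    r_lo <- max(1L, 1L + dr); r_hi <- min(nr, nr + dr)  # destination rows
    if (r_lo > r_hi) next
    sr <- r_lo:r_hi
    for (j in seq_len(ncol(weights))) {
      w <- weights[i, j]
      if (w == 0) next
      dc <- j - r - 1L
      c_lo <- max(1L, 1L + dc); c_hi <- min(nc, nc + dc)
      if (c_lo > c_hi) next
      sc <- c_lo:c_hi
      out[sr, sc] <- out[sr, sc] + w * mask[sr - dr, sc - dc]
    }
  }
  out
}

# producer masks for all four factors from a code lattice (NA = vacant)
producer_masks <- function(lattice) {
  codes <- lattice
  codes[is.na(codes)] <- 0L
  masks <- lapply(0:3, function(b) {
    m <- bitwAnd(codes, 2L^b) > 0L
    dim(m) <- dim(lattice)
    m
  })
  stats::setNames(masks, factor_ids())
}
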