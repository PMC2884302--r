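#' Primary-photon dose kernel parameters
#'
#' The simulator's dose model is deliberately simple: a primary-photon term
#' only. The dose per unit aperture weight at a point is
#' `phi0 * exp(-mu * depth) * T`, where `depth` is the radiological path
#' length from the body surface to the point along the (parallel) beam axis,
#' and `T` is the aperture transmission at the point's BEV projection,
#' i.e. the binary open mask convolved with an isotropic Gaussian penumbra.
#'
#' @param phi0 dose rate at zero depth under a fully open field, Gy per unit
#'   aperture weight (default 2)
#' @param mu effective linear attenuation coefficient in 1/cm (default 0.05,
#'   about right for a 6 MV photon beam in water)
#' @param sigma Gaussian penumbra width in mm (default 3)
#' @param step ray-marching step in mm (default 1)
#' @return list of kernel parameters
#' @export
dose_kernel <- function(phi0 = 2, mu = 0.05, sigma = 3, step = 1) {
  stopifnot(phi0 > 0, mu >= 0, sigma >= 0, step > 0)
  list(phi0 = phi0, mu = mu, sigma = sigma, step = step)
}

#' Compute the dose-influence matrix
#'
#' Entry (m, n) is the dose in Gy delivered to sample point m per unit
#' weight of aperture n, under the primary-photon kernel of [dose_kernel()].
#' Depth is obtained by marching from each point toward the source and
#' accumulating path length inside the body mask; transmission is the
#' penumbra-blurred open mask interpolated bilinearly at the point's BEV
#' coordinates. The computation is deterministic.
#'
#' @param phantom a [build_phantom()] result
#' @param apertures list from [design_apertures()]
#' @param points a [place_sample_points()] result
#' @param kernel parameters from [dose_kernel()]
#' @return object of class `dose_influence_matrix` (see
#'   [dose_influence_matrix()])
#' @export
compute_dose_matrix <- function(phantom, apertures, points,
                                kernel = dose_kernel()) {
  body <- phantom$masks[[phantom$body]]
  P <- points$coords
  m <- nrow(P)
  idx0 <- coords_to_index(P, phantom)
  inside <- !is.na(idx0) & body[pmax(idx0, 1L)]
  if (any(!inside)) {
    stop(sum(!inside), " sample point(s) lie outside the body mask", call. = FALSE)
  }

  gantry <- vapply(apertures, function(a) a$beam$gantry_angle, numeric(1))
  values <- matrix(0, m, length(apertures))
  for (g in unique(gantry)) {
    cols <- which(gantry == g)
    basis <- bev_basis(g)
    depth_mm <- ray_depth(P, basis$u, body, phantom, kernel$step)
    atten <- kernel$phi0 * exp(-kernel$mu * depth_mm / 10)
    uv <- project_uv(P, basis)
    for (ci in cols) {
      a <- apertures[[ci]]
      blurred <- gauss_blur(a$open * 1, kernel$sigma / a$spacing)
      tr <- bilinear(blurred, (uv[, 1] - a$u0) / a$spacing + 1,
        (uv[, 2] - a$v0) / a$spacing + 1)
      values[, ci] <- atten * tr
    }
  }
  dose_influence_matrix(
    values,
    structure = points$structure,
    point_id = points$point_id,
    aperture_id = vapply(apertures, `[[`, character(1), "id"),
    aperture_meta = data.frame(
      id = vapply(apertures, `[[`, character(1), "id"),
      gantry_angle = gantry,
      kind = vapply(apertures, `[[`, character(1), "kind"),
      beam_index = vapply(apertures, `[[`, integer(1), "beam_index"),
      slot = vapply(apertures, `[[`, integer(1), "slot")
    )
  )
}

#' Construct a dose-influence matrix object
#'
#' Container for the m x n matrix of dose per unit aperture weight at each
#' labelled sample point. Entries must be finite and non-negative and every
#' column must irradiate at least one point.
#'
#' @param values numeric m x n matrix, Gy per unit weight
#' @param structure character length m, structure label per row
#' @param point_id optional row identifiers
#' @param aperture_id optional column identifiers
#' @param aperture_meta optional data frame of per-aperture metadata
#' @return object of class `dose_influence_matrix`
#' @export
dose_influence_matrix <- function(values, structure,
                                  point_id = NULL, aperture_id = NULL,
                                  aperture_meta = NULL) {
  values <- as.matrix(values)
  if (length(structure) != nrow(values)) {
    stop("`structure` must label every row of the matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("dose matrix entries must be finite", call. = FALSE)
  if (any(values < 0)) stop("dose matrix entries must be non-negative", call. = FALSE)
  if (any(colSums(values > 0) == 0)) {
    stop("every aperture must deliver positive dose to at least one point",
      call. = FALSE
    )
  }
  point_id <- point_id %||% sprintf("P%05d", seq_len(nrow(values)))
  aperture_id <- aperture_id %||% sprintf("A%03d", seq_len(ncol(values)))
  dimnames(values) <- list(point_id, aperture_id)
  structure(
    list(
      values = values, structure = as.character(structure),
      point_id = point_id, aperture_id = aperture_id,
      aperture_meta = aperture_meta
    ),
    class = "dose_influence_matrix"
  )
}

#' @export
print.dose_influence_matrix <- function(x, ...) {
  cat(
    "Dose-influence matrix:", nrow(x$values), "sample points x",
    ncol(x$values), "apertures\n"
  )
  print(table(x$structure))
  invisible(x)
}

#' @export
dim.dose_influence_matrix <- function(x) dim(x$values)

# physical coords (mm, isocenter origin) -> linear voxel index, NA if outside
coords_to_index <- function(P, phantom) {
  g <- phantom$grid
  sp <- phantom$spacing
  i <- round(P[, 1] / sp[1] + (g[1] + 1) / 2)
  j <- round(P[, 2] / sp[2] + (g[2] + 1) / 2)
  k <- round(P[, 3] / sp[3] + (g[3] + 1) / 2)
  ok <- i >= 1 & i <= g[1] & j >= 1 & j <= g[2] & k >= 1 & k <= g[3]
  out <- (k - 1) * g[1] * g[2] + (j - 1) * g[1] + i
  out[!ok] <- NA_integer_
  as.integer(out)
}

# march from each point toward the source, accumulating path length (mm)
# inside the body mask
ray_depth <- function(P, u, body, phantom, step) {
  tmax <- sqrt(sum((phantom$grid * phantom$spacing)^2))
  ts <- seq(step / 2, tmax, by = step)
  depth <- numeric(nrow(P))
  for (t in ts) {
    pos <- P + matrix(u * t, nrow(P), 3, byrow = TRUE)
    idx <- coords_to_index(pos, phantom)
    hit <- !is.na(idx)
    if (any(hit)) {
      hit[hit] <- body[idx[hit]]
      depth <- depth + step * hit
    }
  }
  depth
}

# separable Gaussian blur of a matrix, zero-padded edges, kernel sum 1
gauss_blur <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  R <- ceiling(4 * sigma_cells)
  k <- stats::dnorm(-R:R, sd = sigma_cells)
  k <- k / sum(k)
  conv1 <- function(mat, along_rows) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (d in -R:R) {
      w <- k[d + R + 1]
      out <- out + w * if (along_rows) num_shift(mat, d, 0L) else num_shift(mat, 0L, d)
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

num_shift <- function(m, di, dj) {
  out <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  oki <- si >= 1L & si <= nrow(m)
  okj <- sj >= 1L & sj <= ncol(m)
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

# bilinear interpolation of matrix `m` at fractional indices (fi, fj);
# zero outside the grid
bilinear <- function(m, fi, fj) {
  nr <- nrow(m)
  nc <- ncol(m)
  i0 <- floor(fi)
  j0 <- floor(fj)
  wi <- fi - i0
  wj <- fj - j0
  val <- numeric(length(fi))
  at <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- numeric(length(i))
    v[ok] <- m[cbind(i[ok], j[ok])]
    v
  }
  val <- (1 - wi) * (1 - wj) * at(i0, j0) +
    wi * (1 - wj) * at(i0 + 1, j0) +
    (1 - wi) * wj * at(i0, j0 + 1) +
    wi * wj * at(i0 + 1, j0 + 1)
  val
}
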