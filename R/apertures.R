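#' Design anatomy-based apertures for each beam
#'
#' For every beam the first aperture conforms to the beam's-eye-view (BEV)
#' projection of the target dilated by a margin. Each organ at risk whose
#' projection falls inside the target's BEV then contributes one further
#' aperture: the conformal opening with that OAR's projection blocked.
#' If a beam still has fewer than `min_per_beam` apertures, the conformal
#' opening is split into half-field sub-apertures (left, right, inferior,
#' superior) until the minimum is reached; apertures beyond `max_per_beam`
#' are dropped. Apertures within a beam are ordered (conformal, blocked,
#' splits), so taking the first k per beam always yields nested sets.
#'
#' Parallel-beam geometry is used throughout: the BEV plane passes through
#' the isocenter perpendicular to the beam axis, with in-plane axes
#' (u = cross-line, v = z).
#'
#' @param phantom a [build_phantom()] result
#' @param beams list of beams from [preset_beams()]
#' @param margin dilation margin around the target projection, mm
#' @param min_per_beam,max_per_beam bounds on apertures per beam
#' @param bev_spacing BEV raster spacing in mm (default: smallest voxel side)
#' @param pad extra BEV raster border beyond the dilated opening, mm; keep a
#'   few penumbra widths so blurred transmission tails stay on the raster
#' @return list of `aperture` objects (`id`, `beam`, `beam_index`, `slot`,
#'   `kind`, `open` logical matrix, `u0`, `v0`, `spacing`)
#' @export
design_apertures <- function(phantom, beams, margin = 5,
                             min_per_beam = 3, max_per_beam = 5,
                             bev_spacing = min(phantom$spacing), pad = 15) {
  stopifnot(min_per_beam >= 1, min_per_beam <= max_per_beam)
  tname <- names(phantom$roles)[phantom$roles == "target"][1]
  onames <- names(phantom$roles)[phantom$roles == "oar"]
  tgt_xyz <- mask_voxel_coords(phantom, tname)
  oar_xyz <- lapply(onames, function(nm) mask_voxel_coords(phantom, nm))
  names(oar_xyz) <- onames

  out <- list()
  for (bi in seq_along(beams)) {
    beam <- beams[[bi]]
    basis <- bev_basis(beam$gantry_angle)
    tuv <- project_uv(tgt_xyz, basis)
    if (nrow(tuv) == 0) {
      stop("beam at gantry ", beam$gantry_angle,
        " degrees has an empty target projection",
        call. = FALSE
      )
    }
    ext <- margin + pad
    grid <- bev_grid(
      range(tuv[, 1]) + c(-ext, ext), range(tuv[, 2]) + c(-ext, ext),
      bev_spacing
    )
    tproj <- mask_close(rasterize_uv(tuv, grid))
    conformal <- mask_dilate(tproj, round(margin / bev_spacing))
    if (!any(conformal)) {
      stop("beam at gantry ", beam$gantry_angle,
        " degrees has an empty target projection",
        call. = FALSE
      )
    }
    aps <- list(list(kind = "target-conformal", open = conformal))
    for (on in onames) {
      oproj <- mask_close(rasterize_uv(project_uv(oar_xyz[[on]], basis), grid))
      if (!any(oproj & tproj)) next # OAR not within the target BEV
      blocked <- conformal & !oproj
      if (!any(blocked)) next
      aps[[length(aps) + 1L]] <- list(kind = "oar-blocked", open = blocked, blocks = on)
    }
    if (length(aps) < min_per_beam) {
      for (sp in split_masks(conformal)) {
        if (length(aps) >= min_per_beam) break
        if (any(sp)) aps[[length(aps) + 1L]] <- list(kind = "target-conformal", open = sp)
      }
      if (length(aps) < min_per_beam) {
        stop("cannot reach min_per_beam = ", min_per_beam, " apertures for gantry ",
          beam$gantry_angle, " degrees",
          call. = FALSE
        )
      }
    }
    if (length(aps) > max_per_beam) aps <- aps[seq_len(max_per_beam)]
    for (si in seq_along(aps)) {
      a <- aps[[si]]
      out[[length(out) + 1L]] <- structure(
        list(
          id = sprintf("G%03d_A%d", round(beam$gantry_angle) %% 360, si),
          beam = beam, beam_index = bi, slot = si, kind = a$kind,
          blocks = a$blocks %||% NA_character_,
          open = a$open, u0 = grid$u0, v0 = grid$v0, spacing = grid$spacing
        ),
        class = "aperture"
      )
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Orthonormal BEV basis for a gantry angle (degrees, clockwise from +y in the
# axial plane): `u` points from isocenter toward the source; e1/e2 span the
# BEV plane (e2 is the patient z axis).
bev_basis <- function(gantry_angle) {
  g <- gantry_angle * pi / 180
  list(
    u = c(sin(g), cos(g), 0),
    e1 = c(cos(g), -sin(g), 0),
    e2 = c(0, 0, 1)
  )
}

mask_voxel_coords <- function(phantom, name) {
  co <- grid_coordinates(phantom$grid, phantom$spacing)
  m <- phantom$masks[[name]]
  cbind(co$X[m], co$Y[m], co$Z[m])
}

project_uv <- function(xyz, basis) {
  cbind(xyz %*% basis$e1, xyz %*% basis$e2)
}

bev_grid <- function(urange, vrange, spacing) {
  nu <- max(2L, ceiling(diff(urange) / spacing) + 1L)
  nv <- max(2L, ceiling(diff(vrange) / spacing) + 1L)
  list(u0 = urange[1], v0 = vrange[1], spacing = spacing, nu = nu, nv = nv)
}

rasterize_uv <- function(uv, grid) {
  m <- matrix(FALSE, grid$nu, grid$nv)
  if (nrow(uv) == 0) return(m)
  i <- round((uv[, 1] - grid$u0) / grid$spacing) + 1L
  j <- round((uv[, 2] - grid$v0) / grid$spacing) + 1L
  ok <- i >= 1L & i <= grid$nu & j >= 1L & j <= grid$nv
  m[cbind(i[ok], j[ok])] <- TRUE
  m
}

mask_shift <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di
  sj <- seq_len(ncol(m)) - dj
  oki <- si >= 1L & si <= nrow(m)
  okj <- sj >= 1L & sj <= ncol(m)
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

mask_dilate <- function(m, r) {
  r <- as.integer(r)
  if (r <= 0L) return(m)
  out <- m
  for (di in -r:r) {
    for (dj in -r:r) {
      if ((di != 0L || dj != 0L) && di^2 + dj^2 <= r^2) {
        out <- out | mask_shift(m, di, dj)
      }
    }
  }
  out
}

mask_erode <- function(m, r) !mask_dilate(!m, r)

# one-cell closing fills pin-holes left by projecting discrete voxel centres
mask_close <- function(m) mask_erode(mask_dilate(m, 1L), 1L)

# sub-field splits of an open mask, in a fixed order. Deliberately NOT a
# partition: complementary halves would sum exactly to the conformal field
# and make dose-matrix columns linearly dependent (singular at lambda = 0).
split_masks <- function(open) {
  idx <- which(open, arr.ind = TRUE)
  mu <- stats::median(idx[, 1])
  mv <- stats::median(idx[, 2])
  q1 <- stats::quantile(idx[, 1], 1 / 3, names = FALSE)
  rowm <- row(open)
  colm <- col(open)
  list(
    open & (rowm <= mu), # left half
    open & (colm <= mv), # inferior half
    open & (rowm <= mu) & (colm <= mv), # inferior-left quadrant
    open & (rowm <= q1) # left third
  )
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf(
    "Aperture %s (gantry %g deg, %s): %d open cells @ %g mm\n",
    x$id, x$beam$gantry_angle, x$kind, sum(x$open), x$spacing
  ))
  invisible(x)
}
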