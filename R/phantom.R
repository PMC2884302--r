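#' Build a synthetic phantom from a parametric specification
#'
#' Rasterises a set of parametric structures (body, target, organs at risk)
#' onto a regular voxel grid. The phantom is the geometric substrate from
#' which beam's-eye-view apertures, sample points and the dose-influence
#' matrix are derived, standing in for patient CT contours.
#'
#' Coordinates are voxel-centred physical positions in mm, axes ordered
#' (x, y, z), origin at the grid centre (the isocenter). Every non-body
#' structure must lie inside the body mask; the target and each OAR must be
#' non-empty and pairwise disjoint.
#'
#' @param spec A phantom specification: a list with elements `grid` (integer
#'   triple, voxels per axis), `spacing` (mm per axis, scalar or triple) and
#'   `structures`, a named list where each entry has a `role`
#'   (`"body"`, `"target"` or `"oar"`) and a `shape` list (see
#'   [shape_mask()] for the supported parametric shapes). May also be a path
#'   to a JSON file in the same layout (see [read_phantom_spec()]).
#' @return An object of class `phantom`: list with `grid`, `spacing`,
#'   `masks` (named logical arrays), `roles` (named character),
#'   `volumes_cc` (named numeric, voxel count times voxel volume) and the
#'   original `spec`.
#' @examples
#' ph <- build_phantom(phantom_preset_spec("case_a", spacing = 4))
#' ph$volumes_cc
#' @export
build_phantom <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) spec <- read_phantom_spec(spec)
  grid <- as.integer(spec$grid)
  spacing <- rep_len(as.numeric(spec$spacing), 3L)
  if (length(grid) != 3L || any(grid < 1L)) {
    stop("invalid phantom spec: `grid` must be three positive integers", call. = FALSE)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("invalid phantom spec: `spacing` must be positive", call. = FALSE)
  }
  structs <- spec$structures
  if (is.null(names(structs)) || any(!nzchar(names(structs)))) {
    stop("invalid phantom spec: structures must be named", call. = FALSE)
  }
  roles <- vapply(structs, function(s) as.character(s$role), character(1))
  if (sum(roles == "body") != 1L) {
    stop("invalid phantom spec: exactly one structure must have role 'body'", call. = FALSE)
  }
  if (!any(roles == "target")) {
    stop("invalid phantom spec: at least one structure must have role 'target'", call. = FALSE)
  }
  bad <- setdiff(unique(roles), c("body", "target", "oar"))
  if (length(bad)) {
    stop("invalid phantom spec: unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  co <- grid_coordinates(grid, spacing)
  masks <- lapply(structs, function(s) shape_mask(s$shape, co))
  names(masks) <- names(structs)
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) {
      stop("invalid phantom spec: structure '", nm, "' rasterises to an empty mask",
        call. = FALSE
      )
    }
  }
  body_name <- names(masks)[roles == "body"]
  body <- masks[[body_name]]
  for (nm in setdiff(names(masks), body_name)) {
    if (any(masks[[nm]] & !body)) {
      stop("invalid phantom spec: structure '", nm, "' extends outside the body",
        call. = FALSE
      )
    }
  }
  tnames <- names(masks)[roles == "target"]
  onames <- names(masks)[roles == "oar"]
  for (tn in tnames) {
    for (on in onames) {
      if (any(masks[[tn]] & masks[[on]])) {
        stop("invalid phantom spec: target '", tn, "' overlaps OAR '", on, "'",
          call. = FALSE
        )
      }
    }
  }
  vox_cc <- prod(spacing) / 1000 # mm^3 -> cc
  volumes <- vapply(masks, function(m) sum(m) * vox_cc, numeric(1))
  structure(
    list(
      grid = grid, spacing = spacing, masks = masks, roles = roles,
      volumes_cc = volumes, body = body_name, spec = spec
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(
    "Phantom:", paste(x$grid, collapse = " x "), "voxels,",
    paste(format(x$spacing, trim = TRUE), collapse = " x "), "mm\n"
  )
  for (nm in names(x$masks)) {
    cat(sprintf(
      "  %-12s %-6s %8.1f cc\n", nm, paste0("[", x$roles[[nm]], "]"),
      x$volumes_cc[[nm]]
    ))
  }
  invisible(x)
}

# Voxel-centred coordinate arrays for a grid; origin (isocenter) at grid centre.
grid_coordinates <- function(grid, spacing) {
  ax <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp
  x <- ax(grid[1], spacing[1])
  y <- ax(grid[2], spacing[2])
  z <- ax(grid[3], spacing[3])
  list(
    X = array(rep(x, times = grid[2] * grid[3]), dim = grid),
    Y = array(rep(rep(y, each = grid[1]), times = grid[3]), dim = grid),
    Z = array(rep(z, each = grid[1] * grid[2]), dim = grid),
    x = x, y = y, z = z, grid = grid, spacing = spacing
  )
}

#' Rasterise a parametric shape onto the phantom grid
#'
#' Supported shape types (all lengths in mm, all centres in isocenter-origin
#' coordinates):
#' \describe{
#'   \item{`sphere`}{`center` (x, y, z), `radius`.}
#'   \item{`cylinder`}{circular cylinder with axis along z: `center` (x, y),
#'     `radius`, optional `z_range` (min, max; defaults to the full grid).}
#'   \item{`ellipse_cylinder`}{elliptical cylinder along z: `center` (x, y),
#'     `semi_axes` (a, b), optional `z_range`.}
#'   \item{`box`}{axis-aligned: `lower` (x, y, z), `upper` (x, y, z).}
#'   \item{`horseshoe`}{annular sector along z (a concave, C-shaped target):
#'     `center` (x, y), `r_inner`, `r_outer`, `gap_direction_deg` (direction
#'     of the opening, degrees counter-clockwise from +x), `gap_width_deg`
#'     (angular width of the opening), optional `z_range`.}
#' }
#'
#' @param shape list with `type` and the parameters above
#' @param coords coordinate arrays from the phantom grid (internal layout)
#' @return logical array over the grid
#' @keywords internal
shape_mask <- function(shape, coords) {
  type <- shape$type
  X <- coords$X
  Y <- coords$Y
  Z <- coords$Z
  zr <- shape$z_range
  zmask <- if (is.null(zr)) TRUE else (Z >= zr[1] & Z <= zr[2])
  m <- switch(type,
    sphere = {
      c3 <- as.numeric(shape$center)
      (X - c3[1])^2 + (Y - c3[2])^2 + (Z - c3[3])^2 <= shape$radius^2
    },
    cylinder = {
      c2 <- as.numeric(shape$center)
      ((X - c2[1])^2 + (Y - c2[2])^2 <= shape$radius^2) & zmask
    },
    ellipse_cylinder = {
      c2 <- as.numeric(shape$center)
      ab <- as.numeric(shape$semi_axes)
      (((X - c2[1]) / ab[1])^2 + ((Y - c2[2]) / ab[2])^2 <= 1) & zmask
    },
    box = {
      lo <- as.numeric(shape$lower)
      hi <- as.numeric(shape$upper)
      (X >= lo[1] & X <= hi[1]) & (Y >= lo[2] & Y <= hi[2]) & (Z >= lo[3] & Z <= hi[3])
    },
    horseshoe = {
      c2 <- as.numeric(shape$center)
      dx <- X - c2[1]
      dy <- Y - c2[2]
      r2 <- dx^2 + dy^2
      ang <- atan2(dy, dx) * 180 / pi
      gap <- abs(((ang - shape$gap_direction_deg + 180) %% 360) - 180) <
        shape$gap_width_deg / 2
      (r2 >= shape$r_inner^2) & (r2 <= shape$r_outer^2) & !gap & zmask
    },
    stop("invalid phantom spec: unknown shape type '", type, "'", call. = FALSE)
  )
  m & array(TRUE, dim = coords$grid) # recycle scalar zmask cleanly
}

#' Packaged phantom preset specifications
#'
#' Two self-contained test geometries at reduced scale:
#' \describe{
#'   \item{`case_a`}{a concave head-and-neck-like case: a horseshoe target
#'     wrapped around a central cord-like cylindrical OAR, with two lateral
#'     parotid-like spherical OARs inside an elliptical body.}
#'   \item{`case_b`}{a brain-like case: a spherical temporal target with an
#'     adjacent brainstem-like cylinder and a small chiasm-like sphere.}
#' }
#'
#' @param name `"case_a"` or `"case_b"`
#' @param spacing voxel spacing in mm (isotropic); the default 2 mm gives a
#'   few hundred sample points per phantom at a density of 1 point/cc
#' @return a phantom specification list for [build_phantom()]
#' @export
phantom_preset_spec <- function(name = c("case_a", "case_b"), spacing = 2) {
  name <- match.arg(name)
  sp <- as.numeric(spacing)
  if (name == "case_a") {
    grid <- as.integer(round(c(120, 120, 80) / sp))
    list(
      name = "case_a", grid = grid, spacing = c(sp, sp, sp),
      structures = list(
        body = list(
          role = "body",
          shape = list(type = "ellipse_cylinder", center = c(0, 0), semi_axes = c(55, 45))
        ),
        ptv = list(
          role = "target",
          shape = list(
            type = "horseshoe", center = c(0, 0), r_inner = 9, r_outer = 28,
            gap_direction_deg = 270, gap_width_deg = 90, z_range = c(-20, 20)
          )
        ),
        cord = list(
          role = "oar",
          shape = list(type = "cylinder", center = c(0, 0), radius = 5)
        ),
        parotid_l = list(
          role = "oar",
          shape = list(type = "sphere", center = c(-38, 0, 0), radius = 10)
        ),
        parotid_r = list(
          role = "oar",
          shape = list(type = "sphere", center = c(38, 0, 0), radius = 10)
        )
      )
    )
  } else {
    grid <- as.integer(round(c(110, 110, 80) / sp))
    list(
      name = "case_b", grid = grid, spacing = c(sp, sp, sp),
      structures = list(
        body = list(
          role = "body",
          shape = list(type = "ellipse_cylinder", center = c(0, 0), semi_axes = c(50, 45))
        ),
        ptv = list(
          role = "target",
          shape = list(type = "sphere", center = c(16, 4, 0), radius = 20)
        ),
        brainstem = list(
          role = "oar",
          shape = list(type = "cylinder", center = c(-12, -10), radius = 6, z_range = c(-30, 30))
        ),
        chiasm = list(
          role = "oar",
          shape = list(type = "sphere", center = c(-10, 10, 4), radius = 4)
        )
      )
    )
  }
}

#' Standard seven-field coplanar beam arrangement
#'
#' @param gantry_angles degrees, clockwise from +y in the axial plane;
#'   defaults to the seven-field arrangement 0, 45, 100, 150, 210, 260, 315
#' @param sad source-axis distance in mm (informational; the simulator uses
#'   parallel-beam geometry)
#' @return list of `beam` objects (`gantry_angle`, `couch_angle`, `sad`,
#'   `isocenter`)
#' @export
preset_beams <- function(gantry_angles = c(0, 45, 100, 150, 210, 260, 315),
                         sad = 1000) {
  if (anyDuplicated(gantry_angles)) {
    stop("gantry angles within a plan must be distinct", call. = FALSE)
  }
  lapply(gantry_angles, function(g) {
    structure(
      list(
        gantry_angle = g %% 360, couch_angle = 0, sad = sad,
        isocenter = c(0, 0, 0)
      ),
      class = "beam"
    )
  })
}
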