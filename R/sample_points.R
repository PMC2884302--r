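#' Place dose-evaluation sample points inside each structure
#'
#' Draws `round(density * volume_cc)` points (at least one) uniformly at
#' random inside every structure mask except the body outline itself, which
#' receives points over the normal tissue outside target and OARs. Placement
#' is seeded and reproducible: the global RNG state is saved and restored.
#'
#' @param phantom a [build_phantom()] result
#' @param density sampling density in points per cc
#' @param seed integer seed recorded with the output
#' @param include_body place points in unclassified normal tissue under the
#'   body's own label (default TRUE; the body then takes part in the
#'   objective like any other dose-limited structure)
#' @return object of class `sample_point_set`: `coords` (m x 3 mm),
#'   `structure` (length m), `point_id`, `density`, `seed`
#' @export
place_sample_points <- function(phantom, density = 1, seed = 1L,
                                include_body = TRUE) {
  if (!is.numeric(density) || density <= 0) {
    stop("sampling density must be positive", call. = FALSE)
  }
  vox_cc <- prod(phantom$spacing) / 1000
  body_name <- phantom$body
  masks <- phantom$masks
  if (include_body) {
    tissue <- masks[[body_name]]
    for (nm in setdiff(names(masks), body_name)) tissue <- tissue & !masks[[nm]]
    masks[[body_name]] <- tissue
  } else {
    masks[[body_name]] <- NULL
  }
  co <- grid_coordinates(phantom$grid, phantom$spacing)
  coords <- NULL
  labels <- character(0)
  with_seed(seed, {
    for (nm in names(masks)) {
      m <- masks[[nm]]
      vol <- sum(m) * vox_cc
      n <- max(1L, as.integer(round(density * vol)))
      cells <- which(m)
      pick <- cells[sample.int(length(cells), n, replace = TRUE)]
      jitter <- matrix(stats::runif(3L * n, -0.5, 0.5), n, 3L)
      p <- cbind(co$X[pick], co$Y[pick], co$Z[pick]) +
        jitter * rep(phantom$spacing, each = n)
      coords <- rbind(coords, p)
      labels <- c(labels, rep(nm, n))
    }
  })
  structure(
    list(
      coords = coords, structure = labels,
      point_id = sprintf("P%05d", seq_along(labels)),
      density = density, seed = as.integer(seed)
    ),
    class = "sample_point_set"
  )
}

#' @export
print.sample_point_set <- function(x, ...) {
  cat(
    "Sample points:", length(x$structure), "points at", x$density,
    "per cc (seed", paste0(x$seed, ")\n")
  )
  print(table(x$structure))
  invisible(x)
}

#' @export
as.data.frame.sample_point_set <- function(x, ...) {
  data.frame(
    point_id = x$point_id, structure = x$structure,
    x = x$coords[, 1], y = x$coords[, 2], z = x$coords[, 3]
  )
}

# evaluate code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  )
  set.seed(as.integer(seed))
  force(code)
}
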