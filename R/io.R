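#' Read and write phantom specifications as JSON
#'
#' @param path JSON file path
#' @return the specification list (see [build_phantom()])
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("phantom spec not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname read_phantom_spec
#' @param spec a phantom specification list
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write and read a dose-influence matrix as wide CSV
#'
#' Layout: two leading label columns (`point_id`, `structure`) followed by
#' one column per aperture. Doses are serialised with 15 significant
#' digits, so a write/read round trip preserves values to at least 12
#' significant digits.
#'
#' @param D0 a [dose_influence_matrix()]
#' @param path CSV file path
#' @export
write_dose_matrix <- function(D0, path) {
  df <- data.frame(
    point_id = D0$point_id, structure = D0$structure,
    check.names = FALSE
  )
  for (j in seq_along(D0$aperture_id)) {
    df[[D0$aperture_id[j]]] <- sprintf("%.15g", D0$values[, j])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_matrix
#' @return `read_dose_matrix()` returns a [dose_influence_matrix()]
#' @export
read_dose_matrix <- function(path) {
  if (!file.exists(path)) stop("dose matrix not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("point_id", "structure")
  if (!all(need %in% names(df))) {
    stop("dose matrix CSV must start with point_id and structure columns",
      call. = FALSE
    )
  }
  ap <- setdiff(names(df), need)
  values <- as.matrix(df[, ap, drop = FALSE])
  storage.mode(values) <- "double"
  dose_influence_matrix(values,
    structure = df$structure,
    point_id = df$point_id, aperture_id = ap
  )
}

objective_to_df <- function(objective) {
  data.frame(
    structure = names(objective$goals),
    role = unname(objective$role),
    d_min = unname(objective$d_min),
    d_max = unname(objective$d_max),
    prescription = unname(objective$prescription),
    penalty = unname(objective$penalty)
  )
}

df_to_objective <- function(df) {
  goals <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$role == "target") {
      structure_goal(r$structure, "target",
        d_min = ifelse(is.na(r$d_min), 0, r$d_min),
        d_max = ifelse(is.na(r$d_max), Inf, r$d_max),
        prescription = r$prescription, penalty = r$penalty
      )
    } else {
      structure_goal(r$structure, "oar",
        d_max = ifelse(is.na(r$d_max), Inf, r$d_max), penalty = r$penalty
      )
    }
  })
  dose_objective(goals)
}

#' Read and write dose objectives (constraints and penalties)
#'
#' CSV layout: one row per structure with columns `structure`, `role`,
#' `d_min`, `d_max`, `prescription`, `penalty`. A `.json` extension reads
#' or writes the same table as JSON.
#'
#' @param path file path (`.csv` or `.json`)
#' @return `read_objective()` returns a [dose_objective()]
#' @export
read_objective <- function(path) {
  if (!file.exists(path)) stop("constraints file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  df_to_objective(df)
}

#' @rdname read_objective
#' @param objective a [dose_objective()]
#' @export
write_objective <- function(objective, path) {
  df <- objective_to_df(objective)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export aperture masks as portable CSV plus a JSON index
#'
#' Each aperture's open mask is written as a 0/1 CSV (rows = u cells,
#' columns = v cells); `index.json` records id, gantry angle, kind, raster
#' origin and spacing for every aperture.
#'
#' @param apertures list from [design_apertures()]
#' @param dir output directory (created if needed)
#' @export
write_apertures <- function(apertures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- lapply(apertures, function(a) {
    file <- paste0(a$id, ".csv")
    utils::write.table(a$open * 1L, file.path(dir, file),
      sep = ",",
      row.names = FALSE, col.names = FALSE
    )
    list(
      id = a$id, file = file, gantry_angle = a$beam$gantry_angle,
      kind = a$kind, blocks = a$blocks, u0 = a$u0, v0 = a$v0,
      spacing = a$spacing
    )
  })
  jsonlite::write_json(index, file.path(dir, "index.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Write an optimization result as JSON plus a per-point dose CSV
#'
#' @param result an [optimize_weights()] result
#' @param json_path output JSON path (weights, costs, options, diagnostics)
#' @param doses_path optional CSV path (point_id, structure, dose_gy)
#' @param point_id optional point identifiers for the dose CSV
#' @param seed seed recorded in the JSON for provenance
#' @export
write_result <- function(result, json_path, doses_path = NULL,
                         point_id = NULL, seed = NA_integer_) {
  doc <- list(
    seed = seed,
    weights = as.list(result$weights),
    cost_initial = result$cost_initial,
    cost_final = result$cost_final,
    percent_reduction = percent_reduction(result$cost_initial, result$cost_final),
    smoothing_lambda = result$smoothing_lambda,
    active_apertures = result$active_apertures,
    conditioning = result$conditioning,
    options = list(nonneg = result$nonneg, nnls = result$nnls),
    elapsed_sec = result$elapsed
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(doses_path)) {
    df <- data.frame(
      point_id = point_id %||% sprintf("P%05d", seq_along(result$doses)),
      structure = result$labels,
      dose_gy = sprintf("%.15g", result$doses)
    )
    utils::write.csv(df, doses_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}

# run manifest: inputs with md5 hashes, seed, options, package version
write_manifest <- function(dir, command, inputs = character(0), seed = NA,
                           options = list()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  doc <- list(
    command = command, seed = seed, options = options, inputs = hashes,
    package_version = as.character(utils::packageVersion("abiplan")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(doc, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(doc)
}
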