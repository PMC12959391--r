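# Plain-text interchange: CSV streams (time_s + ch00..chNN or DoF columns),
# JSON suit designs and configs, and OBJ meshes. Round trips are lossless to
# full double precision.

assert_time_col <- function(df, path) {
  if (!"time_s" %in% names(df)) {
    stop("malformed stream file ", path, ": missing column 'time_s'",
         call. = FALSE)
  }
}

#' Read / write streams as CSV
#'
#' Sensor streams use the mandatory header `time_s, ch00, ch01, ...` (pF);
#' angle streams use `time_s` plus DoF-named columns (degrees).
#'
#' @param stream Tibble to write.
#' @param path File path.
#' @return The read tibble, classed as `sensor_stream` / `angle_stream`.
#' @export
write_sensor_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_stream
#' @export
read_sensor_stream <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  assert_time_col(df, path)
  chans <- setdiff(names(df), "time_s")
  bad <- chans[!grepl("^ch[0-9]+$", chans)]
  if (length(bad) > 0) {
    stop("malformed sensor stream ", path, ": unexpected column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("sensor_stream", class(df))
  df
}

#' @rdname write_sensor_stream
#' @export
write_angle_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_stream
#' @export
read_angle_stream <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  assert_time_col(df, path)
  class(df) <- c("angle_stream", class(df))
  df
}

#' Write / read a suit design as JSON
#'
#' Serializes each sensor's channel, joint, score, rest length and path
#' geometry (vertex compositions, rest positions, skinning weights), enough
#' to re-simulate without re-running the optimizer.
#'
#' @param design A `suit_design`.
#' @param path File path.
#' @export
write_suit_design <- function(design, path) {
  sensors <- purrr::map(seq_len(nrow(design$sensors)), function(i) {
    s <- design$sensors[i, ]
    list(channel = s$channel, joint = s$joint, score = s$score,
         rest_length = s$rest_length, direction = s$direction,
         center_vertex = s$center_vertex,
         node_a = s$node_a, node_b = s$node_b,
         path_nodes = s$path_nodes[[1]],
         path_comp = s$path_comp[[1]],
         path_pos = s$path_pos[[1]],
         path_w = s$path_w[[1]])
  })
  jsonlite::write_json(
    list(status = design$status, overlap_threshold = design$overlap_threshold,
         sensor_length = design$sensor_length, sensors = sensors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_suit_design
#' @export
read_suit_design <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  sensors <- purrr::map_dfr(seq_len(nrow(j$sensors)), function(i) {
    s <- j$sensors[i, ]
    tibble::tibble(channel = as.integer(s$channel), joint = s$joint,
                   score = s$score, rest_length = s$rest_length,
                   direction = s$direction,
                   center_vertex = as.integer(s$center_vertex),
                   node_a = as.integer(s$node_a),
                   node_b = as.integer(s$node_b),
                   path_nodes = list(as.integer(s$path_nodes[[1]])),
                   path_comp = list(s$path_comp[[1]]),
                   path_pos = list(s$path_pos[[1]]),
                   path_w = list(s$path_w[[1]]))
  })
  structure(list(sensors = sensors, status = j$status,
                 overlap_threshold = j$overlap_threshold,
                 sensor_length = j$sensor_length),
            class = "suit_design")
}

#' Write / read a rest mesh as Wavefront OBJ
#'
#' Vertices and triangular faces only (no normals/UVs); skinning weights are
#' not part of the format.
#'
#' @param mesh A `skinned_mesh` (or list with `vertices`/`faces`).
#' @param path File path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0 || length(fl) == 0) {
    stop("malformed OBJ ", path, ": needs 'v' and 'f' records", call. = FALSE)
  }
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(p) as.integer(sub("/.*", "", p[1:3]))))
  structure(list(vertices = verts, faces = faces, weights = NULL),
            class = "skinned_mesh")
}

#' Write / read a body configuration as JSON
#'
#' @param config A [body_config()].
#' @param path File path.
#' @export
write_body_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_body_config
#' @export
read_body_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(body_config, j[setdiff(names(j), character(0))])
}
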