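s2_pos_cols <- function() sprintf("pos_%03d", 1:400)

#' Write damage vectors in the tool-by-position matrix layout
#'
#' One row per tool: `tool_id`, optional metadata columns, then 400 binary
#' position columns `pos_001` ... `pos_400` (dorsal-left 1-100, dorsal-right
#' 101-200, ventral-left 201-300, ventral-right 301-400).
#'
#' @param vectors binary matrix (tools x 400) with tool ids as row names, or
#'   a list of vectors carrying `tool_id` attributes.
#' @param path output CSV path.
#' @param metadata optional data frame of per-tool columns (e.g.
#'   `assemblage`, `raw_material`), one row per tool.
#' @export
write_s2_matrix <- function(vectors, path, metadata = NULL) {
  if (is.list(vectors)) {
    ids <- vapply(vectors, function(v) {
      id <- attr(v, "tool_id"); if (is.null(id)) NA_character_ else id
    }, "")
    vectors <- do.call(rbind, lapply(vectors, as.integer))
    rownames(vectors) <- ids
  }
  if (ncol(vectors) != 400L) stop("vectors must have 400 columns")
  ids <- rownames(vectors)
  if (is.null(ids)) ids <- paste0("tool_", seq_len(nrow(vectors)))
  df <- data.frame(tool_id = ids, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(vectors))
    df <- cbind(df, metadata)
  }
  mat <- as.data.frame(vectors)
  names(mat) <- s2_pos_cols()
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' Read a tool-by-position damage matrix
#'
#' @param path CSV with a header containing the 400 `pos_001`..`pos_400`
#'   columns; every position cell must be 0 or 1.
#' @return list with `vectors` (binary matrix, tool ids as row names) and
#'   `metadata` (the non-position columns).
#' @export
read_s2_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  pos_cols <- s2_pos_cols()
  if (!all(pos_cols %in% names(df))) {
    stop(sprintf("'%s' lacks the 400 position columns pos_001..pos_400", path))
  }
  mat <- as.matrix(df[, pos_cols])
  bad <- which(!(mat %in% c(0L, 1L)) | is.na(mat))
  if (length(bad)) {
    r <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    c <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("non-binary value at row %d, column %s", r, pos_cols[c]))
  }
  storage.mode(mat) <- "integer"
  ids <- if ("tool_id" %in% names(df)) as.character(df$tool_id) else
    paste0("tool_", seq_len(nrow(df)))
  rownames(mat) <- ids
  meta <- df[, setdiff(names(df), pos_cols), drop = FALSE]
  message(sprintf("read %d damage vectors from %s", nrow(mat), path))
  list(vectors = mat, metadata = meta)
}

#' Write assemblage distributions in the distribution-table layout
#'
#' Rows are standardized positions; for each distribution three columns are
#' written: `<label>.count`, `<label>.proportion` and `<label>.smoothed`.
#'
#' @param dists list of `edd_distribution` (same position count).
#' @param path output CSV path.
#' @export
write_s3_distributions <- function(dists, path) {
  if (inherits(dists, "edd_distribution")) dists <- list(dists)
  np <- length(dists[[1L]]$counts)
  out <- data.frame(position = seq_len(np))
  for (d in dists) {
    stopifnot(length(d$counts) == np)
    out[[paste0(d$label, ".count")]] <- d$counts
    out[[paste0(d$label, ".proportion")]] <- d$proportions
    out[[paste0(d$label, ".smoothed")]] <- d$smoothed
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a distribution table
#'
#' @param path CSV produced by [write_s3_distributions()] (or following its
#'   layout).
#' @param alpha span recorded on the rebuilt distributions.
#' @return named list of `edd_distribution` objects. Stored smoothed series
#'   are kept as written.
#' @export
read_s3_distributions <- function(path, alpha = 0.15) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cnt_cols <- grep("\\.count$", names(df), value = TRUE)
  if (!length(cnt_cols)) stop(sprintf("'%s' has no '<label>.count' columns", path))
  labels <- sub("\\.count$", "", cnt_cols)
  out <- list()
  for (lab in labels) {
    d <- distribution_from_counts(df[[paste0(lab, ".count")]], lab,
                                  alpha = alpha, smooth = FALSE)
    sm <- df[[paste0(lab, ".smoothed")]]
    if (!is.null(sm)) d$smoothed <- as.numeric(sm)
    else if (d$total_damage > 0) d$smoothed <- smooth_blocks(d$proportions, alpha)
    out[[lab]] <- d
  }
  out
}

geojson_polygon <- function(ring, properties) {
  ring <- rbind(ring, ring[1L, ])
  list(type = "Feature",
       properties = properties,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                         c(ring[i, 1L], ring[i, 2L])))))
}

#' Write a tool record as a GeoJSON FeatureCollection
#'
#' One outline polygon and one platform point feature per face (property
#' `kind` = "outline"/"platform", `face` = "dorsal"/"ventral"), plus one
#' polygon per damage scar (`kind` = "damage", with `damage_class`).
#'
#' @param tool an `edd_tool`.
#' @param path output path.
#' @export
write_tool_geojson <- function(tool, path) {
  stopifnot(inherits(tool, "edd_tool"))
  features <- list()
  for (face_name in c("dorsal", "ventral")) {
    f <- tool$faces[[face_name]]
    features[[length(features) + 1L]] <-
      geojson_polygon(f$outline, list(kind = "outline", face = face_name))
    features[[length(features) + 1L]] <-
      list(type = "Feature",
           properties = list(kind = "platform", face = face_name),
           geometry = list(type = "Point",
                           coordinates = as.numeric(f$platform_anchor)))
    for (s in f$scars) {
      features[[length(features) + 1L]] <-
        geojson_polygon(s$ring, list(kind = "damage", face = face_name,
                                     damage_class = s$damage_class))
    }
  }
  obj <- list(type = "FeatureCollection",
              properties = list(tool_id = tool$tool_id,
                                assemblage_label = tool$assemblage_label,
                                raw_material = tool$raw_material),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tool record from GeoJSON
#'
#' @param path GeoJSON FeatureCollection following the schema written by
#'   [write_tool_geojson()].
#' @param mirror_ventral reflect the ventral face's x coordinates at
#'   ingestion (for digitizations where the ventral photograph is not already
#'   in photograph-apparent orientation).
#' @return an `edd_tool`.
#' @export
read_tool_geojson <- function(path, mirror_ventral = FALSE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$features)) stop(sprintf("'%s' is not a FeatureCollection", path))
  props <- obj$properties
  coords_matrix <- function(geom) {
    ring <- geom$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  }
  faces <- list(dorsal = list(scars = list()), ventral = list(scars = list()))
  for (ft in obj$features) {
    p <- ft$properties
    face <- p$face
    if (is.null(face) || !face %in% c("dorsal", "ventral")) next
    kind <- p$kind
    if (identical(kind, "outline")) {
      faces[[face]]$outline <- coords_matrix(ft$geometry)
    } else if (identical(kind, "platform")) {
      faces[[face]]$anchor <- as.numeric(unlist(ft$geometry$coordinates))
    } else if (identical(kind, "damage")) {
      cls <- if (is.null(p$damage_class)) NA_character_ else p$damage_class
      faces[[face]]$scars[[length(faces[[face]]$scars) + 1L]] <-
        list(ring = coords_matrix(ft$geometry), damage_class = cls)
    }
  }
  for (fn in c("dorsal", "ventral")) {
    if (is.null(faces[[fn]]$outline) || is.null(faces[[fn]]$anchor)) {
      stop(sprintf("'%s': face '%s' lacks an outline or platform feature", path, fn))
    }
  }
  if (mirror_ventral) {
    flip <- function(m) { m[, 1L] <- -m[, 1L]; m }
    faces$ventral$outline <- flip(faces$ventral$outline)
    faces$ventral$anchor <- c(-faces$ventral$anchor[1L], faces$ventral$anchor[2L])
    faces$ventral$scars <- lapply(faces$ventral$scars, function(s) {
      s$ring <- flip(s$ring); s
    })
  }
  mk <- function(fn) edd_face(faces[[fn]]$outline, faces[[fn]]$anchor, faces[[fn]]$scars)
  edd_tool(if (is.null(props$tool_id)) basename(path) else props$tool_id,
           dorsal = mk("dorsal"), ventral = mk("ventral"),
           assemblage_label = if (is.null(props$assemblage_label)) NA else props$assemblage_label,
           raw_material = if (is.null(props$raw_material)) NA else props$raw_material)
}
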