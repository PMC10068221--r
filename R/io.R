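# CSV / JSON / GeoJSON readers and writers.  All readers reject malformed
# required fields rather than coercing them; block identifiers are always
# read as character so FIPS leading zeros survive.

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "),
         " (in ", path, ")")
  invisible(df)
}

check_numeric_column <- function(raw, col, path) {
  x <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(x) & !is.na(raw[[col]]) & raw[[col]] != "")
  if (length(bad) || anyNA(x))
    stop("non-numeric ", col, " in row(s) ",
         paste(if (length(bad)) bad else which(is.na(x)),
               collapse = ", "), " of ", path)
  x
}

#' Read a block table from CSV
#'
#' Required columns: `block_id`, `x`, `y`, `population`, `supply`;
#' optional `in_report_region` (default `TRUE`).  `block_id` is read
#' verbatim as text.
#'
#' @param path CSV file path.
#' @return A [blocks()] table.
#' @export
read_blocks <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  require_columns(raw, c("block_id", "x", "y", "population", "supply"),
                  path)
  irr <- if ("in_report_region" %in% names(raw))
    as.logical(raw$in_report_region) else TRUE
  blocks(raw$block_id,
         x = check_numeric_column(raw, "x", path),
         y = check_numeric_column(raw, "y", path),
         population = check_numeric_column(raw, "population", path),
         supply = check_numeric_column(raw, "supply", path),
         in_report_region = irr)
}

#' Write a block table to CSV
#' @param blk a [blocks()] table.
#' @param path output CSV path.
#' @export
write_blocks <- function(blk, path) {
  utils::write.csv(as.data.frame(blk), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

fcc477_map <- c(BlockCode = "block_id", Provider_Id = "provider_id",
                MaxAdDown = "download_mbps", MaxAdUp = "upload_mbps")

#' Read per-provider broadband records from CSV
#'
#' Two dialects: `generic` (columns `block_id`, `provider_id`,
#' `download_mbps`, `upload_mbps`) and `fcc477` (FCC Form 477 deployment
#' headers `BlockCode`, `Provider_Id`, `MaxAdDown`, `MaxAdUp`).
#'
#' @param path CSV file path.
#' @param dialect `"generic"` or `"fcc477"`.
#' @return A [broadband_records()] table.
#' @export
read_broadband <- function(path, dialect = c("generic", "fcc477")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, colClasses = "character")
  if (dialect == "fcc477") {
    require_columns(raw, names(fcc477_map), path)
    names(raw)[match(names(fcc477_map), names(raw))] <- fcc477_map
  }
  require_columns(raw, c("block_id", "provider_id", "download_mbps",
                         "upload_mbps"), path)
  down <- check_numeric_column(raw, "download_mbps", path)
  up <- check_numeric_column(raw, "upload_mbps", path)
  bad <- which(down < 0 | up < 0)
  if (length(bad))
    stop("negative speed in row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  broadband_records(raw$block_id, raw$provider_id, down, up)
}

#' Write broadband records to CSV (generic dialect)
#' @param records a [broadband_records()] table.
#' @param path output CSV path.
#' @export
write_broadband <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read / write a sparse OD travel-time matrix
#'
#' Long format, columns `origin`, `destination`, `minutes`; absent pairs
#' are unreachable.  Duplicate pairs and negative times are rejected.
#'
#' @param path CSV file path.
#' @return [read_od()]: an [od_pairs()] table.
#' @export
read_od <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  require_columns(raw, c("origin", "destination", "minutes"), path)
  od_pairs(raw$origin, raw$destination,
           check_numeric_column(raw, "minutes", path))
}

#' @rdname read_od
#' @param od an [od_pairs()] table.
#' @export
write_od <- function(od, path) {
  utils::write.csv(as.data.frame(od), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Read a road graph from node and edge CSVs
#'
#' Node CSV columns: `node_id`, `x`, `y`.  Edge CSV columns:
#' `from_node`, `to_node`, `minutes`, optional `oneway`.
#'
#' @param node_path,edge_path CSV file paths.
#' @return A [road_graph()].
#' @export
read_road_graph <- function(node_path, edge_path) {
  nodes <- utils::read.csv(node_path, colClasses = "character")
  require_columns(nodes, c("node_id", "x", "y"), node_path)
  nodes$x <- check_numeric_column(nodes, "x", node_path)
  nodes$y <- check_numeric_column(nodes, "y", node_path)
  edges <- utils::read.csv(edge_path, colClasses = "character")
  require_columns(edges, c("from_node", "to_node", "minutes"), edge_path)
  edges$minutes <- check_numeric_column(edges, "minutes", edge_path)
  if ("oneway" %in% names(edges)) edges$oneway <- as.logical(edges$oneway)
  road_graph(nodes, edges)
}

#' Read a step-weight schedule from a JSON config
#'
#' Expected shape: `{"breaks": [0.6, 1.2, 3.0],
#' "weights": [0.0, 0.33, 0.66, 1.0]}`, validated against the
#' [step_schedule()] invariants.
#'
#' @param path JSON file path.
#' @return A [step_schedule()].
#' @export
read_schedule <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$breaks) || is.null(cfg$weights))
    stop("schedule config needs 'breaks' and 'weights' (in ", path, ")")
  step_schedule(cfg$breaks, cfg$weights)
}

#' Results table of an accessibility result
#'
#' @param result an `accessibility_result`.
#' @param normalize add a `normalized_score` column
#'   (see [min_max_normalize()]).
#' @param classify_breaks optional breaks for a `class_label` column.
#' @param region_only restrict to report-region blocks.
#' @return `data.frame` with `block_id`, `score` and optional columns.
#' @export
results_table <- function(result, normalize = FALSE,
                          classify_breaks = NULL, region_only = TRUE) {
  blk <- result$blocks
  if (region_only) blk <- blk[blk$in_report_region, , drop = FALSE]
  out <- data.frame(block_id = blk$block_id,
                    score = unname(result$scores[blk$block_id]),
                    stringsAsFactors = FALSE)
  if (normalize) {
    ns <- min_max_normalize(result, region_only = region_only)
    out$normalized_score <- unname(ns[out$block_id])
  }
  if (!is.null(classify_breaks))
    out$class_label <- as.character(
      classify(stats::setNames(out$score, out$block_id),
               classify_breaks))
  out
}

#' Write accessibility results to CSV
#'
#' Scores are written with full double precision (15 significant digits),
#' so a write-read round trip preserves at least 12 significant digits.
#'
#' @inheritParams results_table
#' @param path output CSV path.
#' @export
write_results <- function(result, path, normalize = FALSE,
                          classify_breaks = NULL, region_only = TRUE) {
  tab <- results_table(result, normalize, classify_breaks, region_only)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a difference result to CSV
#' @param diff a [difference()] result.
#' @param path output CSV path for the per-block table.
#' @export
write_difference <- function(diff, path) {
  tab <- diff$table
  tab$delta <- sprintf("%.15g", tab$delta)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write accessibility results as GeoJSON point features
#'
#' Emits one Point feature per in-scope block at its centroid, with
#' `block_id`, `score` and `population` properties -- enough to map the
#' scores when polygon geometry is unavailable.
#'
#' @param result an `accessibility_result`.
#' @param path output GeoJSON path.
#' @param region_only restrict to report-region blocks.
#' @export
write_geojson <- function(result, path, region_only = TRUE) {
  blk <- result$blocks
  if (region_only) blk <- blk[blk$in_report_region, , drop = FALSE]
  features <- lapply(seq_len(nrow(blk)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(blk$x[i], blk$y[i])),
         properties = list(block_id = blk$block_id[i],
                           score = unname(result$scores[blk$block_id[i]]),
                           population = blk$population[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
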