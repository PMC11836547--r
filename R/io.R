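# Readers and writers for the pipeline's tabular interchange formats:
# pollen archives and presence grids as CSV, climate covariates as long CSV,
# species parameters as JSON, range polygons as GeoJSON, configs as YAML.
# Each read/write pair is an identity on the data model.

#' Write / read a pollen archive CSV
#'
#' The column schema is the archive's own (site metadata, one
#' `count_<taxon>` column per taxon, `total_count`); the taxa list is
#' recovered from the count columns on read.
#'
#' @param archive a `pollen_archive`.
#' @param path file path.
#' @return `read_pollen_csv()` returns the archive; `write_pollen_csv()`
#'   returns `path` invisibly.
#' @export
write_pollen_csv <- function(archive, path) {
  utils::write.csv(as.data.frame(archive), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pollen_csv
#' @export
read_pollen_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(POLLEN_REQUIRED_COLS, names(out))
  if (length(miss)) stopf("malformed pollen CSV '%s': missing column(s) %s",
                          path, paste(miss, collapse = ", "))
  cc <- grep("^count_", names(out), value = TRUE)
  taxa <- setdiff(sub("^count_", "", cc), "other")
  attr(out, "taxa") <- taxa
  class(out) <- c("pollen_archive", class(out))
  out
}

#' Write / read a presence grid CSV
#'
#' @param grid a `presence_grid`.
#' @param path file path.
#' @param dims coarse grid dimensions (rows, cols) when reading.
#' @export
write_presence_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_csv
#' @export
read_presence_csv <- function(path, dims = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "bin_centre_bp", "taxon", "state")
  miss <- setdiff(need, names(out))
  if (length(miss)) stopf("malformed presence CSV '%s': missing column(s) %s",
                          path, paste(miss, collapse = ", "))
  attr(out, "dims") <- dims
  class(out) <- c("presence_grid", class(out))
  out
}

#' Write / read the slice-level climate covariates as long CSV
#'
#' Serialises the derived 30-year covariates (one row per slice, cell);
#' the per-year seasonal fields are simulation-internal and are not written.
#'
#' @param slices list of `climate_slice`s.
#' @param path file path.
#' @export
write_climate_csv <- function(slices, path) {
  rows <- lapply(slices, function(sl) {
    nr <- nrow(sl$tmin_winter); nc <- ncol(sl$tmin_winter)
    data.frame(time_bp = sl$time_bp,
               row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
               tmin_winter = as.numeric(sl$tmin_winter),
               gdd = as.numeric(sl$gdd),
               precip_total = as.numeric(sl$precip_total),
               water_balance_summer = as.numeric(sl$water_balance_summer))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_bp", "row", "col", CLIMATE_COVARIATES)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("malformed climate CSV '%s': missing column(s) %s",
                          path, paste(miss, collapse = ", "))
  lapply(split(df, df$time_bp)[order(-as.numeric(names(split(df, df$time_bp))))],
         function(sub) {
           nr <- max(sub$row); nc <- max(sub$col)
           sl <- list(time_bp = sub$time_bp[1L])
           for (v in CLIMATE_COVARIATES) {
             m <- matrix(NA_real_, nr, nc)
             m[cbind(sub$row, sub$col)] <- sub[[v]]
             sl[[v]] <- m
           }
           structure(sl, class = "climate_slice")
         })
}

#' Write / read virtual-species parameters as JSON
#'
#' @param species a [virtual_species()] or list of them.
#' @param path file path.
#' @export
write_species_json <- function(species, path) {
  if (inherits(species, "virtual_species")) species <- list(species)
  jsonlite::write_json(lapply(species, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_species_json
#' @export
read_species_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(lst, function(sp) do.call(virtual_species, sp))
}

#' Read / write a GeoJSON polygon
#'
#' Uses the first ring of the first Polygon (or MultiPolygon) geometry found
#' in the file.
#'
#' @param path file path.
#' @param polygon vertex matrix (columns x, y) when writing.
#' @return a vertex matrix with columns `x`, `y`.
#' @export
read_geojson_polygon <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- if (!is.null(gj$type) && gj$type == "FeatureCollection") {
    gj$features[[1L]]$geometry
  } else if (!is.null(gj$type) && gj$type == "Feature") {
    gj$geometry
  } else gj
  if (is.null(geom$type)) stopf("no geometry found in '%s'", path)
  ring <- switch(geom$type,
                 Polygon = geom$coordinates[[1L]],
                 MultiPolygon = geom$coordinates[[1L]][[1L]],
                 stopf("unsupported geometry type '%s' in '%s'",
                       geom$type, path))
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
  colnames(m) <- c("x", "y")
  m
}

#' @rdname read_geojson_polygon
#' @export
write_geojson_polygon <- function(polygon, path) {
  polygon <- as.matrix(polygon)
  if (!all(polygon[1L, ] == polygon[nrow(polygon), ])) {
    polygon <- rbind(polygon, polygon[1L, ])
  }
  gj <- list(type = "Polygon",
             coordinates = list(lapply(seq_len(nrow(polygon)), function(i)
               as.numeric(polygon[i, ]))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config an [experiment_config()] (or plain list).
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experiment_config, cfg)
}
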