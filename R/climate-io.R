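#' Read a per-sample climate table
#'
#' Expects a CSV with a `sample_id` column and the 20 annual climate variables
#' (see [climate_variables()]). Header aliases such as `DD<0`/`DD_0` and
#' `DD>5`/`DD5` are accepted case-insensitively and normalized to the
#' canonical spelling. Rows with missing or non-finite predictor values are
#' rejected: downstream forests require complete climate rows.
#'
#' @param path CSV file path.
#' @return A tibble with `sample_id` (and `population_id` if present) followed
#'   by the 20 climate columns in canonical order.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- normalize_climate_names(names(df))
  if (!"sample_id" %in% names(df)) {
    stop("climate table must have a sample_id column", call. = FALSE)
  }
  check_climate_columns(df, where = basename(path))
  keep <- intersect(c("sample_id", "population_id"), names(df))
  out <- tibble::as_tibble(df[c(keep, climate_variable_names())])
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in climate table", call. = FALSE)
  }
  out
}

#' Write a climate table as CSV
#' @param climate Climate tibble (as returned by [read_climate_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climate_table <- function(climate, path) {
  utils::write.csv(climate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gridded surfaces -------------------------------------------------------
#
# Grids are tibbles of masked-in cells: columns x, y (cell-center coordinates)
# plus one column per band, with grid geometry carried in attributes. On disk
# each band is an ESRI ASCII grid (.asc, plain text, row 0 = northernmost row)
# and a JSON sidecar records band names, cell size and CRS tag.

#' Construct a climate grid from a cell table
#'
#' @param cells Tibble/data frame with `x`, `y` cell-center coordinates plus
#'   one numeric column per band. Only masked-in (valid) cells are present.
#' @param cellsize Cell edge length in the grid's linear units (default 800 m).
#' @param crs Free-text coordinate-system tag (must be an equal-area or
#'   projected system for area accounting; not interpreted further).
#' @return A `climate_grid` tibble.
#' @export
climate_grid <- function(cells, cellsize = 800, crs = "local-equal-area") {
  cells <- tibble::as_tibble(cells)
  if (!all(c("x", "y") %in% names(cells))) {
    stop("grid cells need x and y columns", call. = FALSE)
  }
  if (anyDuplicated(cells[c("x", "y")])) {
    stop("duplicate grid cells", call. = FALSE)
  }
  structure(cells,
            class = c("climate_grid", class(tibble::tibble()))) |>
    set_grid_meta(cellsize = cellsize, crs = crs)
}

set_grid_meta <- function(g, cellsize, crs) {
  attr(g, "cellsize") <- cellsize
  attr(g, "crs") <- crs
  g
}

#' Grid cell size and cell area
#' @param g A grid tibble (`climate_grid`, `genomic_grid` or `zone_map`).
#' @return `grid_cellsize()`: the linear cell size; `cell_area_km2()`: the
#'   per-cell area in square kilometres.
#' @export
grid_cellsize <- function(g) attr(g, "cellsize") %||% 800

#' @rdname grid_cellsize
#' @export
cell_area_km2 <- function(g) (grid_cellsize(g) / 1000)^2

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the band (non-coordinate) columns of a grid
#' @param g Grid tibble.
#' @return Character vector of band column names.
#' @export
grid_bands <- function(g) setdiff(names(g), c("x", "y", "zone", "cell"))

# ---- ESRI ASCII grid serialization -----------------------------------------

write_asc_band <- function(values, xs, ys, cellsize, path, na_value = -9999) {
  ux <- sort(unique(xs)); uy <- sort(unique(ys), decreasing = TRUE)
  m <- matrix(na_value, nrow = length(uy), ncol = length(ux))
  m[cbind(match(ys, uy), match(xs, ux))] <- values
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", min(ux) - cellsize / 2),
    sprintf("yllcorner %.10g", min(uy) - cellsize / 2),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %g", na_value)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_asc_band <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[[`, "", 1))
  vals <- as.numeric(vapply(kv, `[[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% keys)) {
    stop(sprintf("malformed ASCII grid header in %s", path), call. = FALSE)
  }
  body <- lines[-(1:6)]
  m <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (nrow(m) != vals[["nrows"]] || ncol(m) != vals[["ncols"]]) {
    stop(sprintf("ASCII grid body does not match header dimensions in %s", path),
         call. = FALSE)
  }
  cs <- vals[["cellsize"]]
  xs <- vals[["xllcorner"]] + cs / 2 + (seq_len(ncol(m)) - 1) * cs
  ys <- vals[["yllcorner"]] + cs / 2 + (rev(seq_len(nrow(m))) - 1) * cs
  cells <- expand.grid(x = xs, y = ys)[, c("x", "y")]
  # expand.grid varies x fastest; ys[1] is the northernmost row, matching the
  # row-major body of the raster
  cells$value <- as.vector(t(m))
  # reorder so rows go north-to-south, west-to-east for stable output
  cells <- cells[order(-cells$y, cells$x), ]
  cells <- cells[cells$value != vals[["nodata_value"]], ]
  list(cells = tibble::as_tibble(cells), cellsize = cs)
}

#' Read a multiband climate grid from ASCII rasters
#'
#' @param paths Named character vector of `.asc` file paths, one per climate
#'   variable, or a directory containing `<VAR>.asc` files. All bands must be
#'   co-registered (same cells); cells flagged NODATA in any band are masked
#'   out of all bands.
#' @param crs Coordinate-system tag to attach.
#' @return A `climate_grid` tibble.
#' @export
read_climate_grid <- function(paths, crs = "local-equal-area") {
  if (length(paths) == 1 && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.asc$", full.names = TRUE)
    names(files) <- sub("\\.asc$", "", basename(files))
    paths <- files
  }
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("band paths must be named by climate variable", call. = FALSE)
  }
  names(paths) <- normalize_climate_names(names(paths))
  missing <- setdiff(climate_variable_names(), names(paths))
  if (length(missing) > 0) {
    stop(sprintf("%s absent from grid bands", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  bands <- lapply(paths[climate_variable_names()], read_asc_band)
  cs <- unique(vapply(bands, `[[`, numeric(1), "cellsize"))
  if (length(cs) != 1) stop("bands disagree on cell size", call. = FALSE)
  ref <- bands[[1]]$cells[c("x", "y")]
  out <- ref
  for (v in names(bands)) {
    b <- bands[[v]]$cells
    if (nrow(b) != nrow(ref) || !isTRUE(all.equal(b$x, ref$x)) ||
        !isTRUE(all.equal(b$y, ref$y))) {
      # mask intersection: keep cells present in every band
      out <- dplyr::inner_join(out, stats::setNames(b, c("x", "y", v)),
                               by = c("x", "y"))
    } else {
      out[[v]] <- b$value
    }
  }
  climate_grid(out, cellsize = cs, crs = crs)
}

#' Write a climate grid as per-band ASCII rasters plus a JSON sidecar
#'
#' @param grid A `climate_grid`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written band paths, invisibly.
#' @export
write_climate_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (v in grid_bands(grid)) {
    p <- file.path(dir, paste0(v, ".asc"))
    write_asc_band(grid[[v]], grid$x, grid$y, grid_cellsize(grid), p)
    out[v] <- p
  }
  jsonlite::write_json(
    list(bands = grid_bands(grid), cellsize = grid_cellsize(grid),
         crs = attr(grid, "crs")),
    file.path(dir, "grid.json"), auto_unbox = TRUE)
  invisible(out)
}

# ---- zone maps --------------------------------------------------------------

#' Construct a zone map
#'
#' A categorical raster in tibble form: masked-in cells with integer zone
#' labels. Cells outside the species range are simply absent.
#'
#' @param cells Tibble with `x`, `y`, `zone` (positive integers).
#' @param cellsize Cell edge length (linear units, default 800 m).
#' @param crs Coordinate-system tag; must be a projected/equal-area tag for
#'   area accounting.
#' @param provenance Free-text source tag.
#' @return A `zone_map` tibble.
#' @export
zone_map <- function(cells, cellsize = 800, crs = "local-equal-area",
                     provenance = "gfzone") {
  cells <- tibble::as_tibble(cells)
  if (!all(c("x", "y", "zone") %in% names(cells))) {
    stop("zone map needs x, y, zone columns", call. = FALSE)
  }
  if (anyDuplicated(cells[c("x", "y")])) stop("duplicate zone-map cells", call. = FALSE)
  if (any(is.na(cells$zone)) || any(cells$zone < 1) ||
      any(cells$zone != round(cells$zone))) {
    stop("zone labels must be positive integers", call. = FALSE)
  }
  cells$zone <- as.integer(cells$zone)
  out <- structure(cells, class = c("zone_map", class(tibble::tibble())))
  out <- set_grid_meta(out, cellsize = cellsize, crs = crs)
  attr(out, "provenance") <- provenance
  out
}

#' Write / read a zone map as a categorical ASCII raster
#'
#' `write_zone_map()` writes a single-band ASCII grid (zone id per cell, NODATA
#' outside the mask) plus a JSON sidecar with cell size, CRS and provenance;
#' `read_zone_map()` round-trips it bit-exactly.
#'
#' @param z A [zone_map()].
#' @param path Output `.asc` path.
#' @return `write_zone_map()`: `path`, invisibly. `read_zone_map()`: the
#'   `zone_map`.
#' @export
write_zone_map <- function(z, path) {
  stopifnot(inherits(z, "zone_map"))
  write_asc_band(z$zone, z$x, z$y, grid_cellsize(z), path, na_value = 0)
  jsonlite::write_json(
    list(cellsize = grid_cellsize(z), crs = attr(z, "crs"),
         provenance = attr(z, "provenance")),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_zone_map
#' @export
read_zone_map <- function(path) {
  b <- read_asc_band(path)
  meta <- list(crs = "local-equal-area", provenance = basename(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- utils::modifyList(meta, jsonlite::read_json(side))
  cells <- b$cells
  names(cells) <- c("x", "y", "zone")
  zone_map(cells, cellsize = b$cellsize, crs = meta$crs,
           provenance = meta$provenance)
}
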