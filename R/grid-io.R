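#' Read / write a raster layer as ESRI ASCII grid
#'
#' Plain-text raster exchange format with the
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header. Matrices in
#' this package store row 1 at the south edge; the file format lists rows
#' north to south, so the writer flips row order and the reader flips it
#' back. Round-trip write-read is lossless at the printed precision (15
#' significant digits).
#'
#' @param mat Numeric matrix (rows = y from the south, columns = x).
#' @param path File path.
#' @param origin `c(xllcorner, yllcorner)` in m.
#' @param cellsize Cell size in m.
#' @param nodata NODATA sentinel value.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a list with `mat`, `origin`, `cellsize`, `nodata` (`NA` in
#'   `mat` marks NODATA cells).
#' @export
write_esri_ascii <- function(mat, path, origin = c(0, 0), cellsize = 10,
                             nodata = -9999) {
  stopifnot(is.matrix(mat))
  out <- mat
  out[is.na(out)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(mat)),
           sprintf("nrows %d", nrow(mat)),
           sprintf("xllcorner %.15g", origin[1]),
           sprintf("yllcorner %.15g", origin[2]),
           sprintf("cellsize %.15g", cellsize),
           sprintf("NODATA_value %.15g", nodata))
  rows <- apply(out[rev(seq_len(nrow(out))), , drop = FALSE], 1,
                function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines")
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[[`, character(1), 1))
  vals <- as.numeric(vapply(kv, `[[`, character(1), 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ESRI ASCII header: expected ", paste(need, collapse = "/"))
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  body <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  if (length(body) != nc * nr)
    stop(sprintf("ESRI ASCII body has %d values, expected %d",
                 length(body), nc * nr))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-up storage
  list(mat = m, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
       cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}

#' Read a paired aircraft/road exposure grid from two rasters
#'
#' @param aircraft_path,road_path ESRI ASCII grid files with identical shape,
#'   origin and cell size.
#' @return An `exposure_grid` object.
#' @export
read_grid <- function(aircraft_path, road_path) {
  a <- read_esri_ascii(aircraft_path)
  r <- read_esri_ascii(road_path)
  if (!all(dim(a$mat) == dim(r$mat)) || a$cellsize != r$cellsize ||
      !all(a$origin == r$origin))
    stop("aircraft and road rasters disagree in shape, origin or cell size")
  structure(list(aircraft = a$mat, road = r$mat, origin = a$origin,
                 cellsize = a$cellsize),
            class = "exposure_grid")
}

#' @rdname read_grid
#' @param grid An `exposure_grid`.
#' @param dir Output directory (created if needed).
#' @export
write_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "exposure_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_esri_ascii(grid$aircraft, file.path(dir, "aircraft_laeq.asc"),
                   grid$origin, grid$cellsize)
  write_esri_ascii(grid$road, file.path(dir, "road_laeq.asc"),
                   grid$origin, grid$cellsize)
  invisible(dir)
}

#' Long-format CSV export of an annoyance grid
#'
#' One row per cell and layer: `x,y,layer,value` (cell centers in m).
#'
#' @param agrid An `annoyance_grid` from [annoyance_surface()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
annoyance_grid_to_csv <- function(agrid, path) {
  stopifnot(inherits(agrid, "annoyance_grid"))
  rows <- lapply(names(agrid$layers), function(nm) {
    m <- agrid$layers[[nm]]
    idx <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
    data.frame(x = agrid$origin[1] + (idx$j - 0.5) * agrid$cellsize,
               y = agrid$origin[2] + (idx$i - 0.5) * agrid$cellsize,
               layer = nm, value = m[cbind(idx$i, idx$j)])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
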