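# Regular grids on the projected plane. A grid is defined by the lower-left
# corner of its lower-left cell (km), the cell size (km) and the cell counts.
# Cells are half-open squares [x0 + (i-1)c, x0 + ic) x [y0 + (j-1)c, y0 + jc),
# identified by their 1-based (ix, iy) indices; values are stored in an
# nx x ny matrix indexed [ix, iy].

#' Define a regular projected grid
#'
#' @param x0,y0 Lower-left corner of the grid (km, projected plane).
#' @param nx,ny Number of cells in x and y.
#' @param cell_km Cell size (km), > 0.
#' @return An object of class `ir_grid`.
#' @export
make_grid <- function(x0, y0, nx, ny, cell_km) {
  stopifnot(cell_km > 0, nx >= 1, ny >= 1)
  structure(list(x0 = x0, y0 = y0, nx = as.integer(nx), ny = as.integer(ny),
                 cell_km = cell_km),
            class = "ir_grid")
}

#' @export
print.ir_grid <- function(x, ...) {
  cat(sprintf("<ir_grid %d x %d cells of %.4g km, origin (%.1f, %.1f) km>\n",
              x$nx, x$ny, x$cell_km, x$x0, x$y0))
  invisible(x)
}

grid_same <- function(g1, g2) {
  isTRUE(all.equal(unclass(g1)[c("x0", "y0", "cell_km")],
                   unclass(g2)[c("x0", "y0", "cell_km")])) &&
    g1$nx == g2$nx && g1$ny == g2$ny
}

# Cell-centre coordinate vectors (km).
grid_xc <- function(g) g$x0 + (seq_len(g$nx) - 0.5) * g$cell_km
grid_yc <- function(g) g$y0 + (seq_len(g$ny) - 0.5) * g$cell_km

# lon/lat of all cell centres as nx*ny-row matrix in column-major cell order.
grid_centres_lonlat <- function(g) {
  xy <- expand.grid(x = grid_xc(g), y = grid_yc(g))
  polar_lonlat(xy$x, xy$y)
}

# Cell index of projected points; 0 when outside the grid.
grid_cell_index <- function(g, x, y) {
  ix <- floor((x - g$x0) / g$cell_km) + 1
  iy <- floor((y - g$y0) / g$cell_km) + 1
  ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
  cbind(ix = ifelse(ok, ix, 0L), iy = ifelse(ok, iy, 0L))
}

grid_cell_of_lonlat <- function(g, lon, lat) {
  xy <- polar_xy(lon, lat)
  grid_cell_index(g, xy[, "x"], xy[, "y"])
}

# Area of one cell, km^2 (planar; the projection is equidistant so cell
# areas are treated as uniform).
grid_cell_area <- function(g) g$cell_km^2

# Count of 8-connected components among TRUE cells of an nx x ny logical
# matrix. Iterative flood fill (no recursion).
count_components_8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  ncomp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    lab[start] <- ncomp
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- ((cur - 1L) %% nx) + 1L
      cj <- ((cur - 1L) %/% nx) + 1L
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0L && dj == 0L) next
        ni <- ci + di; nj <- cj + dj
        if (ni < 1L || ni > nx || nj < 1L || nj > ny) next
        k <- (nj - 1L) * nx + ni
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- ncomp
          stack <- c(stack, k)
        }
      }
    }
  }
  ncomp
}
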