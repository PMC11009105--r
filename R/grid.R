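#' Build a rectangular lattice of grid cells with queen (8-neighbour) adjacency
#'
#' Creates the lattice that stands in for an atlas grid: one row per cell with
#' integer row/column indices and planar centroid coordinates, plus a sparse
#' symmetric adjacency matrix over the up-to-8 surrounding cells (queen moves).
#'
#' @param n_rows,n_cols Lattice dimensions; both must be at least 2.
#' @param cell_size Spacing between cell centroids, in arbitrary planar units.
#'
#' @return A tibble of class `gs_grid` with columns `cell_id`, `row`, `col`,
#'   `x`, `y`, carrying the adjacency as a sparse logical matrix in the
#'   `"adjacency"` attribute (dimnames are cell ids).
#'
#' @examples
#' g <- make_grid(3, 3)
#' grid_neighbours(g)[["c02_02"]]  # the centre cell touches all 8 others
#' @export
make_grid <- function(n_rows, n_cols, cell_size = 1) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1)
  if (!is.finite(n_rows) || !is.finite(n_cols) || n_rows < 2 || n_cols < 2 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("`n_rows` and `n_cols` must be integers >= 2", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  cells <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  wid <- max(2L, nchar(as.character(max(n_rows, n_cols))))
  cells <- dplyr::mutate(
    cells,
    cell_id = sprintf("c%0*d_%0*d", wid, .data$row, wid, .data$col),
    x = (.data$col - 0.5) * cell_size,
    y = (.data$row - 0.5) * cell_size
  )
  cells <- dplyr::select(cells, "cell_id", "row", "col", "x", "y")

  adj <- queen_adjacency(cells$row, cells$col)
  dimnames(adj) <- list(cells$cell_id, cells$cell_id)

  out <- tibble::new_tibble(cells, class = "gs_grid")
  attr(out, "adjacency") <- adj
  out
}

# Sparse symmetric queen adjacency from integer lattice coordinates.
# Two cells are adjacent iff their Chebyshev distance is exactly 1.
queen_adjacency <- function(row, col) {
  n_rows <- max(row)
  n_cols <- max(col)
  idx <- matrix(NA_integer_, n_rows, n_cols)
  idx[cbind(row, col)] <- seq_along(row)
  from <- integer(0)
  to <- integer(0)
  shifts <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (s in shifts) {
    r2 <- row + s[1]
    c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= n_rows & c2 >= 1L & c2 <= n_cols
    j <- idx[cbind(r2[ok], c2[ok])]
    from <- c(from, which(ok), j)
    to <- c(to, j, which(ok))
  }
  Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(length(row), length(row)))
}

#' Neighbour lists of a lattice
#'
#' @param grid A grid built by [make_grid()].
#' @return A named list: for each cell, the character vector of adjacent cell ids.
#' @export
grid_neighbours <- function(grid) {
  adj <- grid_adjacency(grid)
  ids <- colnames(adj)
  apply(adj > 0, 1, function(z) ids[z], simplify = FALSE)
}

#' @rdname grid_neighbours
#' @return `grid_adjacency()`: the sparse symmetric 0/1 adjacency matrix.
#' @export
grid_adjacency <- function(grid) {
  adj <- attr(grid, "adjacency")
  if (is.null(adj)) stop("not a grid built by make_grid(): no adjacency attribute", call. = FALSE)
  adj
}

#' Intrinsic CAR precision structure for a lattice
#'
#' Builds the precision matrix Q = D - W of the intrinsic conditional
#' autoregressive (iCAR) prior over the queen-adjacency graph: D is the
#' diagonal of neighbour counts and W the 0/1 adjacency. Q is symmetric
#' positive semi-definite with the constant vector (per connected component)
#' in its null space; the spatial random effect is identified by a sum-to-zero
#' constraint, applied per connected component during sampling.
#'
#' Isolated cells (no neighbours) cannot carry a structured effect; they are
#' dropped from the structure with a warning and callers exclude them from
#' the spatial term.
#'
#' @param grid A grid built by [make_grid()], or any object with a
#'   [grid_adjacency()] attribute.
#' @return A list of class `gs_icar`: `Q` (sparse symmetric), `W`, `D`
#'   (neighbour counts, named), `cell_id`, `n_components`, `component`
#'   (integer component label per cell), and `rank` (n - n_components).
#' @export
build_icar <- function(grid) {
  W <- grid_adjacency(grid)
  d <- Matrix::rowSums(W)
  isolated <- d == 0
  if (any(isolated)) {
    warning(sum(isolated), " isolated cell(s) excluded from the spatial structure",
            call. = FALSE)
    keep <- which(!isolated)
    W <- W[keep, keep, drop = FALSE]
    d <- d[keep]
  }
  Q <- Matrix::Diagonal(x = d) - W
  Q <- methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
  comp <- graph_components(W)
  list(
    Q = Q, W = W, D = d, cell_id = colnames(W),
    n_components = max(comp), component = comp,
    rank = length(d) - max(comp)
  ) |> structure(class = "gs_icar")
}

# Connected components by breadth-first search on a sparse adjacency matrix.
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  Wl <- methods::as(W, "CsparseMatrix")
  nb <- split(Wl@i + 1L, factor(rep(seq_len(n), diff(Wl@p)), levels = seq_len(n)))
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    k <- k + 1L
    frontier <- start
    comp[start] <- k
    while (length(frontier)) {
      nxt <- unique(unlist(nb[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

# Pairwise centroid distances, dense; grids at desk scale are small.
grid_distances <- function(grid) {
  as.matrix(stats::dist(cbind(grid$x, grid$y)))
}
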