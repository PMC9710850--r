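#' Spatiotemporal cell-density datasets
#'
#' A `density_dataset` holds scratch-assay style density observations on a
#' fixed space-time grid with one or more experimental replicates. Densities
#' are stored as an N x M x Rep array (space x time x replicate); positions
#' and times are strictly increasing. Datasets carry a `units_state` flag so
#' the working-unit rescaling (see [rescale_units()]) is applied exactly once.
#'
#' @param positions numeric, strictly increasing spatial coordinates.
#' @param times numeric, strictly increasing observation times.
#' @param densities numeric array `length(positions) x length(times) x Rep`
#'   (a matrix is treated as a single replicate).
#' @param units_state `"raw"` (micrometres, hours, cells per square
#'   micrometre) or `"rescaled"` (millimetres, days, densities times 1e6).
#' @return An object of class `density_dataset`.
#' @export
density_dataset <- function(positions, times, densities,
                            units_state = c("raw", "rescaled")) {
  units_state <- match.arg(units_state)
  positions <- as.numeric(positions)
  times <- as.numeric(times)
  if (length(positions) < 1L || any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.matrix(densities)) densities <- array(densities, c(dim(densities), 1L))
  if (!is.array(densities) || length(dim(densities)) != 3L)
    stop("densities must be an N x M x Rep array")
  d <- dim(densities)
  if (d[1] != length(positions) || d[2] != length(times))
    stop("densities dimensions do not match positions/times")
  if (d[3] < 1L) stop("at least one replicate is required")
  if (!all(is.finite(densities)))
    stop("densities must be finite with no missing cells")
  structure(
    list(positions = positions, times = times, densities = densities,
         replicate_count = d[3], units_state = units_state),
    class = "density_dataset")
}

#' @export
print.density_dataset <- function(x, ...) {
  cat(sprintf(
    "density_dataset: %d positions x %d times x %d replicates (%s units)\n",
    length(x$positions), length(x$times), x$replicate_count, x$units_state))
  invisible(x)
}

#' Number of observations in a dataset
#'
#' @param data a [density_dataset()].
#' @return `N * M * Rep`.
#' @export
n_observations <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  length(data$densities)
}

#' Read a delimited density table
#'
#' Reads a text table with header columns `position`, `time`, `density`, and
#' `replicate` and assembles a validated [density_dataset()]. Rows may appear
#' in any order; every replicate must observe the full position x time grid.
#'
#' @param path path to a delimited text file.
#' @param dialect `"auto"` (sniff comma vs tab from the header line),
#'   `"csv"`, or `"tsv"`.
#' @return A [density_dataset()] in raw units.
#' @export
load_density_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    header <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", header)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  required <- c("position", "time", "density", "replicate")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "))
  num <- lapply(required, function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric '%s' in column '%s' at data row %d",
                   tab[[col]][bad[1]], col, bad[1]))
    v
  })
  names(num) <- required
  density_table_to_dataset(as.data.frame(num))
}

# Assemble the grid layout from long-format rows; space varies fastest within
# each time block and replicates are appended as whole blocks.
density_table_to_dataset <- function(df) {
  positions <- sort(unique(df$position))
  times <- sort(unique(df$time))
  reps <- sort(unique(df$replicate))
  N <- length(positions); M <- length(times); R <- length(reps)
  if (nrow(df) != N * M * R)
    stop("validation error: ragged replicates (expected ", N * M * R,
         " rows for a full grid, found ", nrow(df), ")")
  arr <- array(NA_real_, c(N, M, R))
  i <- match(df$position, positions)
  j <- match(df$time, times)
  r <- match(df$replicate, reps)
  idx <- cbind(i, j, r)
  if (anyDuplicated(idx))
    stop("validation error: duplicated (position, time, replicate) rows")
  arr[idx] <- df$density
  if (anyNA(arr))
    stop("validation error: ragged replicates (grid not fully observed)")
  density_dataset(positions, times, arr, units_state = "raw")
}

#' Write a dataset back to delimited text
#'
#' Inverse of [load_density_table()]: emits long-format rows in the canonical
#' layout (space fastest, then time, replicates appended).
#'
#' @param data a [density_dataset()].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_density_table <- function(data, path, dialect = c("csv", "tsv")) {
  stopifnot(inherits(data, "density_dataset"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- as.data.frame(flatten_densities(data))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten densities into the canonical observation layout
#'
#' Stacks the density array into a long table ordered space-fastest within
#' each time block, with replicates appended as whole blocks. This is the
#' layout used to build the Gaussian-process training vector and inputs.
#'
#' @param data a [density_dataset()].
#' @return A list with `position`, `time`, `replicate`, and `density`
#'   vectors of length `N * M * Rep`.
#' @export
flatten_densities <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  N <- length(data$positions); M <- length(data$times)
  R <- data$replicate_count
  list(
    position = rep(rep(data$positions, times = M), times = R),
    time = rep(rep(data$times, each = N), times = R),
    replicate = rep(seq_len(R), each = N * M),
    density = as.vector(data$densities))
}

#' Rebuild the density array from the canonical flattened layout
#'
#' @param data a [density_dataset()] giving the grid shape.
#' @param values vector of length `N * M * Rep` in the layout of
#'   [flatten_densities()].
#' @return An N x M x Rep array.
#' @export
unflatten_densities <- function(data, values) {
  stopifnot(inherits(data, "density_dataset"))
  if (length(values) != n_observations(data))
    stop("dimension error: expected ", n_observations(data), " values")
  array(values, dim(data$densities))
}

# Working-unit conversion constants: positions um -> mm, times h -> d,
# densities cells um^-2 scaled by 1e6 so u = O(10^3) after rescaling.
.rescale_factors <- list(x = 1e-3, t = 1 / 24, u = 1e6)

#' Rescale a dataset to working units
#'
#' Converts positions to millimetres (divide by 1e3), times to days (divide
#' by 24), and multiplies densities by 1e6, putting all quantities on O(1) to
#' O(1e3) scales so that downstream optimisation is well conditioned.
#'
#' @param data a raw-unit [density_dataset()].
#' @return The rescaled dataset (`units_state = "rescaled"`).
#' @seealso [unrescale_units()] for the exact inverse.
#' @export
rescale_units <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  if (data$units_state != "raw")
    stop("state error: dataset is already rescaled")
  density_dataset(data$positions * .rescale_factors$x,
                  data$times * .rescale_factors$t,
                  data$densities * .rescale_factors$u,
                  units_state = "rescaled")
}

#' Undo the working-unit rescaling
#'
#' @param data a rescaled [density_dataset()].
#' @return The dataset in raw units.
#' @export
unrescale_units <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  if (data$units_state != "rescaled")
    stop("state error: dataset is not rescaled")
  density_dataset(data$positions / .rescale_factors$x,
                  data$times / .rescale_factors$t,
                  data$densities / .rescale_factors$u,
                  units_state = "raw")
}

#' Drop the left-most spatial column
#'
#' Scratch-assay imaging often produces an inflated density at the left edge
#' of the field of view; this removes the first spatial point from every time
#' and replicate.
#'
#' @param data a [density_dataset()] with at least two spatial points.
#' @return The dataset with `N - 1` positions.
#' @export
drop_leftmost <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  N <- length(data$positions)
  if (N < 2L) stop("cannot drop the sole spatial column")
  density_dataset(data$positions[-1L], data$times,
                  data$densities[-1L, , , drop = FALSE],
                  units_state = data$units_state)
}

#' Replicate-averaged density matrix
#'
#' @param data a [density_dataset()].
#' @return An N x M matrix of densities averaged over replicates.
#' @export
average_replicates <- function(data) {
  stopifnot(inherits(data, "density_dataset"))
  apply(data$densities, c(1, 2), mean)
}

#' Unit-interval evaluation grid
#'
#' Builds an `n x m` grid of equally spaced points on the unit square, with
#' the physical spans of the dataset retained so that derivatives taken on
#' the normalised scale can be mapped back to physical units.
#'
#' @param data a [density_dataset()].
#' @param n,m number of spatial and temporal grid points (each >= 2).
#' @return An object of class `unit_grid` with fields `xi`, `tau` (unit
#'   interval coordinates), `x_span`, `t_span` (physical endpoints), and
#'   `xs`, `ts` (physical grid coordinates).
#' @export
unit_interval_grid <- function(data, n = 50L, m = 50L) {
  stopifnot(inherits(data, "density_dataset"))
  n <- as.integer(n); m <- as.integer(m)
  if (n < 2L || m < 2L) stop("grid error: n and m must both be >= 2")
  x_span <- range(data$positions)
  t_span <- range(data$times)
  xi <- seq(0, 1, length.out = n)
  tau <- seq(0, 1, length.out = m)
  structure(
    list(xi = xi, tau = tau, x_span = x_span, t_span = t_span,
         xs = x_span[1] + xi * diff(x_span),
         ts = t_span[1] + tau * diff(t_span),
         n = n, m = m),
    class = "unit_grid")
}

#' Map physical coordinates onto the unit interval
#'
#' @param x numeric coordinates.
#' @param span length-2 physical endpoints.
#' @return `(x - span[1]) / (span[2] - span[1])`.
#' @export
to_unit_interval <- function(x, span) {
  (x - span[1]) / (span[2] - span[1])
}
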