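`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators are bit-reproducible without clobbering
#' the session RNG.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = ge)
    } else if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
      rm(".Random.seed", envir = ge)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one global seed to named pipeline stages, so each
#' random stage has its own reproducible stream. Result is always a valid
#' 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * ((seq_along(codes) - 1L) %% 29L + 1L))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 1) %% 2147483629)
}

# world coordinates (mm) of voxel centres along one axis, centred on the grid
voxel_centers <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

# Trilinear interpolation of `vol` at continuous 1-based voxel coordinates.
# `ijk` is an n x 3 matrix; points outside the grid evaluate to 0.
interp_trilinear <- function(vol, ijk) {
  d <- dim(vol)
  x <- ijk[, 1]; y <- ijk[, 2]; z <- ijk[, 3]
  # snap near-integer coordinates so identity resampling is exact
  x <- ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  y <- ifelse(abs(y - round(y)) < 1e-9, round(y), y)
  z <- ifelse(abs(z - round(z)) < 1e-9, round(z), z)
  out <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  x0 <- pmin(pmax(floor(x), 1), d[1]); x1 <- pmin(x0 + 1, d[1])
  y0 <- pmin(pmax(floor(y), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
  z0 <- pmin(pmax(floor(z), 1), d[3]); z1 <- pmin(z0 + 1, d[3])
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  fz <- pmin(pmax(z - z0, 0), 1)
  g <- function(i, j, k) vol[cbind(i, j, k)]
  v <-
    g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    g(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    g(x1, y1, z0) * fx * fy * (1 - fz) +
    g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    g(x1, y0, z1) * fx * (1 - fy) * fz +
    g(x0, y1, z1) * (1 - fx) * fy * fz +
    g(x1, y1, z1) * fx * fy * fz
  v[out] <- 0
  v
}

# Nearest-neighbour interpolation (labels); outside the grid -> 0.
interp_nearest <- function(vol, ijk) {
  d <- dim(vol)
  i <- round(ijk[, 1]); j <- round(ijk[, 2]); k <- round(ijk[, 3])
  out <- i < 1 | i > d[1] | j < 1 | j > d[2] | k < 1 | k > d[3]
  i <- pmin(pmax(i, 1), d[1]); j <- pmin(pmax(j, 1), d[2])
  k <- pmin(pmax(k, 1), d[3])
  v <- vol[cbind(i, j, k)]
  v[out] <- 0
  v
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

is_binary_array <- function(x) {
  if (is.logical(x)) return(TRUE)
  all(x %in% c(0, 1))
}
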