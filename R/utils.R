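# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Fast data.frame constructor: skips data.frame()'s name mangling and checks.
# All columns must already be equal-length vectors.
fast_df <- function(cols) {
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library code does not disturb user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation; stays within 32-bit integer range.
# A linear-congruential mix keyed by stream index; collisions across the
# (master, index) pairs used here are astronomically unlikely to matter.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483629
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 104729 + 12345) %% 2147483629
  }
  as.integer(s) + 1L
}

# Polynomial rolling hash of a character vector, hex string; used to stamp
# output files with a short configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_epelir <- function(msg, class) {
  stop(structure(class = c(class, "epelir_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# --- quaternion helpers (unit quaternions as length-4 numeric w,x,y,z) ------

quat_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * axis)
}

quat_mult <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

# Summed geodesic angle (degrees) along a path of unit quaternions (n x 4
# matrix). Uses 2*acos(|<q_i, q_{i+1}>|), invariant to the q ~ -q ambiguity.
quat_path_angle_deg <- function(q) {
  n <- nrow(q)
  if (is.null(n) || n < 2L) return(0)
  d <- abs(rowSums(q[-n, , drop = FALSE] * q[-1L, , drop = FALSE]))
  sum(2 * acos(pmin(d, 1)) * 180 / pi)
}
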