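# Internal geometry helpers. All coordinates are nanometres; all angles are
# degrees unless a name says otherwise.

.DEG <- 180 / pi

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.row_norms <- function(m) sqrt(rowSums(m * m))

.unit_rows <- function(m) {
  n <- .row_norms(m)
  m / ifelse(n > 0, n, 1)
}

# Angle in degrees between rows of a and b (or a matrix and a single vector).
.angle_deg <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = nrow(a), ncol = length(b), byrow = TRUE)
  na <- .row_norms(a)
  nb <- .row_norms(b)
  ct <- rowSums(a * b) / (na * nb)
  acos(.clamp(ct, -1, 1)) * .DEG
}

.as_xyz_matrix <- function(x, what = "points") {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_nm", "y_nm", "z_nm"), names(x))
    if (length(cols) == 3L) {
      x <- as.matrix(x[, c("x_nm", "y_nm", "z_nm")])
    } else {
      x <- as.matrix(x)
    }
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != 3L) stop(what, " must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  x
}

# Exact nearest-neighbour search: for each row of `query`, index of the
# closest row of `ref` (ties -> lowest index) and the Euclidean distance.
# Chunked so the distance matrix never exceeds ~chunk x nrow(ref).
.nn_bruteforce <- function(query, ref, chunk = 2000L) {
  query <- .as_xyz_matrix(query, "query")
  ref <- .as_xyz_matrix(ref, "reference")
  if (nrow(ref) == 0L) stop("reference point set is empty")
  nq <- nrow(query)
  idx <- integer(nq)
  dst <- numeric(nq)
  r2 <- rowSums(ref * ref)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(s + chunk - 1L, nq)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q * q), r2, "+") - 2 * tcrossprod(q, ref)
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dst[s:e] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, distance = dst)
}

# Radius search on one point cloud: list of neighbour index vectors
# (inclusive of self, inclusive boundary at exactly `radius`).
.radius_neighbors <- function(points, radius, chunk = 1000L) {
  points <- .as_xyz_matrix(points)
  n <- nrow(points)
  out <- vector("list", n)
  r2all <- rowSums(points * points)
  rad2 <- radius * radius
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q * q), r2all, "+") - 2 * tcrossprod(q, points)
    for (i in seq_len(nrow(d2))) {
      out[[s + i - 1L]] <- which(d2[i, ] <= rad2 + 1e-9)
    }
  }
  out
}

# Largest-remainder allocation of n items to probabilities p (sums to n).
.allocate_counts <- function(n, p) {
  if (n == 0L) return(integer(length(p)))
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Orthonormal basis perpendicular to unit vector v.
.perp_basis <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(
    v[2] * e1[3] - v[3] * e1[2],
    v[3] * e1[1] - v[1] * e1[3],
    v[1] * e1[2] - v[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

# Write a data frame as TSV with 6-significant-digit floats; deterministic.
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = "NA"
  )
  invisible(path)
}

.filament_key <- function(df) paste(df$tomogram_id, df$filament_id, sep = "\r")
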