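# Independent brute-force oracles, written against plain arrays so they
# share no code path with the package's compiled kernels.

# Flood-fill component labelling via iterative stack, pure R.
oracle_label_components <- function(arr, connectivity = 26) {
  dims <- dim(arr)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  man <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6"  = offs[man == 1, , drop = FALSE],
                 "18" = offs[man <= 2, , drop = FALSE],
                 "26" = offs)
  labels <- array(0L, dim = dims)
  nxt <- 0L
  fg <- which(arr, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    v <- fg[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    stack <- list(v)
    labels[v[1], v[2], v[3]] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (arr[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
  }
  labels
}

# World coordinates of TRUE voxels for an axis-aligned geometry.
oracle_world_coords <- function(arr, geometry) {
  idx <- which(arr, arr.ind = TRUE) - 1
  t(apply(idx, 1, function(v)
    (geometry$affine %*% c(v, 1))[1:3]))
}

# All-pairs distance matrix between two coordinate sets.
oracle_dist_matrix <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  out
}

# Surface voxels: foreground with a background/outside 6-neighbour.
oracle_surface <- function(arr) {
  dims <- dim(arr)
  out <- array(FALSE, dims)
  fg <- which(arr, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(fg))) {
    v <- fg[r, ]
    for (k in 1:6) {
      nb <- v + offs[k, ]
      if (any(nb < 1) || any(nb > dims) || !arr[nb[1], nb[2], nb[3]]) {
        out[v[1], v[2], v[3]] <- TRUE
        break
      }
    }
  }
  out
}

oracle_dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

oracle_hd95 <- function(a, b, geometry) {
  sa <- oracle_world_coords(oracle_surface(a), geometry)
  sb <- oracle_world_coords(oracle_surface(b), geometry)
  d <- oracle_dist_matrix(sa, sb)
  max(as.numeric(stats::quantile(apply(d, 1, min), 0.95)),
      as.numeric(stats::quantile(apply(d, 2, min), 0.95)))
}

oracle_min_distance <- function(a, b, geometry) {
  if (any(a & b)) return(0)
  ca <- oracle_world_coords(a, geometry)
  cb <- oracle_world_coords(b, geometry)
  min(oracle_dist_matrix(ca, cb))
}

# Random blobby lattice: a few dilated seed points, possibly empty.
random_lattice <- function(dims, n_seeds = 3, grow = 0.4) {
  arr <- array(FALSE, dims)
  n <- sample(0:n_seeds, 1)
  if (n > 0) {
    for (i in seq_len(n)) {
      c0 <- sapply(dims, function(d) sample(seq_len(d), 1))
      idx <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                   z = seq_len(dims[3])))
      d <- sqrt(rowSums((idx - matrix(c0, nrow(idx), 3, byrow = TRUE))^2))
      r <- stats::runif(1, 1, max(2, min(dims) * grow))
      arr <- arr | array(d <= r, dims)
    }
    # sprinkle noise voxels
    flip <- sample(length(arr), max(1, round(0.01 * length(arr))))
    arr[flip] <- !arr[flip]
  }
  arr
}

# Reference closing: brute-force dilation/erosion loops on a padded
# lattice (pad = radius * iterations), cropped back afterwards.
oracle_closing <- function(arr, radius = 2, iterations = 1) {
  r <- ceiling(radius)
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  pad <- r * iterations
  dims <- dim(arr)
  big <- array(FALSE, dims + 2 * pad)
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])] <- arr
  get_at <- function(a, v) {
    d <- dim(a)
    if (any(v < 1) || any(v > d)) FALSE else a[v[1], v[2], v[3]]
  }
  dilate1 <- function(a) {
    out <- array(FALSE, dim(a))
    fg <- which(a, arr.ind = TRUE)
    for (i in seq_len(nrow(fg)))
      for (k in seq_len(nrow(offs))) {
        v <- fg[i, ] + offs[k, ]
        if (all(v >= 1) && all(v <= dim(a))) out[v[1], v[2], v[3]] <- TRUE
      }
    out
  }
  erode1 <- function(a) {
    out <- array(FALSE, dim(a))
    fg <- which(a, arr.ind = TRUE)
    for (i in seq_len(nrow(fg))) {
      ok <- TRUE
      for (k in seq_len(nrow(offs)))
        if (!get_at(a, fg[i, ] + offs[k, ])) { ok <- FALSE; break }
      if (ok) out[fg[i, 1], fg[i, 2], fg[i, 3]] <- TRUE
    }
    out
  }
  for (i in seq_len(iterations)) big <- dilate1(big)
  for (i in seq_len(iterations)) big <- erode1(big)
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])]
}
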