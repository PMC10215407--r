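# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R loops and closed forms only.

# breadth-first flood fill labeling, independent of the C++ implementation
flood_fill_labels <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  reach <- switch(as.character(connectivity),
                  "6" = 1, "18" = 2, "26" = 3,
                  stop("bad connectivity"))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= reach, , drop = FALSE]
  labels <- array(0L, dims)
  counts <- numeric(0)
  nxt <- 0L
  todo <- which(mask != 0)
  for (s in todo) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    cnt <- 0
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cnt <- cnt + 1
      z <- (cur - 1) %/% (dims[1] * dims[2])
      rem <- (cur - 1) %% (dims[1] * dims[2])
      y <- rem %/% dims[1]
      x <- rem %% dims[1]
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs[k, 1]; yy <- y + offs[k, 2]; zz <- z + offs[k, 3]
        if (xx < 0 || xx >= dims[1] || yy < 0 || yy >= dims[2] ||
            zz < 0 || zz >= dims[3]) next
        idx <- 1 + xx + dims[1] * (yy + dims[2] * zz)
        if (mask[idx] != 0 && labels[idx] == 0L) {
          labels[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
    counts <- c(counts, cnt)
  }
  list(labels = labels, counts = counts)
}

# layer-by-layer trainable-parameter count for the U-Net topology
unet_param_count_formula <- function(widths, in_ch = 1) {
  L <- length(widths)
  conv_params <- function(cin, cout) 9 * cin * cout + cout + 2 * cout
  total <- 0
  for (l in seq_len(L)) {
    cin <- if (l == 1) in_ch else widths[l - 1]
    total <- total + conv_params(cin, widths[l]) +
      conv_params(widths[l], widths[l])
  }
  for (l in (L - 1):1) {
    cin <- widths[l + 1]; cout <- widths[l]
    total <- total + (4 * cin * cout + cout + 2 * cout) +   # upconv + BN
      conv_params(2 * cout, cout) + conv_params(cout, cout)
  }
  total + widths[1] + 1                                      # final 1x1
}

# small random voxel blob: a few random boxes/ellipsoids unioned
random_blob_mask <- function(seed, dims) {
  set.seed(seed)
  m <- array(0L, dims)
  for (i in seq_len(sample(1:3, 1))) {
    c0 <- sapply(dims, function(d) runif(1, 2, d - 1))
    r0 <- sapply(dims, function(d) runif(1, 1, d / 3))
    g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                     z = seq_len(dims[3]))
    inside <- ((g$x - c0[1]) / r0[1])^2 + ((g$y - c0[2]) / r0[2])^2 +
      ((g$z - c0[3]) / r0[3])^2 < 1
    m[as.matrix(g[inside, ])] <- 1L
  }
  if (sum(m) == 0) m[dims[1] %/% 2, dims[2] %/% 2, dims[3] %/% 2] <- 1L
  m
}

# phantom with a randomized single ventricle, mirroring the slice-dataset
# geometry draws
random_phantom <- function(seed) {
  geom <- list(offset = NULL, semi = NULL)
  set.seed(seed)
  geom$offset <- runif(3, -6, 6)
  geom$semi <- c(runif(1, 6, 11), runif(1, 7, 13), runif(1, 5, 10))
  center <- c(64, 48, 64) * c(1.0, 1.5, 1.0) / 2
  generate_head_phantom(phantom_spec(
    ventricles = list(list(center = center + geom$offset,
                           semiaxes = geom$semi)),
    seed = seed))
}
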