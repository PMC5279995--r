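# Shared fixtures, all generated in code.

# digital sphere/ellipsoid masks (voxel-center inclusion)
digital_sphere <- function(r, n = 2 * ceiling(r) + 11, center = rep((n + 1) / 2, 3)) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <= r^2,
        c(n, n, n))
}

digital_ellipsoid <- function(semi, n) {
  c0 <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array(((g$x - c0) / semi[1])^2 + ((g$y - c0) / semi[2])^2 +
          ((g$z - c0) / semi[3])^2 <= 1, c(n, n, n))
}

# small desk-scale study design used across generator tests
small_design <- function(n_nodules = 3, seed = 42) {
  study_design(n_nodules = n_nodules, volume_shape = c(48, 48, 48),
               spacing = c(1, 1, 1), nodule_size_range = c(8, 14),
               seed = seed)
}

# cache expensive simulations across tests within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# two-block feature table: features 1-3 copy source A, 4-5 copy source B,
# with small independent jitter (within-block |CC| ~ 0.993, between ~ 0)
make_block_table <- function(seed = 1, n_nodules = 52, jitter_sd = 0.085) {
  set.seed(seed)
  n <- n_nodules * 9
  A <- rnorm(n); B <- rnorm(n)
  df <- data.frame(nodule_id = rep(seq_len(n_nodules), each = 9),
                   algorithm_id = rep(rep(1:3, each = 3), n_nodules),
                   init_id = rep(1:3, 3 * n_nodules))
  for (i in 1:3) df[[paste0("fA", i)]] <- A + rnorm(n, 0, jitter_sd)
  for (i in 1:2) df[[paste0("fB", i)]] <- B + rnorm(n, 0, jitter_sd)
  feature_table(df)
}

# brute-force run enumeration: literally walk every line of every
# direction, independent of the matrix implementation
brute_force_runs <- function(q, mask, dirs) {
  dims <- dim(mask)
  out <- vector("list", nrow(dirs))
  inside <- function(p) all(p >= 1) && all(p <= dims)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    runs <- list()
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        p <- c(x, y, z)
        if (!mask[x, y, z]) next
        prev <- p - d
        # start of a run: predecessor outside mask or different level
        if (inside(prev) && mask[prev[1], prev[2], prev[3]] &&
            q[prev[1], prev[2], prev[3]] == q[x, y, z]) next
        len <- 1L
        cur <- p + d
        while (inside(cur) && mask[cur[1], cur[2], cur[3]] &&
               q[cur[1], cur[2], cur[3]] == q[x, y, z]) {
          len <- len + 1L
          cur <- cur + d
        }
        runs[[length(runs) + 1L]] <- c(level = q[x, y, z], length = len)
      }
    out[[k]] <- do.call(rbind, runs)
  }
  out
}

# brute-force connected components by breadth-first search over an
# adjacency matrix
bfs_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  list(membership = comp, count = k)
}
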