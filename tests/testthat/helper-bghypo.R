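# shared fixtures and independent oracles

## a reduced phantom: 96 mm field of view, 3/4-scale anatomy, small lesions
## (large enough for several non-touching pallidal lesions, ~3x faster than
## the full-size default grid)
small_spec <- function(n_subjects = 2, seed = 1L, ...) {
  phantom_spec(n_subjects = n_subjects, seed = seed,
               shape = c(96L, 96L, 48L), voxel_size = c(1, 1, 2),
               lesion_radius_mm = c(0.8, 1.8), ...)
}

mask_from_indices <- function(shape, idx, voxel_size = c(1, 1, 1)) {
  arr <- array(0L, dim = shape)
  arr[idx] <- 1L
  voxel_grid(arr, voxel_size = voxel_size, kind = "mask")
}

mask_from_array <- function(arr, voxel_size = c(1, 1, 1)) {
  voxel_grid(array(as.integer(arr != 0), dim = dim(arr)),
             voxel_size = voxel_size, kind = "mask")
}

## brute-force 6-connected flood fill, independent of the package's
## graph-based implementation
ff_components <- function(arr) {
  d <- dim(arr)
  lab <- array(0L, dim = d)
  cur <- 0L
  idx_all <- which(arr > 0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(sum(arr > 0))
    queue[1] <- start
    head <- 1L; tail <- 1L
    lab[start] <- cur
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      co <- arrayInd(v, d)
      for (a in 1:3) for (s in c(-1L, 1L)) {
        nb <- co
        nb[a] <- nb[a] + s
        if (nb[a] < 1L || nb[a] > d[a]) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (arr[li] > 0 && lab[li] == 0L) {
          lab[li] <- cur
          tail <- tail + 1L
          queue[tail] <- li
        }
      }
    }
  }
  lab
}

## exact two-sided rank-sum p by full enumeration of all C(m+n, m) labelings
enum_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  u_of <- function(ix) {
    ra <- rank(pooled)[ix]
    sum(ra) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(length(pooled), m), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

## independent Huber location oracle: clipped-mean fixed point with given scale
huber_fixed_point <- function(x, s, c = 1.345, iters = 500) {
  mu <- median(x)
  for (i in seq_len(iters))
    mu <- mean(pmin(pmax(x, mu - c * s), mu + c * s))
  mu
}

## closed-form least squares through the normal equations
ls_coef <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}
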