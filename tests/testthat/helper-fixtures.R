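# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures are stored.

## Independent oracle for the ZXZ convention: explicit elementary
## rotation product, coded separately from euler_to_matrix.
oracle_zxz <- function(phi, psi, theta) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  rx <- function(a) {
    a <- a * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  }
  rz(psi) %*% rx(theta) %*% rz(phi)
}

rand_rotation <- function() {
  euler_to_matrix(c(runif(1, 0, 360), runif(1, 0, 360), runif(1, 0, 180)))
}

small_particles <- function(n = 3) {
  particle_table(data.frame(
    particle_id = seq_len(n), vesicle_id = rep(1L, n),
    x = seq_len(n) + 0.5, y = 2, z = 3,
    phi = seq(0, 300, length.out = n) %% 360, psi = 10, theta = 20,
    cc_score = seq(0.9, 0.5, length.out = n), halfset = 1L))
}

## A tiny scene with one planted triad at a known pose.
single_triad_scene <- function(angles = c(77, 0, 0),
                               pos = c(23.4, 24.2, 23.8),
                               dims = c(48, 48, 48), voxel = 13.68,
                               boxsize = 32) {
  tmpl <- make_triad_template(boxsize, voxel, coat_height = 50)
  arr <- array(0, dims)
  R <- euler_to_matrix(angles)
  q <- round(pos); delta <- pos - q
  Rt <- t(R)
  stamp <- resample_volume(as_vol_array_test(tmpl), rotation = Rt,
                           offset = as.numeric(-Rt %*% delta))
  half <- boxsize / 2 - 1
  x0 <- q - half
  arr[(x0[1] + 1):(x0[1] + boxsize), (x0[2] + 1):(x0[2] + boxsize),
      (x0[3] + 1):(x0[3] + boxsize)] <- stamp
  list(tomogram = volume3d(arr, voxel), template = tmpl,
       angles = angles, pos = pos, rotation = R)
}

as_vol_array_test <- function(v) {
  a <- unclass(v)
  attr(a, "voxel_size") <- NULL
  attr(a, "origin") <- NULL
  a
}

## Radial mean profile of a volume about a center (simple oracle).
radial_profile_oracle <- function(vol, center) {
  a <- as_vol_array_test(vol)
  d <- dim(a)
  r <- sqrt(outer(outer(((seq_len(d[1]) - 1) - center[1])^2,
                        ((seq_len(d[2]) - 1) - center[2])^2, "+"),
                  ((seq_len(d[3]) - 1) - center[3])^2, "+"))
  rb <- round(r)
  data.frame(r = as.numeric(names(tapply(a, rb, mean))),
             density = as.numeric(tapply(a, rb, mean)))
}

## Connected components of a logical 3D array (6-neighbourhood flood
## fill); small volumes only, used as an independent oracle.
flood_fill_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- ci
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1 || nb[ax] > d[ax]) next
        lin <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- ncomp
          queue <- c(queue, lin)
        }
      }
    }
  }
  ncomp
}

vol_like_test <- function(data, vol) {
  volume3d(array(data, dim(vol)), voxel_size = attr(vol, "voxel_size"))
}

Rz_test <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
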