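# Scoring of ab initio recovery against ground truth. A reference-free
# solution is defined modulo one global in-plane rotation and one common
# local-frame offset (the emergent reference's arbitrary azimuth and
# residual centering); both are estimated from loose matches and removed
# before per-particle errors are computed.

score_recovery <- function(truth, found, match_radius = 1.5,
                           loose_radius = 4) {
  loose <- lapply(seq_len(nrow(truth)), function(i) {
    dd <- sqrt((found$x - truth$x[i])^2 + (found$y - truth$y[i])^2 +
               (found$z - truth$z[i])^2)
    j <- which.min(dd)
    if (dd[j] > loose_radius) return(NULL)
    Rf <- euler_to_matrix(c(found$phi[j], found$psi[j], found$theta[j]))
    list(o = as.numeric(t(Rf) %*% c(truth$x[i] - found$x[j],
                                    truth$y[i] - found$y[j],
                                    truth$z[i] - found$z[j])),
         dphi = (truth$phi[i] - found$phi[j]) %% 120)
  })
  loose <- Filter(Negate(is.null), loose)
  if (length(loose) < 3)
    return(list(n_recovered = 0, ang_err = numeric(0), pos_err = numeric(0)))
  o_hat <- apply(do.call(rbind, lapply(loose, `[[`, "o")), 2, median)
  a <- 2 * pi * vapply(loose, `[[`, 0, "dphi") / 120
  g_hat <- (atan2(mean(sin(a)), mean(cos(a))) * 120 / (2 * pi)) %% 120
  corr <- t(vapply(seq_len(nrow(found)), function(j) {
    Rf <- euler_to_matrix(c(found$phi[j], found$psi[j], found$theta[j]))
    c(found$x[j], found$y[j], found$z[j]) + as.numeric(Rf %*% o_hat)
  }, numeric(3)))
  ang_err <- c(); pos_err <- c()
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((corr[, 1] - truth$x[i])^2 + (corr[, 2] - truth$y[i])^2 +
               (corr[, 3] - truth$z[i])^2)
    j <- which.min(dd)
    if (dd[j] > match_radius) next
    Rt <- euler_to_matrix(c(truth$phi[i], truth$psi[i], truth$theta[i]))
    Rf <- euler_to_matrix(c(found$phi[j], found$psi[j], found$theta[j])) %*%
      coatsitu:::Rz(g_hat)
    ae <- min(vapply(c(0, 120, 240), function(g)
      rotation_angle(Rt %*% coatsitu:::Rz(g), Rf), numeric(1)))
    ang_err <- c(ang_err, ae)
    pos_err <- c(pos_err, dd[j])
  }
  list(n_recovered = length(ang_err), ang_err = ang_err, pos_err = pos_err,
       global_offset = o_hat, global_phi = g_hat)
}
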