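# Shared fixture builders; everything is generated in code at test time.

# small static recording at a fixed attitude
static_recording <- function(q = euler_to_quat(0.3, -0.2, 0.5), secs = 5,
                             noise = sensor_noise_model(0, 0, 0, 0),
                             rate = 50, seed = 1) {
  prof <- activity_profile("static", base_orientation = q)
  tr <- make_orientation_trajectory(prof, secs, rate)
  imu <- synthesize_imu(tr, noise = noise, seed = seed)
  rec <- data.frame(time = tr$time, imu, label = "static", marker = FALSE,
                    qw = tr$q[, 1], qx = tr$q[, 2], qy = tr$q[, 3],
                    qz = tr$q[, 4])
  attr(rec, "subject") <- 1L
  attr(rec, "sample_rate") <- rate
  class(rec) <- c("labeled_recording", "data.frame")
  rec
}

# run the fusion filter over a sensor stream, returning the final state
run_filter <- function(imu, state) {
  for (i in seq_len(nrow(imu)))
    state <- fuse_step(state,
                       as.numeric(imu[i, c("acc_x", "acc_y", "acc_z")]),
                       as.numeric(imu[i, c("gyr_x", "gyr_y", "gyr_z")]),
                       as.numeric(imu[i, c("mag_x", "mag_y", "mag_z")]))
  state
}

random_unit_quat <- function() quat_normalize(stats::rnorm(4))

# independent exhaustive KNN oracle: literal per-query scan with
# euclidean_distance semantics re-derived from first principles
oracle_knn <- function(xtr, ytr, xte, k) {
  cls <- sort(unique(ytr))
  labs <- character(nrow(xte))
  P <- matrix(0, nrow(xte), length(cls), dimnames = list(NULL, cls))
  for (i in seq_len(nrow(xte))) {
    d <- vapply(seq_len(nrow(xtr)), function(j)
      sqrt(sum((xtr[j, ] - xte[i, ])^2)), 0)
    nb <- order(d)[seq_len(k)]
    counts <- table(factor(ytr[nb], levels = cls))
    p <- as.numeric(counts) / k
    top <- cls[p == max(p)]
    labs[i] <- if (length(top) == 1L) top else
      ytr[nb][match(TRUE, ytr[nb] %in% top)]
    P[i, ] <- p
  }
  list(label = labs, prob = P)
}

# feature table from raw matrices
ft_of <- function(x, label, subject, tag = "raw6") {
  x <- as.matrix(x)
  structure(list(x = x, label = as.character(label),
                 subject = rep(as.integer(subject), length.out = nrow(x)),
                 tag = tag),
            class = "feature_table")
}
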