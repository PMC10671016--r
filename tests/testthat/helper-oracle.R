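# Straight-from-definition oracles, written independently of the package
# implementation (per-pixel loops, no integral images, no shift tricks).

# Local mean over a block_size neighbourhood with edge replication.
oracle_local_mean <- function(frame, block_size) {
  r <- (block_size - 1) / 2
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      qi <- min(max(i + di, 1), nr)
      qj <- min(max(j + dj, 1), nc)
      acc <- acc + frame[qi, qj]
    }
    out[i, j] <- acc / block_size^2
  }
  out
}

oracle_binarize <- function(frame, params) {
  bad <- !is.finite(frame)
  f <- frame
  if (any(bad)) {
    fill <- mean(frame[!bad])
    if (!is.finite(fill)) fill <- 0
    f[bad] <- fill
  }
  lm <- oracle_local_mean(f, params$block_size)
  act <- f > lm + params$offset
  act[bad] <- FALSE
  act
}

# Erosion/dilation with a diamond element; out-of-frame neighbours ignored.
oracle_erode <- function(m, radius) {
  if (radius == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    keep <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (abs(di) + abs(dj) > radius) next
      qi <- i + di; qj <- j + dj
      if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
      if (!m[qi, qj]) keep <- FALSE
    }
    out[i, j] <- keep
  }
  out
}

oracle_dilate <- function(m, radius) {
  if (radius == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (abs(di) + abs(dj) > radius) next
      qi <- i + di; qj <- j + dj
      if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
      if (m[qi, qj]) hit <- TRUE
    }
    out[i, j] <- hit
  }
  out
}

oracle_clean <- function(m, params) {
  opened <- oracle_dilate(oracle_erode(m, params$open_radius),
                          params$open_radius)
  oracle_erode(oracle_dilate(opened, params$close_radius),
               params$close_radius)
}

# Connected components by iterated min-label propagation (a different
# algorithm from the package's flood fill).
oracle_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      best <- lab[i, j]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (connectivity == 4 && abs(di) + abs(dj) > 1) next
        qi <- i + di; qj <- j + dj
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && lab[qi, qj] < best) best <- lab[qi, qj]
      }
      if (best < lab[i, j]) {
        lab[i, j] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # renumber compactly
  ids <- sort(unique(lab[lab > 0]))
  for (k in seq_along(ids)) lab[lab == ids[k]] <- k
  lab
}

# Full from-definition ROI detector.
oracle_detect_rois <- function(dff, params, frames = "post") {
  idx <- if (frames == "post") which(dff$timestamps > 0) else
    seq_along(dff$timestamps)
  d <- dim(dff$values)
  occ <- matrix(0, d[2], d[3])
  for (f in idx) {
    occ <- occ + oracle_clean(oracle_binarize(dff$values[f, , ], params),
                              params)
  }
  occ <- occ / length(idx)
  support <- occ >= params$occupancy_min & occ > 0
  lab <- oracle_components(support, params$connectivity)
  max_area <- if (is.null(params$max_area)) floor(d[2] * d[3] / 4) else
    params$max_area
  rois <- list()
  for (l in seq_len(max(lab, 0))) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < params$min_area || nrow(px) > max_area) next
    rois[[length(rois) + 1]] <- list(
      pixels = unname(px),
      centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
      area = nrow(px))
  }
  if (length(rois)) {
    ord <- order(sapply(rois, function(r) r$centroid[1]),
                 sapply(rois, function(r) r$centroid[2]))
    rois <- rois[ord]
    for (i in seq_along(rois)) rois[[i]]$id <- i
  }
  rois
}

# Reference interval binning written independently of bin_series():
# interval k covers ((k-1)w, kw]; kept iff inside the recorded span
# (frame centres +/- half a period).
# A bin is complete when it holds (nearly) the full complement of frames
# for its width at the recording's frame period.
bin_series_ref <- function(values, ts, width) {
  dt <- if (length(ts) > 1) ts[2] - ts[1] else width
  ks <- unique(ceiling(ts / width))
  full <- sapply(ks, function(k)
    sum(ts > (k - 1) * width & ts <= k * width)) >= width / dt - 0.5
  sapply(sort(ks[full]), function(k)
    mean(values[ts > (k - 1) * width & ts <= k * width]))
}

# Textbook repeated-measures sums of squares via explicit double sums.
oracle_rm_ss <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ss_total <- 0; ss_subject <- 0; ss_time <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_total <- ss_total + (x[i, j] - grand)^2
  }
  for (i in seq_len(n)) ss_subject <- ss_subject + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ss_time <- ss_time + n * (mean(x[, j]) - grand)^2
  c(total = ss_total, subject = ss_subject, time = ss_time,
    error = ss_total - ss_subject - ss_time)
}
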