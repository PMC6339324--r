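# Fixture builders and independent oracles used across the suite.

cal1 <- function() Calibration(pixelSizeXY = 1, sliceSpacingZ = 1)

# logical disk mask of radius r centred in a (2*r + margin) square
makeDisk <- function(r, margin = 10L, size = NULL) {
  n <- if (is.null(size)) as.integer(2 * r + margin) else as.integer(size)
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(rr, cc) (rr - ctr)^2 + (cc - ctr)^2 <= r^2)
}

# logical ellipse mask with semi-axes a, b rotated by theta (radians)
makeEllipse <- function(a, b, theta = 0, margin = 10L) {
  n <- as.integer(2 * max(a, b) + margin)
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(rr, cc) {
    dr <- rr - ctr; dc <- cc - ctr
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

# sum of isotropic Gaussian bumps; peaks: matrix with rows (r0, c0, height, sigma)
makeBlobImage <- function(n, peaks) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(peaks))) {
    img <- img + peaks[i, 3] *
      outer(seq_len(n), seq_len(n), function(r, c)
        exp(-((r - peaks[i, 1])^2 + (c - peaks[i, 2])^2) / (2 * peaks[i, 4]^2)))
  }
  img
}

# --- independent oracles -------------------------------------------------

# SD projection oracle via apply()/sd(), independent of the package's
# vectorised implementation
oracleSdProjection <- function(vox) apply(vox, c(1, 2), stats::sd)

# Grayscale opening with a ball structuring function, plain R shifts;
# independent of the compiled morphology.
oracleBallOpening <- function(img, rPx) {
  ri <- floor(rPx)
  offs <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rPx^2, ]
  offs$h <- sqrt(rPx^2 - offs$dr^2 - offs$dc^2)
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
  }
  ero <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(offs)))
    ero <- pmin(ero, shift(img, offs$dr[i], offs$dc[i], Inf) - offs$h[i])
  dil <- matrix(-Inf, nr, nc)
  for (i in seq_len(nrow(offs)))
    dil <- pmax(dil, shift(ero, offs$dr[i], offs$dc[i], -Inf) + offs$h[i])
  dil
}

# Marker-based watershed oracle: a pixel belongs to the seed reachable along
# the path minimising the maximum of the inverted image (minimax / highest
# saddle criterion). Returns the basin label per pixel plus the margin
# between the best and second-best seed; pixels with ~zero margin are on the
# watershed line and excluded from comparisons. O(n^2) scan Dijkstra --
# fixtures must stay small.
oracleWatershedMinimax <- function(img, seedIdx) {
  inv <- max(img) - img
  n <- length(inv)
  nr <- nrow(inv)
  nc <- ncol(inv)
  nbOff <- expand.grid(dr = -1:1, dc = -1:1)
  nbOff <- nbOff[!(nbOff$dr == 0 & nbOff$dc == 0), ]
  dists <- matrix(Inf, n, length(seedIdx))
  for (s in seq_along(seedIdx)) {
    dist <- rep(Inf, n)
    done <- rep(FALSE, n)
    dist[seedIdx[s]] <- inv[seedIdx[s]]
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      ur <- (u - 1) %% nr + 1
      uc <- (u - 1) %/% nr + 1
      for (k in seq_len(nrow(nbOff))) {
        vr <- ur + nbOff$dr[k]; vc <- uc + nbOff$dc[k]
        if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
        v <- vr + (vc - 1) * nr
        nd <- max(dist[u], inv[v])
        if (nd < dist[v]) dist[v] <- nd
      }
    }
    dists[, s] <- dist
  }
  best <- apply(dists, 1, which.min)
  srt <- apply(dists, 1, sort)
  margin <- srt[2, ] - srt[1, ]
  list(label = matrix(best, nr, nc), margin = matrix(margin, nr, nc))
}

# random label mask of a few rectangles for evaluation property tests
randomLabelMask <- function(n = 64L, k = 4L, seed = 1L) {
  set.seed(seed)
  lab <- matrix(0L, n, n)
  for (i in seq_len(k)) {
    w <- sample(6:14, 2)
    r0 <- sample(seq_len(n - w[1]), 1)
    c0 <- sample(seq_len(n - w[2]), 1)
    lab[r0:(r0 + w[1]), c0:(c0 + w[2])] <- i
  }
  # relabel to consecutive ids in case of total occlusion
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  LabelMask(lab, cal1())
}
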