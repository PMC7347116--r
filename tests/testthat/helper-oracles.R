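# Independent oracle implementations used to cross-check the package's
# compiled primitives. These deliberately share no code with the
# implementation under test.

# Even-odd point-in-polygon with boundary counted as inside: plain R
# crossing-count per query point.
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  on_boundary <- FALSE
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- i %% n + 1
    xa <- poly[i, 1]; ya <- poly[i, 2]
    xb <- poly[j, 1]; yb <- poly[j, 2]
    cross <- (xb - xa) * (y - ya) - (yb - ya) * (x - xa)
    if (abs(cross) < 1e-9 &&
        x >= min(xa, xb) - 1e-9 && x <= max(xa, xb) + 1e-9 &&
        y >= min(ya, yb) - 1e-9 && y <= max(ya, yb) + 1e-9)
      on_boundary <- TRUE
    if ((ya > y) != (yb > y)) {
      xint <- xa + (y - ya) / (yb - ya) * (xb - xa)
      if (x < xint) inside <- !inside
    }
  }
  on_boundary || inside
}

# Brute-force rasterization: scan every pixel center.
oracle_rasterize <- function(poly, H, W) {
  m <- matrix(0L, H, W)
  for (yy in 0:(H - 1))
    for (xx in 0:(W - 1))
      if (oracle_point_in_polygon(xx, yy, poly)) m[yy + 1, xx + 1] <- 1L
  m
}

# Polygon area by fan triangulation from the first vertex (signed triangle
# cross products), independent of the shoelace path in the package.
oracle_polygon_area <- function(poly) {
  poly <- unname(as.matrix(poly))
  n <- nrow(poly)
  if (n < 3) return(0)
  s <- 0
  for (i in 2:(n - 1)) {
    ax <- poly[i, 1] - poly[1, 1]; ay <- poly[i, 2] - poly[1, 2]
    bx <- poly[i + 1, 1] - poly[1, 1]; by <- poly[i + 1, 2] - poly[1, 2]
    s <- s + (ax * by - ay * bx) / 2
  }
  abs(s)
}

# Plain R flood-fill connected-component labelling.
oracle_label <- function(bin, connectivity = 8) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  nb <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (bin[r, c] == 0 || lab[r, c] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            bin[rr, cc] != 0 && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive maximum one-to-one matching size over candidate pairs
# (detection i, annotation j); used to check the greedy matcher on small
# instances.
oracle_max_matching <- function(pairs, nd, na) {
  if (nrow(pairs) == 0) return(0L)
  best <- 0L
  rec <- function(k, used_d, used_a, size) {
    best <<- max(best, size)
    if (k > nrow(pairs)) return(invisible())
    rec(k + 1, used_d, used_a, size)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_d[i] && !used_a[j]) {
      used_d[i] <- TRUE; used_a[j] <- TRUE
      rec(k + 1, used_d, used_a, size + 1L)
    }
  }
  rec(1L, logical(nd), logical(na), 0L)
  best
}

# Fill interior holes: background 4-components not reachable from the
# border become foreground. Keeps test blobs simply connected, the domain
# over which the area <= pixel-count invariant is stated.
fill_holes <- function(m) {
  bg <- oracle_label(1L - m, 4)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labs <- border_labs[border_labs > 0]
  m[bg > 0 & !(bg %in% border_labs)] <- 1L
  m
}

# A simply-connected random blob: union of chained disks stamped onto a
# grid (connected by construction), holes filled.
random_blob <- function(H = 40, W = 40, n_disks = 4, rmax = 6) {
  m <- matrix(0L, H, W)
  cx <- runif(1, rmax, W - 1 - rmax)
  cy <- runif(1, rmax, H - 1 - rmax)
  for (k in seq_len(n_disks)) {
    r <- runif(1, 1, rmax)
    for (yy in max(0, floor(cy - r)):min(H - 1, ceiling(cy + r)))
      for (xx in max(0, floor(cx - r)):min(W - 1, ceiling(cx + r)))
        if ((xx - cx)^2 + (yy - cy)^2 <= r^2) m[yy + 1, xx + 1] <- 1L
    ang <- runif(1, 0, 2 * pi)
    step <- runif(1, 0, 0.9 * r)
    cx <- min(max(cx + step * cos(ang), 1), W - 2)
    cy <- min(max(cy + step * sin(ang), 1), H - 2)
  }
  fill_holes(m)
}

# Small fixtures shared across tests.
tiny_scene <- function(seed = 11, ...) {
  generate_scene(scene_config(image_shape = c(96L, 96L),
                              n_mononucleated = 10L, n_mng = 2L,
                              seed = seed, ...))
}

tiny_net_config <- function(epochs = 2L, seed = 42L) {
  network_config(input_size = 32L, depth = 2L, base_filters = 4L,
                 epochs = epochs, learning_rate = 1e-3, seed = seed)
}

constant_model <- function(value, input_size = 32L, depth = 2L) {
  # a model whose sigmoid head always outputs `value` (0 < value < 1):
  # zero weights everywhere and a head bias at the logit of `value`
  cfg <- network_config(input_size = input_size, depth = depth,
                        base_filters = 2L, epochs = 1L, seed = 1L)
  m <- build_unet(cfg)
  m$params <- lapply(m$params, function(l)
    list(W = l$W * 0, b = l$b * 0))
  nl <- length(m$params)
  m$params[[nl]]$b <- log(value / (1 - value))
  structure(list(epoch = 1L, params = m$params, loss = NA_real_,
                 config = cfg), class = "unet_checkpoint")
}
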