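# Independent brute-force oracles. These deliberately use different
# algorithms / traversals from the package implementation: naive per-pixel
# loops, vertical-ray point-in-polygon, explicit double sums.

# even-odd point-in-polygon via a vertical (upward) ray, one pixel at a time
oracle_polygon_mask <- function(poly, shape) {
  nr <- shape[1]; nc <- shape[2]
  m <- matrix(FALSE, nr, nc)
  n <- nrow(poly)
  for (row in seq_len(nr)) {
    for (col in seq_len(nc)) {
      px <- col - 1; py <- row - 1
      cnt <- 0L
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        x1 <- poly[i, 1]; y1 <- poly[i, 2]
        x2 <- poly[j, 1]; y2 <- poly[j, 2]
        if (x1 == x2) next
        if ((x1 <= px && px < x2) || (x2 <= px && px < x1)) {
          yc <- y1 + (px - x1) * (y2 - y1) / (x2 - x1)
          if (yc > py) cnt <- cnt + 1L
        }
      }
      m[row, col] <- (cnt %% 2L) == 1L
    }
  }
  m
}

oracle_first_order <- function(levels, n_levels) {
  x <- levels[!is.na(levels)]
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  if (v == 0) return(c(variance = 0, skewness = 0, kurtosis = 0, entropy = 0))
  h <- vapply(seq_len(n_levels), function(l) sum(x == l), numeric(1)) / n
  ent <- 0
  for (p in h) if (p > 0) ent <- ent - p * log2(p)
  c(variance = v,
    skewness = sum((x - mu)^3) / n / v^1.5,
    kurtosis = sum((x - mu)^4) / n / v^2 - 3,
    entropy = ent)
}

# offsets as in the package: degrees -> (d_row, d_col), rows grow downwards
oracle_offsets <- list(`0` = c(0, 1), `45` = c(-1, 1),
                       `90` = c(-1, 0), `135` = c(-1, -1))

oracle_glcm <- function(levels, ng, directions, distance = 1) {
  d <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (k in seq_len(d[3])) {
    for (dir in directions) {
      off <- oracle_offsets[[as.character(dir)]] * distance
      for (r in seq_len(d[1])) {
        for (c in seq_len(d[2])) {
          r2 <- r + off[1]; c2 <- c + off[2]
          if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
          a <- levels[r, c, k]; b <- levels[r2, c2, k]
          if (is.na(a) || is.na(b)) next
          counts[a, b] <- counts[a, b] + 1
          counts[b, a] <- counts[b, a] + 1   # symmetric accumulation
        }
      }
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  contrast <- energy <- homog <- 0
  mu_x <- mu_y <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    contrast <- contrast + (i - j)^2 * P[i, j]
    energy <- energy + P[i, j]^2
    homog <- homog + P[i, j] / (1 + abs(i - j))
    mu_x <- mu_x + i * P[i, j]
    mu_y <- mu_y + j * P[i, j]
  }
  sx <- sy <- covar <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    sx <- sx + (i - mu_x)^2 * P[i, j]
    sy <- sy + (j - mu_y)^2 * P[i, j]
    covar <- covar + (i - mu_x) * (j - mu_y) * P[i, j]
  }
  corr <- if (sx * sy == 0) 1 else covar / sqrt(sx * sy)
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog)
}

# walk every scan line pixel by pixel, flushing runs at NA / change of level
oracle_glrlm <- function(levels, ng, directions) {
  d <- dim(levels)
  runs <- list()
  add_line <- function(vals) {
    cur <- NA; len <- 0
    for (v in c(vals, NA)) {   # trailing NA flushes the final run
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur) && len > 0) runs[[length(runs) + 1]] <<- c(cur, len)
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
    }
  }
  for (k in seq_len(d[3])) {
    sl <- levels[, , k, drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, d[1], d[2])
    for (dir in as.character(directions)) {
      if (dir == "0") {
        for (r in seq_len(d[1])) add_line(sl[r, ])
      } else if (dir == "90") {
        for (c in seq_len(d[2])) add_line(sl[, c])
      } else if (dir == "45") {      # up-right: row decreases, col increases
        for (s in (1 + 1):(d[1] + d[2])) {
          rs <- intersect(seq_len(d[1]), s - seq_len(d[2]))
          add_line(vapply(sort(rs, decreasing = TRUE),
                          function(r) sl[r, s - r], numeric(1)))
        }
      } else if (dir == "135") {     # down-right: both increase
        for (s in (1 - d[1]):(d[2] - 1)) {
          rs <- intersect(seq_len(d[1]), seq_len(d[2]) - s)
          add_line(vapply(sort(rs), function(r) sl[r, r + s], numeric(1)))
        }
      }
    }
  }
  jmax <- max(vapply(runs, `[`, numeric(1), 2), 1)
  p <- matrix(0, ng, jmax)
  for (rn in runs) p[rn[1], rn[2]] <- p[rn[1], rn[2]] + 1
  p
}

oracle_glrlm_features <- function(p, N_r, N_p) {
  ng <- nrow(p); jm <- ncol(p)
  out <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = N_r / N_p, LGRE = 0,
           HGRE = 0, SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0)
  for (i in seq_len(ng)) for (j in seq_len(jm)) {
    pij <- p[i, j]
    out["SRE"] <- out["SRE"] + pij / j^2
    out["LRE"] <- out["LRE"] + pij * j^2
    out["LGRE"] <- out["LGRE"] + pij / i^2
    out["HGRE"] <- out["HGRE"] + pij * i^2
    out["SRLGE"] <- out["SRLGE"] + pij / (i^2 * j^2)
    out["SRHGE"] <- out["SRHGE"] + pij * i^2 / j^2
    out["LRLGE"] <- out["LRLGE"] + pij * j^2 / i^2
    out["LRHGE"] <- out["LRHGE"] + pij * i^2 * j^2
  }
  for (i in seq_len(ng)) out["GLN"] <- out["GLN"] + sum(p[i, ])^2
  for (j in seq_len(jm)) out["RLN"] <- out["RLN"] + sum(p[, j])^2
  idx <- c("SRE", "LRE", "GLN", "RLN", "LGRE", "HGRE", "SRLGE", "SRHGE",
           "LRLGE", "LRHGE")
  out[idx] <- out[idx] / N_r
  out
}

# all 19 features of a quantized level array, via the oracles only
oracle_all_features <- function(levels, ng, directions = c("0", "45", "90", "135")) {
  P <- oracle_glcm(levels, ng, directions)
  p <- oracle_glrlm(levels, ng, directions)
  n_masked <- sum(!is.na(levels))
  c(oracle_first_order(levels, ng),
    oracle_glcm_features(P),
    oracle_glrlm_features(p, sum(p), n_masked * length(directions)))
}

# build a quantized_roi object directly from a level array (NA = unmasked)
qroi_from_levels <- function(levels, ng) {
  if (length(dim(levels)) == 2) levels <- array(levels, c(dim(levels), 1))
  structure(list(levels = levels, mask = !is.na(levels),
                 n_levels = as.integer(ng),
                 n_masked_pixels = sum(!is.na(levels))),
            class = "quantized_roi")
}

package_all_features <- function(levels, ng, directions = c("0", "45", "90", "135")) {
  q <- qroi_from_levels(levels, ng)
  c(first_order_features(q),
    glcm_features(compute_glcm(q, 1, directions)),
    glrlm_features(compute_glrlm(q, directions)))
}
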