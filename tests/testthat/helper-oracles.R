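# Independent brute-force oracles, deliberately written as plain R loops
# over cells so they share no code path with the package implementation.

# flood-fill connected components of same-class cells (class > 0)
oracle_label <- function(cls, connectivity = 8) {
  nr <- nrow(cls); nc <- ncol(cls)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- cls[r, c]
    if (is.na(v) || v <= 0 || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      rc <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        r2 <- rc[1] + nbrs[k, 1]; c2 <- rc[2] + nbrs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        v2 <- cls[r2, c2]
        if (!is.na(v2) && v2 == v && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# partition of cell indices by label, as a canonical set-of-sets signature
label_partition <- function(lab) {
  grp <- split(which(lab > 0), lab[lab > 0])
  unname(grp[order(vapply(grp, min, 1L))])
}

# total heterogeneous 4-adjacent pairs by class pair, and per-class-pair
# face counts; excludes NA neighbours and the grid boundary
oracle_edge_faces <- function(cls) {
  nr <- nrow(cls); nc <- ncol(cls)
  out <- list()
  add <- function(out, a, b) {
    key <- paste(min(a, b), max(a, b))
    out[[key]] <- (out[[key]] %||% 0L) + 1L
    out
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- cls[r, c]
    if (is.na(v)) next
    if (r < nr && !is.na(cls[r + 1, c]) && cls[r + 1, c] != v)
      out <- add(out, v, cls[r + 1, c])
    if (c < nc && !is.na(cls[r, c + 1]) && cls[r, c + 1] != v)
      out <- add(out, v, cls[r, c + 1])
  }
  out
}

oracle_total_edge_faces <- function(cls, include_background = TRUE) {
  f <- oracle_edge_faces(cls)
  if (!include_background)
    f <- f[!grepl("^0 ", names(f))]
  sum(unlist(f))
}

# per-patch perimeter in faces (faces to out-of-grid, NA, or other label)
oracle_perimeter <- function(lab, id) {
  nr <- nrow(lab); nc <- ncol(lab)
  per <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lab[r, c] != id) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) per <- per + 1L
      else if (lab[r2, c2] != id) per <- per + 1L
    }
  }
  per
}

# nodata-aware oracle perimeter needs the class map to distinguish NA cells;
# here "other label" covers background (lab 0) and NA cells both have lab 0.

# full set-B oracle on a class map of {NA,0,1}
oracle_metrics_b <- function(cls, cell_size) {
  lab <- oracle_label(cls, 8)
  np <- max(lab)
  area_cells <- tabulate(lab[lab > 0], np)
  a_m2 <- area_cells * cell_size^2
  per_m <- vapply(seq_len(np), function(i) oracle_perimeter(lab, i),
                  1L) * cell_size
  frac <- 2 * log(0.25 * per_m) / log(a_m2)
  frac[a_m2 == 1] <- NA
  te <- oracle_total_edge_faces(cls) * cell_size
  area_land <- sum(!is.na(cls)) * cell_size^2
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  list(NP = np, AREA.MN = mean(a_m2) / 1e4, AREA.SD = sdp(a_m2 / 1e4),
       ED = te / (area_land / 1e4), TE = te,
       FRAC.MN = mean(frac, na.rm = TRUE),
       FRAC.SD = sdp(frac[!is.na(frac)]))
}

# set-C oracle: height-class map with classes 1..m, background 0
oracle_metrics_c <- function(cls, cell_size, contrast) {
  lab <- oracle_label(cls, 8)
  np <- max(lab)
  area_cells <- tabulate(lab[lab > 0], np)
  a_m2 <- area_cells * cell_size^2
  per_m <- vapply(seq_len(np), function(i) oracle_perimeter(lab, i),
                  1L) * cell_size
  frac <- 2 * log(0.25 * per_m) / log(a_m2)
  frac[a_m2 == 1] <- NA
  nr <- nrow(cls); nc <- ncol(cls)
  te <- 0; wte <- 0
  elen <- rep(0, np); edep <- rep(0, np)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- cls[r, c]
    if (is.na(v)) next
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc) next
      v2 <- cls[r2, c2]
      if (is.na(v2) || v2 == v) next
      dep <- contrast[v + 1, v2 + 1]
      te <- te + cell_size
      wte <- wte + dep * cell_size
      if (v > 0) {
        id <- lab[r, c]
        elen[id] <- elen[id] + cell_size; edep[id] <- edep[id] + dep * cell_size
      }
      if (v2 > 0) {
        id <- lab[r2, c2]
        elen[id] <- elen[id] + cell_size; edep[id] <- edep[id] + dep * cell_size
      }
    }
  }
  econ <- ifelse(elen > 0, edep / elen, NA)
  cls_of <- vapply(seq_len(np), function(i) cls[which(lab == i)[1]], 1L)
  parea <- tapply(a_m2, cls_of, sum)
  pp <- parea / sum(parea)
  area_land <- sum(!is.na(cls)) * cell_size^2
  sdp <- function(x) { x <- x[!is.na(x)]; sqrt(mean((x - mean(x))^2)) }
  list(NP = np, AREA.MN = mean(a_m2) / 1e4, AREA.SD = sdp(a_m2 / 1e4),
       TE = te, FRAC.MN = mean(frac, na.rm = TRUE), FRAC.SD = sdp(frac),
       CWED = wte / (area_land / 1e4),
       ECON.MN = mean(econ, na.rm = TRUE), ECON.SD = sdp(econ),
       SHDI = -sum(pp * log(pp)))
}

# exhaustive-pair GLCM oracle
oracle_glcm <- function(g, offsets, levels, symmetric = TRUE) {
  P <- matrix(0, levels, levels)
  nr <- nrow(g); nc <- ncol(g)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- g[r, c]; b <- g[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
      if (symmetric) P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
    }
  }
  P / sum(P)
}

# naive double-sum texture statistics
oracle_texture <- function(P) {
  g <- nrow(P)
  ent <- 0; con <- 0; asm <- 0; hom <- 0; dis <- 0
  for (i in seq_len(g)) for (j in seq_len(g)) {
    p <- P[i, j]
    if (p > 0) ent <- ent - p * log(p)
    con <- con + (i - j)^2 * p
    asm <- asm + p^2
    hom <- hom + p / (1 + (i - j)^2)
    dis <- dis + abs(i - j) * p
  }
  c(ENTROPY = ent, CONTRAST = con, ASM = asm, HOMOGENEITY = hom,
    DISSIMILARITY = dis)
}

# Moran's I with rook-adjacency binary weights
oracle_moran <- function(m) {
  ok <- !is.na(m)
  mu <- mean(m[ok])
  z <- m - mu
  num <- 0; W <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(m[r, c])) next
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc || is.na(m[r2, c2])) next
      num <- num + 2 * z[r, c] * z[r2, c2]
      W <- W + 2
    }
  }
  n <- sum(ok)
  (n / W) * num / sum(z[ok]^2)
}

# random class map generator for property batteries
random_class_map <- function(nr, nc, n_class, p_bg = 0.3, p_na = 0.05) {
  v <- sample(0:n_class, nr * nc, replace = TRUE,
              prob = c(p_bg, rep((1 - p_bg) / n_class, n_class)))
  v[stats::runif(nr * nc) < p_na] <- NA
  matrix(as.integer(v), nr, nc)
}

# wrap a numeric matrix as a window with given cell size
make_window <- function(m, cell_size = 30) {
  as_window(height_raster(m, cell_size = cell_size))
}

# turn a class matrix into a height_class_map-compatible object by building
# heights that classify back to it (for feeding package functions)
heights_from_classes <- function(cls, thresholds = c(5, 10, 15, 25)) {
  mids <- c(2.5, 7.5, 12.5, 20, 30)
  h <- matrix(0, nrow(cls), ncol(cls))
  h[!is.na(cls) & cls > 0] <- mids[cls[!is.na(cls) & cls > 0]]
  h[is.na(cls)] <- NA
  h
}
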