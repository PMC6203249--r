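# Finite-volume discretization: non-uniform tensor-product Cartesian grids.
#
# The fine region (uniform spacing = the geometry's `resolution`) covers the
# cavity / reactive surface; cell widths then grow geometrically toward the
# far-field boundary. Cells are classified solvent / solid / bulk(Dirichlet)
# by their centers; all face lists needed for assembly are precomputed here so
# that paired solves (with and without binding sites) share the identical
# discretization and their truncation errors cancel in rate ratios.

graded_widths <- function(h0, extent, ratio) {
  if (extent <= 0) return(numeric(0))
  w <- numeric(0); x <- 0; h <- h0
  while (x < extent) { h <- h * ratio; w <- c(w, h); x <- x + h }
  w
}

# Edges from 0: n_fine uniform cells of width h, then geometric growth to at
# least `outer`. Returns the positive edge vector starting at 0.
axis_half <- function(h, fine, outer, ratio) {
  nf <- max(1L, ceiling(fine / h))
  e <- seq(0, nf * h, length.out = nf + 1)
  ext <- outer - e[length(e)]
  if (ext > 0) e <- c(e, e[length(e)] + cumsum(graded_widths(h, ext, ratio)))
  e
}

axis_sym <- function(h, fine, outer, ratio) {
  e <- axis_half(h, fine, outer, ratio)
  c(-rev(e[-1]), e)
}

# Axis with exact fit of a landmark L (e.g. the lumen height): uniform cells
# of width ~h from 0 to L, a short uniform pad above, then geometric growth.
axis_landmark <- function(h, L, pad_cells, outer, ratio) {
  n1 <- max(1L, round(L / h))
  hz <- L / n1
  e <- seq(0, L + pad_cells * hz, length.out = n1 + pad_cells + 1)
  ext <- outer - e[length(e)]
  if (ext > 0) e <- c(e, e[length(e)] + cumsum(graded_widths(hz, ext, ratio)))
  e
}

# Build the full discretization of a geometry. `sites` only matter at solve
# time (through the potential); the grid itself is site-independent.
discretize <- function(geom, resolution = NULL, bulk_radius = NULL,
                       grade_ratio = 1.35) {
  h <- resolution %||% geom$resolution
  Rb <- bulk_radius %||% geom$bulk_radius
  if (geom$kind == "cylinder") {
    H <- geom$lumen_height; r_in <- geom$lumen_radius
    xe <- axis_sym(h, r_in + 2 * h, Rb + 2 * h, grade_ratio)
    ye <- xe
    ze <- axis_landmark(h, H, 3L, H + Rb + 2 * h, grade_ratio)
    bulk_center <- c(0, 0, H)
  } else if (geom$kind == "sphere") {
    a <- geom$radius
    if (geom$octant) {
      xe <- axis_half(h, a + 2 * h, Rb + 2 * h, grade_ratio)
    } else {
      xe <- axis_sym(h, a + 2 * h, Rb + 2 * h, grade_ratio)
    }
    ye <- ze <- xe
    bulk_center <- c(0, 0, 0)
  } else if (geom$kind == "mesh") {
    v <- geom$mesh$vertices
    ctr <- geom$center
    mk <- function(ax) {
      lo <- min(v[, ax]) - 2 * h; hi <- max(v[, ax]) + 2 * h
      nf <- ceiling((hi - lo) / h)
      e <- seq(lo, hi, length.out = nf + 1)
      lo_ext <- (Rb + 2 * h) - (ctr[ax] - lo)
      hi_ext <- (Rb + 2 * h) - (hi - ctr[ax])
      if (lo_ext > 0) e <- c(lo - rev(cumsum(graded_widths(h, lo_ext, grade_ratio))), e)
      if (hi_ext > 0) e <- c(e, hi + cumsum(graded_widths(h, hi_ext, grade_ratio)))
      e
    }
    xe <- mk(1); ye <- mk(2); ze <- mk(3)
    bulk_center <- ctr
  } else stop("unknown geometry kind: ", geom$kind)

  xc <- (utils::head(xe, -1) + utils::tail(xe, -1)) / 2; dxv <- diff(xe)
  yc <- (utils::head(ye, -1) + utils::tail(ye, -1)) / 2; dyv <- diff(ye)
  zc <- (utils::head(ze, -1) + utils::tail(ze, -1)) / 2; dzv <- diff(ze)
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  dims <- c(nx, ny, nz)
  X <- array(rep(xc, ny * nz), dims)
  Y <- array(rep(rep(yc, each = nx), nz), dims)
  Z <- array(rep(zc, each = nx * ny), dims)
  DX <- array(rep(dxv, ny * nz), dims)
  DY <- array(rep(rep(dyv, each = nx), nz), dims)
  DZ <- array(rep(dzv, each = nx * ny), dims)

  type <- array(0L, dims)
  cat_faces <- NULL
  if (geom$kind == "cylinder") {
    R2 <- X^2 + Y^2
    type[Z < geom$lumen_height & R2 > geom$lumen_radius^2] <- 1L
    bd2 <- R2 + (Z - bulk_center[3])^2
    type[type == 0L & bd2 > Rb^2] <- 2L
  } else if (geom$kind == "sphere") {
    R2 <- X^2 + Y^2 + Z^2
    type[R2 < geom$radius^2] <- 1L
    type[type == 0L & R2 > Rb^2] <- 2L
  } else {
    inside <- voxelize_mesh(geom$mesh, xc, yc, zc)
    type[inside] <- 1L
    d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2
    type[type == 0L & d2 > Rb^2] <- 2L
  }

  sol <- which(type == 0L)
  idx <- array(0L, dims); idx[sol] <- seq_along(sol)
  n <- length(sol)

  shift_up <- function(A, ax) {
    if (ax == 1) A[c(2:nx, NA), , , drop = FALSE]
    else if (ax == 2) A[, c(2:ny, NA), , drop = FALSE]
    else A[, , c(2:nz, NA), drop = FALSE]
  }

  fp <- fq <- integer(0); fcp <- fcq <- integer(0)
  fA <- fdP <- fdQ <- numeric(0)
  bp <- integer(0); bcp <- integer(0); bA <- bdP <- bdQ <- numeric(0)
  sp <- integer(0); scp <- integer(0); sA <- sdP <- numeric(0) # solid-adjacent
  cell_lin <- array(seq_len(prod(dims)), dims)
  for (ax in 1:3) {
    tQ <- shift_up(type, ax)
    dP <- list(DX, DY, DZ)[[ax]]
    dQ <- shift_up(dP, ax)
    Aface <- switch(ax, DY * DZ, DX * DZ, DX * DY)
    iQ <- shift_up(idx, ax)
    cQ <- shift_up(cell_lin, ax)
    ok <- !is.na(tQ)
    w <- which(ok & type == 0L & tQ == 0L)
    fp <- c(fp, idx[w]); fq <- c(fq, iQ[w])
    fcp <- c(fcp, cell_lin[w]); fcq <- c(fcq, cQ[w])
    fA <- c(fA, Aface[w]); fdP <- c(fdP, dP[w] / 2); fdQ <- c(fdQ, dQ[w] / 2)
    w1 <- which(ok & type == 0L & tQ == 2L)
    w2 <- which(ok & type == 2L & tQ == 0L)
    bp <- c(bp, idx[w1], iQ[w2]); bcp <- c(bcp, cell_lin[w1], cQ[w2])
    bA <- c(bA, Aface[w1], Aface[w2])
    bdP <- c(bdP, dP[w1] / 2, dQ[w2] / 2)
    bdQ <- c(bdQ, dQ[w1] / 2, dP[w2] / 2)
    w1 <- which(ok & type == 0L & tQ == 1L)
    w2 <- which(ok & type == 1L & tQ == 0L)
    sp <- c(sp, idx[w1], iQ[w2]); scp <- c(scp, cell_lin[w1], cQ[w2])
    sA <- c(sA, Aface[w1], Aface[w2])
    sdP <- c(sdP, dP[w1] / 2, dQ[w2] / 2)
  }

  # catalytic faces
  mult <- 1
  if (geom$kind == "cylinder") {
    # bottom boundary faces of the first cell layer, inside the disk
    lay <- which(type[, , 1] == 0L &
                   (X[, , 1]^2 + Y[, , 1]^2) < geom$catalytic_radius^2)
    ct_p <- idx[, , 1][lay]
    ct_cell <- cell_lin[, , 1][lay]
    ct_A <- (DX[, , 1] * DY[, , 1])[lay]
    ct_d <- (DZ[, , 1] / 2)[lay]
    A_true <- pi * geom$catalytic_radius^2
  } else if (geom$kind == "sphere") {
    ct_p <- sp; ct_cell <- scp; ct_A <- sA; ct_d <- sdP
    sp <- integer(0); scp <- integer(0); sA <- numeric(0); sdP <- numeric(0)
    mult <- if (geom$octant) 8 else 1
    A_true <- 4 * pi * geom$radius^2 / mult
  } else {
    cat_tri <- which(geom$mesh$label == "catalytic")
    if (!length(cat_tri)) stop("mesh geometry has no catalytic faces")
    pts <- cbind(as.vector(X)[scp], as.vector(Y)[scp], as.vector(Z)[scp])
    dmin <- point_tri_mindist(pts, geom$mesh, cat_tri)
    near <- dmin < 1.2 * h
    ct_p <- sp[near]; ct_cell <- scp[near]; ct_A <- sA[near]; ct_d <- sdP[near]
    sp <- sp[!near]; scp <- scp[!near]; sA <- sA[!near]; sdP <- sdP[!near]
    A_true <- sum(mesh_face_areas(geom$mesh)[cat_tri])
    if (!length(ct_p)) stop("refinement error: catalytic patch unresolved ",
                            "(no boundary faces near the tagged triangles)")
  }
  gamma <- A_true / sum(ct_A)

  list(
    geom = geom, h = h, Rb = Rb, dims = dims,
    xe = xe, ye = ye, ze = ze, xc = xc, yc = yc, zc = zc,
    cx = as.vector(X), cy = as.vector(Y), cz = as.vector(Z),
    vol = as.vector(DX * DY * DZ),
    type = type, sol = sol, idx = idx, n = n,
    fp = fp, fq = fq, fcp = fcp, fcq = fcq, fA = fA, fdP = fdP, fdQ = fdQ,
    bp = bp, bcp = bcp, bA = bA, bdP = bdP, bdQ = bdQ,
    ct_p = ct_p, ct_cell = ct_cell, ct_A = ct_A, ct_d = ct_d,
    gamma = gamma, mult = mult, cat_area_true = A_true
  )
}

# Rasterized volume of the solvent cells lying in the lumen (cylinder only);
# used to verify the discretization against the closed-form volume.
grid_lumen_volume <- function(grid) {
  geom <- grid$geom
  stopifnot(geom$kind == "cylinder")
  inlum <- grid$type == 0L &
    grid$cz < geom$lumen_height &
    (grid$cx^2 + grid$cy^2) <= geom$lumen_radius^2
  sum(grid$vol[as.vector(inlum)])
}

# Mark cells whose center lies inside the closed mesh, by ray casting along +z
# with parity counting, column by column.
voxelize_mesh <- function(mesh, xc, yc, zc) {
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  v <- mesh$vertices; f <- mesh$faces
  eps <- c(1.2345e-7, 2.3456e-7) # nudge columns off edges/vertices
  hits_col <- vector("list", nx * ny)
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1], ]; p2 <- v[f[t, 2], ]; p3 <- v[f[t, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- which(xc + eps[1] >= xr[1] & xc + eps[1] <= xr[2])
    iy <- which(yc + eps[2] >= yr[1] & yc + eps[2] <= yr[2])
    if (!length(ix) || !length(iy)) next
    px <- rep(xc[ix] + eps[1], length(iy))
    py <- rep(yc[iy] + eps[2], each = length(ix))
    d <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(d) < 1e-14) next # triangle vertical to the ray
    w1 <- ((p2[1] - px) * (p3[2] - py) - (p3[1] - px) * (p2[2] - py)) / d
    w2 <- ((p3[1] - px) * (p1[2] - py) - (p1[1] - px) * (p3[2] - py)) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    zhit <- w1[inside] * p1[3] + w2[inside] * p2[3] + w3[inside] * p3[3]
    cols <- (rep(ix, length(iy)))[inside] +
      (rep(iy, each = length(ix))[inside] - 1L) * nx
    for (ii in seq_along(cols)) {
      cid <- cols[ii]
      hits_col[[cid]] <- c(hits_col[[cid]], zhit[ii])
    }
  }
  inside_arr <- array(FALSE, c(nx, ny, nz))
  for (cid in which(lengths(hits_col) > 0)) {
    zh <- sort(hits_col[[cid]])
    if (length(zh) %% 2 != 0) next # grazing ray; leave column as solvent
    i <- ((cid - 1L) %% nx) + 1L
    j <- ((cid - 1L) %/% nx) + 1L
    for (m in seq(1, length(zh), by = 2)) {
      kk <- which(zc > zh[m] & zc < zh[m + 1])
      if (length(kk)) inside_arr[i, j, kk] <- TRUE
    }
  }
  inside_arr
}

# Minimum distance from each point to a set of mesh triangles.
point_tri_mindist <- function(pts, mesh, tri_ix) {
  v <- mesh$vertices; f <- mesh$faces
  dmin <- rep(Inf, nrow(pts))
  for (t in tri_ix) {
    a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; cc <- v[f[t, 3], ]
    ab <- b - a; ac <- cc - a
    nrm <- c(ab[2] * ac[3] - ab[3] * ac[2],
             ab[3] * ac[1] - ab[1] * ac[3],
             ab[1] * ac[2] - ab[2] * ac[1])
    nn <- sum(nrm^2)
    ap <- sweep(pts, 2, a)
    # project onto the triangle plane, then clamp via barycentric coordinates
    dist_plane <- (ap %*% nrm)[, 1] / sqrt(nn)
    proj <- pts - outer(dist_plane, nrm / sqrt(nn))
    apx <- sweep(proj, 2, a)
    d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
    d20 <- apx %*% ab; d21 <- apx %*% ac
    den <- d00 * d11 - d01 * d01
    vv <- (d11 * d20 - d01 * d21) / den
    ww <- (d00 * d21 - d01 * d20) / den
    inside <- vv >= 0 & ww >= 0 & vv + ww <= 1
    dcur <- rep(Inf, nrow(pts))
    dcur[inside] <- abs(dist_plane[inside])
    # edge distances for points projecting outside
    out <- which(!inside)
    if (length(out)) {
      seg_d <- function(p0, p1) {
        e <- p1 - p0
        tt <- pmin(1, pmax(0, (sweep(pts[out, , drop = FALSE], 2, p0) %*% e)[, 1] / sum(e^2)))
        q <- outer(tt, e) + rep(p0, each = length(out))
        sqrt(rowSums((pts[out, , drop = FALSE] - q)^2))
      }
      dcur[out] <- pmin(seg_d(a, b), seg_d(b, cc), seg_d(cc, a))
    }
    dmin <- pmin(dmin, dcur)
  }
  dmin
}
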