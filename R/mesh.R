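# Triangulated molecular surface meshes: OFF / PLY / STL import, validation
# (watertightness, orientation), export with partition labels, and simple
# programmatic builders used for testing and for synthetic enzyme surrogates.
#
# A mesh is a list with `vertices` (n x 3 matrix, A), `faces` (m x 3 integer
# matrix of 1-based vertex indices, counter-clockwise seen from outside) and
# optionally `label` (per-face character: "wall", "catalytic", "bulk").

mesh_face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Signed volume via the divergence theorem; positive for outward orientation.
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Validate a closed, oriented surface mesh
#'
#' Checks that every edge is shared by exactly two faces (watertightness),
#' that the two incident faces traverse the edge in opposite directions
#' (consistent orientation), and that the surface is globally oriented
#' outward (positive enclosed volume).
#'
#' @param mesh A mesh list (`vertices`, `faces`).
#' @return The mesh, invisibly, on success; otherwise an error describing the
#'   open or inconsistently oriented edges.
#' @export
validate_mesh <- function(mesh) {
  f <- mesh$faces
  stopifnot(is.matrix(f), ncol(f) == 3, nrow(f) >= 4)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]) # directed half-edges
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(key)
  if (any(cnt != 2)) {
    open <- names(cnt)[cnt != 2]
    stop("mesh is not watertight: ", length(open),
         " edge(s) not shared by exactly 2 faces (e.g. vertices ",
         paste(utils::head(open, 3), collapse = "; "), ")")
  }
  dkey <- paste(he[, 1], he[, 2])
  if (any(table(dkey) != 1))
    stop("orientation error: some edges are traversed twice in the same ",
         "direction (inconsistent face winding)")
  if (mesh_signed_volume(mesh) <= 0)
    stop("orientation error: surface normals point inward (non-positive ",
         "enclosed volume); flip the face winding")
  invisible(mesh)
}

#' Read a triangulated surface mesh
#'
#' Reads OFF (ASCII), PLY (ASCII or binary little/big endian) or STL (ASCII or
#' binary), inferring the format from the file extension. Quad faces are
#' split into triangles; STL's duplicated corner vertices are merged.
#'
#' @param path Path to the mesh file.
#' @return A mesh list with `vertices` and `faces`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    off = read_off(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop("unsupported mesh format: .", ext, " (expected OFF, PLY or STL)"))
  mesh
}

triangulate_faces <- function(faces_list) {
  out <- lapply(faces_list, function(ix) {
    n <- length(ix)
    if (n < 3) stop("mesh face with fewer than 3 vertices")
    if (n == 3) return(matrix(ix, 1, 3))
    t(vapply(2:(n - 1), function(j) ix[c(1, j, j + 1)], integer(3)))
  })
  do.call(rbind, out)
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  if (!grepl("^OFF", trimws(txt[1]))) stop("not an OFF file: ", path)
  counts <- scan(text = txt[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = paste(txt[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- lapply(txt[(3 + nv):(2 + nv + nf)], function(l) {
    v <- scan(text = l, quiet = TRUE)
    as.integer(v[2:(1 + v[1])]) + 1L
  })
  list(vertices = verts, faces = triangulate_faces(fl))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 500) stop("PLY header not terminated")
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elems <- grep("^element", header)
  get_count <- function(name) {
    l <- grep(paste0("^element ", name), header, value = TRUE)
    if (!length(l)) 0L else as.integer(strsplit(trimws(l[1]), "\\s+")[[1]][3])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  # per-element property lines
  elem_names <- sub("^element (\\w+).*", "\\1", header[elems])
  prop_of <- function(name) {
    i0 <- elems[match(name, elem_names)]
    i1 <- c(elems, grep("^end_header", header))[which(c(elems, grep("^end_header", header)) > i0)][1]
    grep("^property", header[i0:i1], value = TRUE)
  }
  vprops <- strsplit(trimws(prop_of("vertex")), "\\s+")
  fprops <- strsplit(trimws(prop_of("face")), "\\s+")
  ply_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                int32 = 4, uint32 = 4, float = 4, float32 = 4,
                double = 8, float64 = 8)
  read_scalar <- function(type, n, endian) {
    sz <- ply_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = endian)
    else readBin(con, "integer", n = n, size = sz,
                 signed = !(sz < 4 && grepl("^u", type)), endian = endian)
  }
  if (fmt == "ascii") {
    vx <- matrix(scan(con, n = nv * length(vprops), quiet = TRUE),
                 ncol = length(vprops), byrow = TRUE)
    xyz_ix <- match(c("x", "y", "z"), vapply(vprops, `[`, "", 3))
    verts <- vx[, xyz_ix, drop = FALSE]
    fl <- vector("list", nf)
    for (i in seq_len(nf)) {
      cntv <- scan(con, n = 1, quiet = TRUE)
      fl[[i]] <- as.integer(scan(con, n = cntv, quiet = TRUE)) + 1L
      extra <- length(fprops) - 1L
      if (extra > 0) scan(con, n = extra, quiet = TRUE)
    }
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    vtypes <- vapply(vprops, `[`, "", 2)
    vnames <- vapply(vprops, `[`, "", 3)
    verts_all <- matrix(0, nv, length(vtypes))
    for (i in seq_len(nv))
      for (j in seq_along(vtypes))
        verts_all[i, j] <- read_scalar(vtypes[j], 1, endian)
    verts <- verts_all[, match(c("x", "y", "z"), vnames), drop = FALSE]
    fl <- vector("list", nf)
    for (i in seq_len(nf)) {
      for (p in fprops) {
        if (p[2] == "list") {
          cntv <- read_scalar(p[3], 1, endian)
          ix <- read_scalar(p[4], cntv, endian)
          if (p[length(p)] == "vertex_indices" || p[length(p)] == "vertex_index")
            fl[[i]] <- as.integer(ix) + 1L
        } else read_scalar(p[2], 1, endian)
      }
    }
  }
  list(vertices = verts, faces = triangulate_faces(fl))
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 84)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") && {
    txt <- tryCatch(readLines(path, warn = FALSE), error = function(e) "")
    any(grepl("facet", txt))
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    xyz <- matrix(scan(text = gsub("vertex", "", vl), quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    ntri <- readBin(con, "integer", size = 4, endian = "little")
    xyz <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", n = 12, size = 4, endian = "little")
      xyz[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
  }
  # merge duplicated corner vertices
  key <- apply(round(xyz, 9), 1, paste, collapse = ",")
  uix <- !duplicated(key)
  vid <- match(key, key[uix])
  verts <- xyz[uix, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Write a mesh as ASCII PLY with per-face partition labels
#'
#' @param mesh A mesh list; if it has a `label` field, a per-face integer
#'   property `partition` is written (0 wall, 1 catalytic, 2 bulk).
#' @param path Output path.
#' @param sidecar Optional list of parameters written as a JSON sidecar next
#'   to the mesh (same path with `.json` appended).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, sidecar = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  lab <- mesh$label
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               if (!is.null(lab)) "property int partition",
               "end_header"), con)
  writeLines(apply(v, 1, function(r) paste(format(r, digits = 9), collapse = " ")), con)
  code <- if (!is.null(lab)) match(lab, c("wall", "catalytic", "bulk")) - 1L
  face_txt <- paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L,
                    if (!is.null(lab)) code else "")
  writeLines(trimws(face_txt), con)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a molecular surface mesh as an enzyme geometry
#'
#' Imports a closed, consistently oriented surface mesh bounding the enzyme
#' body (solvent lies outside the surface) and tags its faces: faces selected
#' by `catalytic_selection` form the reactive patch, faces selected by
#' `bulk_selection` (rarely used) are held at bulk concentration, and all
#' remaining faces reflect. The far-field boundary is a sphere of
#' `bulk_radius` around the mesh.
#'
#' @param path Mesh file (OFF/PLY/STL), or a mesh list built in code.
#' @param catalytic_selection Either an integer vector of face indices or a
#'   predicate `function(centroids)` returning a logical over faces.
#' @param bulk_selection As `catalytic_selection`, or `NULL` (default:
#'   far-field sphere only).
#' @param resolution Fine-region grid spacing used when solving (A).
#' @param bulk_radius Far-field sphere radius (A); default 3x the mesh
#'   circumradius about its centroid.
#' @return An `enzyme_geometry` of kind `"mesh"`.
#' @export
load_mesh <- function(path, catalytic_selection, bulk_selection = NULL,
                      resolution = 0.5, bulk_radius = NULL) {
  mesh <- if (is.character(path)) read_mesh(path) else path
  validate_mesh(mesh)
  cent <- mesh_face_centroids(mesh)
  pick <- function(sel) {
    if (is.null(sel)) return(rep(FALSE, nrow(mesh$faces)))
    if (is.function(sel)) return(as.logical(sel(cent)))
    seq_len(nrow(mesh$faces)) %in% sel
  }
  is_cat <- pick(catalytic_selection)
  is_bulk <- pick(bulk_selection)
  if (!any(is_cat)) stop("empty catalytic selection: no reactive patch")
  if (any(is_cat & is_bulk)) stop("catalytic and bulk selections overlap")
  mesh$label <- ifelse(is_cat, "catalytic", ifelse(is_bulk, "bulk", "wall"))
  ctr <- colMeans(mesh$vertices)
  circum <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  if (is.null(bulk_radius)) bulk_radius <- 3 * circum
  ar <- mesh_face_areas(mesh)
  cent <- mesh_face_centroids(mesh)
  cat_ctr <- colSums(cent[is_cat, , drop = FALSE] * ar[is_cat]) /
    sum(ar[is_cat])
  structure(list(
    kind = "mesh", mesh = mesh, center = ctr, cat_center = cat_ctr,
    catalytic_radius = NA_real_,
    bulk_radius = bulk_radius, resolution = resolution,
    source = if (is.character(path)) paste0("mesh:", path) else "mesh:<memory>"
  ), class = "enzyme_geometry")
}

#' Icosphere test mesh
#'
#' Subdivided icosahedron approximating a sphere; a standard synthetic test
#' surface.
#'
#' @param radius Sphere radius.
#' @param subdiv Number of 4-fold subdivisions (0 = icosahedron).
#' @param center Center 3-vector.
#' @return A mesh list.
#' @export
build_icosphere <- function(radius = 1, subdiv = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nf * 4, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, `+`)
  list(vertices = v, faces = f)
}

# Triangulated surface of revolution: profile (r_i, z_i) with r >= 0, revolved
# about z in `n_seg` segments. Consecutive profile points with r > 0 generate
# quad strips; points on the axis (r = 0) generate triangle fans. The profile
# must be a closed loop traversed so the outward normal points away from the
# solid (counter-clockwise in the (r, z) half-plane).
revolve_profile <- function(profile, n_seg = 48) {
  np <- nrow(profile)
  on_axis <- profile[, 1] < 1e-12
  idx <- vector("list", np)
  verts <- NULL
  for (i in seq_len(np)) {
    if (on_axis[i]) {
      verts <- rbind(verts, c(0, 0, profile[i, 2]))
      idx[[i]] <- rep(nrow(verts), n_seg)
    } else {
      th <- 2 * pi * (0:(n_seg - 1)) / n_seg
      ring <- cbind(profile[i, 1] * cos(th), profile[i, 1] * sin(th),
                    profile[i, 2])
      idx[[i]] <- nrow(verts %||% matrix(0, 0, 3)) + seq_len(n_seg)
      verts <- rbind(verts, ring)
    }
  }
  faces <- NULL
  ring_id <- NULL
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    ia <- idx[[i]]; ib <- idx[[j]]
    nxt <- c(2:n_seg, 1)
    if (on_axis[i] && on_axis[j]) next
    if (on_axis[i]) {
      tri <- cbind(ia[1], ib, ib[nxt])
    } else if (on_axis[j]) {
      tri <- cbind(ia, ib[1], ia[nxt])
    } else {
      tri <- rbind(cbind(ia, ib, ib[nxt]), cbind(ia, ib[nxt], ia[nxt]))
    }
    faces <- rbind(faces, tri)
    ring_id <- c(ring_id, rep(i, nrow(tri)))
  }
  mesh <- list(vertices = verts, faces = faces, segment = ring_id)
  if (mesh_signed_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  }
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic tunnel-enzyme surface mesh
#'
#' Builds a closed surface of revolution representing a generic tunnel-shaped
#' enzyme lumen of the kind found in acyltransferases: a wide vestibule
#' (where non-native ligands bind in surface-adjacent pockets) opening from
#' the top of the body, connected by a narrow catalytic tunnel to the reactive
#' center buried at its bottom. This is a synthetic stand-in surface used to
#' exercise the mesh import and solver pipeline; it is not derived from any
#' crystal structure.
#'
#' @param tunnel_radius Radius of the narrow catalytic tunnel (A).
#' @param tunnel_length Length of the tunnel (A).
#' @param vestibule_radius Radius of the wide vestibule above the tunnel (A).
#' @param vestibule_depth Depth of the vestibule, from the top face down to
#'   the tunnel mouth (A).
#' @param body_radius Outer body radius (A).
#' @param body_height Outer body height (A); the lumen is drilled from the
#'   top, so the tunnel bottom sits at
#'   `body_height - vestibule_depth - tunnel_length`.
#' @param n_seg Azimuthal segments.
#' @return A list with `mesh` (faces labelled: tunnel-bottom disk faces are
#'   tagged `"catalytic"`) and `cat_center` (center of the catalytic disk).
#' @export
build_tunnel_mesh <- function(tunnel_radius = 2, tunnel_length = 6,
                              vestibule_radius = 8, vestibule_depth = 7,
                              body_radius = 11, body_height = 17,
                              n_seg = 48) {
  stopifnot(tunnel_radius < vestibule_radius,
            vestibule_radius < body_radius,
            tunnel_length + vestibule_depth < body_height)
  zb <- body_height - vestibule_depth - tunnel_length # tunnel bottom
  zs <- zb + tunnel_length                            # tunnel/vestibule shoulder
  # closed profile in the (r, z) half-plane, solid on its left
  profile <- rbind(
    c(0, zb),                            # axis, tunnel bottom
    c(tunnel_radius, zb),                # catalytic disk rim
    c(tunnel_radius, zs),                # tunnel wall
    c(vestibule_radius, zs),             # shoulder annulus
    c(vestibule_radius, body_height),    # vestibule wall
    c(body_radius, body_height),         # top annulus
    c(body_radius, 0),                   # outer wall
    c(0, 0))                             # bottom disk to the axis
  mesh <- revolve_profile(profile, n_seg = n_seg)
  lab <- rep("wall", nrow(mesh$faces))
  lab[mesh$segment == 1] <- "catalytic"
  mesh$label <- lab
  list(mesh = mesh, cat_center = c(0, 0, zb))
}
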