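#' Triangulated surface of a binary mask
#'
#' Extracts the closed boundary surface of a voxel mask as a triangle mesh in
#' world millimetres. Every face between a foreground voxel and a background
#' (or out-of-volume) voxel contributes two consistently outward-oriented
#' triangles whose corners sit on the voxel corners, so the mesh is
#' watertight by construction and its enclosed volume equals the voxel volume
#' of the mask exactly. Smooth a mask first ([smooth_mask()]) if stair-step
#' artefacts matter for printing.
#'
#' @param mask a nonempty [binary_mask()].
#' @return An object of class `triangle_mesh`: list with `vertices`
#'   (n x 3 matrix, mm) and `faces` (m x 3 integer matrix, 1-based,
#'   counter-clockwise seen from outside).
#' @seealso [write_stl()], [surface_volume()], [is_watertight()]
#' @export
mask_to_surface <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask_logical(mask)
  if (!any(m)) stop("segmentation error: empty mask has no surface",
                    call. = FALSE)
  d <- dim(m)
  nc <- d + 1L  # corner grid is (nx+1) x (ny+1) x (nz+1)
  corner_key <- function(cx, cy, cz) cx + nc[1] * (cy + nc[2] * cz)  # 0-based
  tris <- vector("list", 6L)
  ti <- 0L
  for (axis in 1:3) {
    others <- setdiff(1:3, axis)
    for (dir in c(1L, -1L)) {
      face_here <- m & !shift_axis(m, dir, axis, FALSE)
      idx <- which(face_here, arr.ind = TRUE)  # 1-based voxel indices
      if (nrow(idx) == 0L) next
      # corner offsets (0/1 per axis) of the quad on this voxel face
      base <- idx - 1L                         # 0-based voxel corner origin
      off_a <- if (dir == 1L) 1L else 0L
      b <- others[1L]; cc <- others[2L]
      quad <- list(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
      corners <- vapply(quad, function(q) {
        co <- base
        co[, axis] <- co[, axis] + off_a
        co[, b] <- co[, b] + q[1L]
        co[, cc] <- co[, cc] + q[2L]
        corner_key(co[, 1], co[, 2], co[, 3])
      }, numeric(nrow(idx)))
      if (nrow(idx) == 1L) corners <- matrix(corners, nrow = 1L)
      # winding: traversing the quad in (b, cc) order yields a normal along
      # +axis when (axis, b, cc) is a right-handed (cyclic) triple, -axis
      # otherwise; pick the order whose normal points toward `dir`
      cyclic <- axis != 2L  # others are in increasing order, so only axis 2
                            # gives an odd permutation (2,1,3)
      use_natural <- (cyclic && dir == 1L) || (!cyclic && dir == -1L)
      if (use_natural) {
        t1 <- corners[, c(1L, 2L, 3L), drop = FALSE]
        t2 <- corners[, c(1L, 3L, 4L), drop = FALSE]
      } else {
        t1 <- corners[, c(1L, 3L, 2L), drop = FALSE]
        t2 <- corners[, c(1L, 4L, 3L), drop = FALSE]
      }
      ti <- ti + 1L; tris[[ti]] <- rbind(t1, t2)
    }
  }
  allt <- do.call(rbind, tris[seq_len(ti)])
  keys <- sort(unique(as.vector(allt)))
  faces <- matrix(match(as.vector(allt), keys), ncol = 3L)
  # decode corner keys back to 0-based corner indices, then to world mm:
  # corner c of the grid sits at origin + (c - 0.5) * spacing
  cz <- keys %/% (nc[1] * nc[2])
  rem <- keys %% (nc[1] * nc[2])
  cy <- rem %/% nc[1]
  cx <- rem %% nc[1]
  verts <- cbind(mask$origin[1] + (cx - 0.5) * mask$spacing[1],
                 mask$origin[2] + (cy - 0.5) * mask$spacing[2],
                 mask$origin[3] + (cz - 0.5) * mask$spacing[3])
  structure(list(vertices = verts, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles, enclosed volume ", signif(surface_volume(x), 6),
      " mm^3\n", sep = "")
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed volume by the divergence theorem,
#' `sum(det(v1, v2, v3)) / 6` over the faces; positive for outward-oriented
#' closed surfaces.
#'
#' @param mesh a `triangle_mesh`.
#' @return Volume in mm^3.
#' @export
surface_volume <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
      v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
      v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Watertightness (closed, consistently oriented) check
#'
#' A mesh is accepted when every undirected edge is used by exactly two
#' faces, once in each direction -- the edge-manifold condition for a closed
#' orientable surface.
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(mesh$vertices)
  fwd <- (he_from - 1) * nv + he_to
  rev <- (he_to - 1) * nv + he_from
  # closed + consistently oriented: every directed edge appears exactly once
  # and is matched by its opposite
  !anyDuplicated(fwd) && all(fwd %in% rev)
}

#' Write a binary STL file
#'
#' Little-endian binary STL, units mm, with recomputed facet normals.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  f <- mesh$faces
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "bonesurro binary STL (mm)"))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  dat <- t(cbind(n, v1, v2, v3))  # 12 floats per facet, column-per-facet
  for (i in seq_len(nrow(f))) {
    writeBin(as.double(dat[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' Reads a little-endian binary STL into a `triangle_mesh`, welding vertices
#' that agree to float precision.
#'
#' @param path `.stl` path.
#' @return A `triangle_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", size = 4L, endian = "little")
  vals <- matrix(0, nrow = 12L, ncol = nfac)
  for (i in seq_len(nfac)) {
    vals[, i] <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "integer", size = 2L, endian = "little")
  }
  pts <- rbind(t(vals[4:6, , drop = FALSE]), t(vals[7:9, , drop = FALSE]),
               t(vals[10:12, , drop = FALSE]))
  key <- apply(pts, 1L, function(p) paste(format(p, digits = 9), collapse = ","))
  uk <- unique(key)
  verts <- pts[match(uk, key), , drop = FALSE]
  idx <- match(key, uk)
  faces <- cbind(idx[seq_len(nfac)], idx[nfac + seq_len(nfac)],
                 idx[2L * nfac + seq_len(nfac)])
  structure(list(vertices = verts, faces = faces), class = "triangle_mesh")
}

#' Export printable surfaces of a segmentation
#'
#' Writes the periosteal surface (outer boundary of the filled bone), the
#' endosteal surface (boundary of the endosteal cavity) and the spongiosa
#' solid to binary STL files `<stem>_periosteal.stl`, `<stem>_endosteal.stl`
#' and `<stem>_spongiosa.stl`. The periosteal and endosteal files are the
#' pair a slicer needs to print cortex and spongiosa with separate
#' parameters.
#'
#' @param seg a `femur_segmentation` from [segment_femur()], or a list with
#'   `bone`, `cortex`, `spongiosa` masks.
#' @param stem output path stem (directory + basename without extension).
#' @return An object of class `surface_pair`: list with `triangle_mesh`
#'   elements `periosteal`, `endosteal` and the written `paths`, invisibly.
#' @export
export_surfaces <- function(seg, stem) {
  filled <- fill_holes3(mask_logical(seg$bone))
  peri <- mask_to_surface(mask_like(filled, seg$bone))
  endo <- mask_to_surface(seg$spongiosa)
  paths <- paste0(stem, c("_periosteal.stl", "_endosteal.stl",
                          "_spongiosa.stl"))
  write_stl(peri, paths[1])
  write_stl(endo, paths[2])
  write_stl(endo, paths[3])  # spongiosa solid: same closed cavity region
  invisible(structure(list(periosteal = peri, endosteal = endo, paths = paths),
                      class = "surface_pair"))
}

#' @export
print.surface_pair <- function(x, ...) {
  cat("<surface_pair>\n  periosteal: ", nrow(x$periosteal$faces),
      " triangles, ", signif(surface_volume(x$periosteal), 6), " mm^3\n",
      "  endosteal:  ", nrow(x$endosteal$faces), " triangles, ",
      signif(surface_volume(x$endosteal), 6), " mm^3\n", sep = "")
  invisible(x)
}
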