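# Shared fixtures, all generated in code.

# Coarse (1 mm) phantoms keep the routine corridor tests fast; the
# acceptance tests use the 0.5 mm study phantom.
coarse_bicone <- function(elevation = 15, azimuth = 8, breach = NULL,
                          side = "left") {
  make_channel_phantom(phantom_spec(shape = "bicone",
                                    channel_elevation = elevation,
                                    channel_azimuth = azimuth,
                                    voxel_spacing = 1, breach = breach,
                                    side = side))
}

coarse_cylinder <- function(diameter = 6, elevation = 15, azimuth = 0) {
  make_channel_phantom(phantom_spec(shape = "cylinder",
                                    channel_waist_diameter = diameter,
                                    channel_end_diameter = diameter,
                                    channel_elevation = elevation,
                                    channel_azimuth = azimuth,
                                    voxel_spacing = 1))
}

# A synthetic safety map around a given binary mask (pitch in mm).
fake_safety_map <- function(safe, pitch = 1, entry = NULL, exit = NULL) {
  n_u <- nrow(safe); n_v <- ncol(safe)
  if (is.null(entry)) entry <- matrix(0, n_u, n_v)
  if (is.null(exit)) exit <- matrix(50, n_u, n_v)
  entry[!safe] <- NA; exit[!safe] <- NA
  structure(list(safe = safe, entry = entry, exit = exit,
                 u = c(1, 0, 0), v = c(0, 1, 0), direction = c(0, 0, 1),
                 center = c(0, 0, 0),
                 us = (seq_len(n_u) - (n_u + 1) / 2) * pitch,
                 vs = (seq_len(n_v) - (n_v + 1) / 2) * pitch,
                 pixel_pitch = pitch, min_len = 40, gap_tol = 0,
                 step = pitch / 2),
            class = "safety_map")
}

# Brute-force oracle: for every safe pixel the largest integer radius r
# such that all pixels whose centre lies within distance r are safe
# (pixels outside the grid count unsafe). Returns the global maximum.
brute_force_disc <- function(safe) {
  bg <- which(!safe, arr.ind = TRUE)
  fg <- which(safe, arr.ind = TRUE)
  if (nrow(fg) == 0) return(list(radius = -1))
  best <- -1; best_px <- NULL
  for (k in seq_len(nrow(fg))) {
    i <- fg[k, 1]; j <- fg[k, 2]
    # distance to nearest unsafe centre, including the implicit border
    d_border <- min(i - 0, j - 0, nrow(safe) + 1 - i, ncol(safe) + 1 - j)
    d_bg <- if (nrow(bg)) sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) else Inf
    d <- min(d_border, d_bg)
    r <- ceiling(d) - 1
    if (r > best) { best <- r; best_px <- c(i, j) }
  }
  list(radius = best, px = best_px)
}

# ASCII STL of an axis-aligned box, written in code (text fixture).
write_cube_stl <- function(path, lo = c(0, 0, 0), hi = c(10, 10, 10)) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  # 12 triangles, outward orientation irrelevant for parity voxelization
  f <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8),
             c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
             c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6))
  lines <- c("solid cube")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2],
                       v[f[i, ], 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
  invisible(path)
}

# ASCII PLY of the same box.
write_cube_ply <- function(path, lo = c(0, 0, 0), hi = c(10, 10, 10)) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 7), c(1, 7, 5), c(2, 8, 4), c(2, 6, 8),
             c(1, 5, 6), c(1, 6, 2), c(3, 4, 8), c(3, 8, 7),
             c(1, 2, 4), c(1, 4, 3), c(5, 7, 8), c(5, 8, 6)) - 1
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 8",
               "property float x", "property float y", "property float z",
               "element face 12", "property list uchar int vertex_indices",
               "end_header",
               sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}
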