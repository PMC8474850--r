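# Readers and writers for the formats the pipeline consumes and emits:
# NIfTI and MetaImage binary label volumes, STL/PLY surface meshes
# (voxelized on read), landmark JSON/CSV, truth JSON, cohort CSV, and
# plain PGM safety-map renders for QC.

#' Write a bone model as a label volume
#'
#' NIfTI (`.nii`/`.nii.gz`, via RNifti) or MetaImage (`.mha` single file /
#' `.mhd` + `.raw`, MET_UCHAR). The voxel spacing and origin are stored in
#' the header; the occupancy is written as 0/1.
#'
#' @param model a [bone_model()].
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
write_bone_model <- function(model, path) {
  stopifnot(inherits(model, "bone_model"))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(model$occupancy)
    RNifti::pixdim(img) <- model$spacing
    aff <- diag(c(model$spacing, 1))
    aff[1:3, 4] <- model$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("mha", "mhd")) {
    write_metaimage(model, path)
  } else {
    stop("unknown bone-model format: .", ext,
         " (use .nii, .nii.gz, .mha or .mhd)")
  }
  invisible(path)
}

write_metaimage <- function(model, path) {
  d <- dim(model$occupancy)
  local_data <- tolower(sub(".*\\.", "", path)) == "mha"
  raw_path <- sub("\\.mhd$", ".raw", path)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(model$origin, collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(model$spacing, collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    "ElementType = MET_UCHAR",
    paste("ElementDataFile =",
          if (local_data) "LOCAL" else basename(raw_path))
  )
  payload <- as.raw(as.vector(model$occupancy))
  if (local_data) {
    con <- file(path, "wb")
    writeLines(hdr, con)
    writeBin(payload, con)
    close(con)
  } else {
    writeLines(hdr, path)
    writeBin(payload, raw_path)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0)
      stop("corrupted MetaImage header: no ElementDataFile line")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("corrupted MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "ElementType")
  if (!all(need %in% names(hdr)))
    stop("corrupted MetaImage header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage data is not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (length(d) != 3 || any(is.na(d)) || any(d <= 0))
    stop("corrupted MetaImage header: bad DimSize")
  typ <- hdr$ElementType
  spec <- switch(typ,
                 MET_UCHAR = list(what = integer(), size = 1, signed = FALSE),
                 MET_CHAR = list(what = integer(), size = 1, signed = TRUE),
                 MET_USHORT = list(what = integer(), size = 2, signed = FALSE),
                 MET_SHORT = list(what = integer(), size = 2, signed = TRUE),
                 MET_INT = list(what = integer(), size = 4, signed = TRUE),
                 MET_FLOAT = list(what = numeric(), size = 4),
                 MET_DOUBLE = list(what = numeric(), size = 8),
                 stop("unsupported MetaImage ElementType: ", typ))
  n <- prod(d)
  if (hdr$ElementDataFile == "LOCAL") {
    vals <- readBin(con, spec$what, n = n, size = spec$size,
                    signed = if (is.null(spec$signed)) TRUE else spec$signed,
                    endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path)) stop("missing raw data file: ", raw_path)
    vals <- readBin(raw_path, spec$what, n = n, size = spec$size,
                    signed = if (is.null(spec$signed)) TRUE else spec$signed,
                    endian = "little")
  }
  if (length(vals) < n)
    stop("corrupted MetaImage: expected ", n, " voxels, got ", length(vals))
  list(data = array(vals, d), spacing = sp, origin = org)
}

#' Read a bone model from a label volume or surface mesh
#'
#' NIfTI and MetaImage label volumes are binarized (nonzero, or the given
#' `label`); STL (ASCII or binary) and ASCII PLY triangle meshes are
#' checked for watertightness and voxelized at `pitch` mm by z-column ray
#' parity.
#'
#' @param path input file (`.nii`, `.nii.gz`, `.mha`, `.mhd`, `.stl`,
#'   `.ply`).
#' @param pitch voxel pitch used when voxelizing a mesh, mm.
#' @param label optional label value to extract from a label volume;
#'   default any nonzero voxel.
#' @return a [bone_model()].
#' @export
read_bone_model <- function(path, pitch = 0.5, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    aff <- RNifti::xform(img)
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    occ <- if (is.null(label)) arr != 0 else arr == label
    bone_model(occ, spacing = sp[1:3], origin = aff[1:3, 4])
  } else if (ext %in% c("mha", "mhd")) {
    mi <- read_metaimage(path)
    occ <- if (is.null(label)) mi$data != 0 else mi$data == label
    bone_model(occ, spacing = mi$spacing, origin = mi$origin)
  } else if (ext %in% c("stl", "ply")) {
    mesh <- if (ext == "stl") read_stl(path) else read_ply(path)
    mesh_to_model(mesh, pitch)
  } else {
    stop("unknown bone-model format: .", ext)
  }
}

# --- mesh handling -------------------------------------------------------

# Merge per-facet vertices into an indexed (vertices, faces) pair.
index_mesh <- function(tri_vertices) {
  key <- apply(round(tri_vertices, 9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  vertices <- tri_vertices[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 84)
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") && {
    txt <- suppressWarnings(readLines(path, n = 20, warn = FALSE))
    any(grepl("facet", txt))
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("corrupted ASCII STL: vertex count not a multiple of 3")
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(x) as.numeric(x[2:4]), numeric(3)))
    if (any(is.na(nums))) stop("corrupted ASCII STL: non-numeric vertex")
    index_mesh(nums)
  } else {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (is.na(nf) || nf <= 0 || sz < 84 + 50 * nf)
      stop("corrupted binary STL header (facet count ", nf, ")")
    tri <- matrix(0, nf * 3, 3)
    for (f in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      tri[(3 * f - 2):(3 * f), ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
    index_mesh(tri)
  }
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || txt[1] != "ply") stop("corrupted PLY: no magic")
  if (!any(grepl("^format ascii", txt[1:5])))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", txt)
  if (is.na(endh)) stop("corrupted PLY: no end_header")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", txt, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("corrupted PLY: missing element counts")
  vlines <- txt[(endh + 1):(endh + nv)]
  vertices <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                       function(x) as.numeric(x[1:3]), numeric(3)))
  flines <- txt[(endh + nv + 1):(endh + nv + nf)]
  faces <- t(vapply(strsplit(trimws(flines), "\\s+"), function(x) {
    if (as.integer(x[1]) != 3) stop("only triangle PLY faces are supported")
    as.integer(x[2:4]) + 1L
  }, integer(3)))
  if (any(is.na(vertices)) || any(is.na(faces)))
    stop("corrupted PLY: non-numeric data")
  list(vertices = vertices, faces = faces)
}

# Count boundary edges: watertight iff every undirected edge is shared by
# exactly two faces.
mesh_hole_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) != 2)
}

mesh_to_model <- function(mesh, pitch, pad = 1) {
  holes <- mesh_hole_edges(mesh)
  if (holes > 0)
    stop("mesh is not watertight: ", holes,
         " edge(s) not shared by exactly two faces")
  lo <- apply(mesh$vertices, 2, min) - pad * pitch
  hi <- apply(mesh$vertices, 2, max) + pad * pitch
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / pitch)) + 1L)
  occ <- voxelize_mesh_cpp(mesh$vertices, mesh$faces - 1L, dims, lo,
                           rep(pitch, 3))
  bone_model(array(occ, dims), spacing = pitch, origin = lo)
}

# --- landmarks, truth, cohort, config ------------------------------------

#' Read landmarks from JSON or CSV
#'
#' JSON: either an object `{"asis_left": [x,y,z], ...}` or an array of
#' records `{"name":, "x":, "y":, "z":}`; an optional `table_up` entry is
#' honoured. CSV: columns `name,x,y,z`. Coordinates in mm, scanner frame.
#'
#' @param path input file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  pts <- list()
  if (ext == "json") {
    j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    tu <- NULL
    if (is.list(j) && !is.data.frame(j) && !is.null(j$landmarks)) {
      tu <- j$table_up
      j <- j$landmarks
    }
    if (is.data.frame(j)) {
      for (i in seq_len(nrow(j)))
        pts[[j$name[i]]] <- c(j$x[i], j$y[i], j$z[i])
    } else {
      pts <- lapply(j, as.numeric)
    }
    if (!is.null(tu)) pts$table_up <- as.numeric(tu)
  } else if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "x", "y", "z") %in% names(d)))
    for (i in seq_len(nrow(d)))
      pts[[d$name[i]]] <- c(d$x[i], d$y[i], d$z[i])
  } else {
    stop("unknown landmark format: .", ext)
  }
  need <- c("asis_left", "asis_right", "pubic_symphysis")
  if (!all(need %in% names(pts)))
    stop("landmark file must define: ", paste(need, collapse = ", "))
  landmark_set(pts$asis_left, pts$asis_right, pts$pubic_symphysis,
               table_up = if (!is.null(pts$table_up)) pts$table_up
               else c(0, 0, 1))
}

#' Write landmarks as JSON
#'
#' @param lm a [landmark_set()].
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  recs <- lapply(c("asis_left", "asis_right", "pubic_symphysis"),
                 function(nm) list(name = nm, x = lm[[nm]][1],
                                   y = lm[[nm]][2], z = lm[[nm]][3]))
  obj <- list(landmarks = recs, table_up = lm$table_up)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write phantom ground truth as a JSON sidecar
#' @param truth a `phantom_truth` (from [make_channel_phantom()]).
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a safety map as a portable graymap (PGM) for QC
#'
#' Three gray levels: background (no bone on the ray), unsafe bone
#' (cortical superimposition — the dark rim), and safe corridor pixels
#' (the bright "U-shaped" region).
#'
#' @param map a [ray_safety_map()].
#' @param path output `.pgm` path (plain, P2).
#' @return the path, invisibly.
#' @export
write_safety_map_pgm <- function(map, path) {
  stopifnot(inherits(map, "safety_map"))
  lev <- matrix(0L, nrow(map$safe), ncol(map$safe))
  lev[!is.na(map$entry)] <- 100L
  lev[map$safe] <- 255L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(lev), ncol(lev)), "255"), con)
  # PGM rows scan the image top-to-bottom; emit v as rows
  for (j in rev(seq_len(ncol(lev))))
    writeLines(paste(lev[, j], collapse = " "), con)
  invisible(path)
}

#' Run configuration
#'
#' All tunable parameters of an end-to-end run, serializable to YAML or
#' JSON and round-tripping losslessly.
#'
#' @param alphas fluoroscopic angles, degrees.
#' @param cutoff insertion cutoff, mm.
#' @param azimuth_range,azimuth_step azimuth scan, degrees.
#' @param min_len,gap_tol ray-safety parameters, mm.
#' @param pixel_pitch safety-map pitch, mm (`NULL` = half voxel).
#' @param sides hips to measure.
#' @param seed integer RNG seed.
#' @param restarts jittered measurement repeats (max kept).
#' @param posthoc post-hoc procedure.
#' @param pooled_t use pooled-variance t tests.
#' @param alpha_level significance level.
#' @return an object of class `run_config` (a list).
#' @export
run_config <- function(alphas = c(5, 15, 25, 35, 45), cutoff = 3.5,
                       azimuth_range = 30, azimuth_step = 1,
                       min_len = 40, gap_tol = 0, pixel_pitch = NULL,
                       sides = "left", seed = 1L, restarts = 1L,
                       posthoc = "tukey", pooled_t = TRUE,
                       alpha_level = 0.05) {
  stopifnot(all(alphas >= 0 & alphas < 90), cutoff >= 0,
            azimuth_step > 0, min_len > 0, gap_tol >= 0,
            all(sides %in% c("left", "right")), restarts >= 1,
            posthoc %in% c("tukey", "bonferroni"),
            alpha_level > 0, alpha_level < 1)
  structure(list(alphas = alphas, cutoff = cutoff,
                 azimuth_range = azimuth_range, azimuth_step = azimuth_step,
                 min_len = min_len, gap_tol = gap_tol,
                 pixel_pitch = pixel_pitch, sides = sides,
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 posthoc = posthoc, pooled_t = pooled_t,
                 alpha_level = alpha_level),
            class = "run_config")
}

#' Write / read a run configuration (YAML or JSON by extension)
#' @param cfg a [run_config()].
#' @param path `.yaml`/`.yml` or `.json` path.
#' @return the path ([write_run_config()]) or the [run_config()]
#'   ([read_run_config()]).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(cfg), path)
  } else if (ext == "json") {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else stop("unknown config format: .", ext)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  lst <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unknown config format: .", ext)
  lst <- lst[!vapply(lst, is.null, logical(1))]  # absent pixel_pitch = NULL
  do.call(run_config, lst)
}
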