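# Sampling volumes onto surface meshes and summarizing per subdivision.

#' Sample a scalar volume at surface vertex coordinates
#'
#' Vertices are mapped from world (mm) to voxel coordinates through the
#' inverse affine and interpolated. Trilinear interpolation is exact for
#' linear fields; vertices falling outside the volume are returned as NA and
#' excluded from downstream means.
#'
#' @param volume 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (voxel indices are 0-based, as in
#'   NIfTI convention).
#' @param mesh a [surface_mesh()] with vertices in world coordinates.
#' @param method `"trilinear"` or `"nearest"`.
#' @return numeric vector, one value per vertex (NA outside the volume).
#' @export
sample_volume_to_surface <- function(volume, affine, mesh,
                                     method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  assert_that(length(dim(volume)) == 3, "volume must be a 3-D array")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  v <- cbind(mesh$vertices, 1) %*% t(solve(affine))
  vox <- v[, 1:3, drop = FALSE]  # 0-based continuous voxel coordinates
  dims <- dim(volume)
  out <- rep(NA_real_, nrow(vox))

  if (method == "nearest") {
    idx <- round(vox) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
      idx[, 2] >= 1 & idx[, 2] <= dims[2] &
      idx[, 3] >= 1 & idx[, 3] <= dims[3]
    out[ok] <- volume[idx[ok, , drop = FALSE]]
    return(out)
  }

  lo <- floor(vox)
  fr <- vox - lo
  ok <- lo[, 1] >= 0 & lo[, 1] <= dims[1] - 2 &
    lo[, 2] >= 0 & lo[, 2] <= dims[2] - 2 &
    lo[, 3] >= 0 & lo[, 3] <= dims[3] - 2
  # allow vertices exactly on the upper face
  hi_ok <- function(k) abs(vox[, k] - (dims[k] - 1)) < 1e-9
  for (k in 1:3) {
    on_face <- hi_ok(k) & lo[, k] == dims[k] - 1
    lo[on_face, k] <- dims[k] - 2
    fr[on_face, k] <- 1
  }
  ok <- lo[, 1] >= 0 & lo[, 1] <= dims[1] - 2 &
    lo[, 2] >= 0 & lo[, 2] <= dims[2] - 2 &
    lo[, 3] >= 0 & lo[, 3] <= dims[3] - 2 &
    fr[, 1] >= -1e-9 & fr[, 2] >= -1e-9 & fr[, 3] >= -1e-9
  w <- which(ok)
  if (length(w)) {
    acc <- numeric(length(w))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (dx * fr[w, 1] + (1 - dx) * (1 - fr[w, 1])) *
        (dy * fr[w, 2] + (1 - dy) * (1 - fr[w, 2])) *
        (dz * fr[w, 3] + (1 - dz) * (1 - fr[w, 3]))
      acc <- acc + wt *
        volume[cbind(lo[w, 1] + 1 + dx, lo[w, 2] + 1 + dy, lo[w, 3] + 1 + dz)]
    }
    out[w] <- acc
  }
  out
}

#' Mean value per subdivision
#'
#' Unweighted arithmetic mean of the per-vertex values over each subdivision
#' label (area-weighted means available via `weights`). NA vertices are
#' excluded; an entirely empty subdivision is an error.
#'
#' @param vertex_values numeric per-vertex values (NA allowed).
#' @param labels factor/character per-vertex subdivision labels; entries in
#'   `exclude` are ignored.
#' @param subject,hemisphere identifiers copied into the output rows.
#' @param weights optional per-vertex weights (e.g. vertex areas).
#' @param exclude labels that are not subdivisions (default "background").
#' @return data.frame (subject, hemisphere, subdivision, mean_rtop,
#'   n_vertices).
#' @export
subdivision_means <- function(vertex_values, labels, subject = "s01",
                              hemisphere = "left", weights = NULL,
                              exclude = "background") {
  assert_that(length(vertex_values) == length(labels),
              "values and labels must align")
  keep <- !(as.character(labels) %in% exclude) & !is.na(labels)
  labs <- factor(as.character(labels)[keep])
  vals <- vertex_values[keep]
  wts <- if (is.null(weights)) rep(1, length(vals)) else weights[keep]
  rows <- lapply(levels(labs), function(l) {
    sel <- labs == l & is.finite(vals)
    if (!any(sel))
      stop("subdivision '", l, "' has no usable vertices")
    data.frame(subject = subject, hemisphere = hemisphere, subdivision = l,
               mean_rtop = sum(vals[sel] * wts[sel]) / sum(wts[sel]),
               n_vertices = sum(sel))
  })
  do.call(rbind, rows)
}

#' Merge fine multimodal-atlas labels into the tripartite scheme
#'
#' Reconstructs the three functional subdivisions from a fine-grained
#' multimodal parcellation of the insula: dAI = AVI + MI + FOP3; vAI = AAIC;
#' PI = PoI1 + PoI2 + Ig + FOP2. Any other label becomes background.
#'
#' @param fine_labels character/factor vector of fine labels per vertex.
#' @param mapping named list giving the fine labels for each subdivision
#'   (names vAI, dAI, PI).
#' @return factor with levels vAI, dAI, PI, background.
#' @export
merge_multimodal_labels <- function(fine_labels,
                                    mapping = list(
                                      dAI = c("AVI", "MI", "FOP3"),
                                      vAI = "AAIC",
                                      PI = c("PoI1", "PoI2", "Ig", "FOP2"))) {
  fine <- as.character(fine_labels)
  required <- unlist(mapping, use.names = FALSE)
  absent <- setdiff(required, unique(fine))
  if (length(absent))
    stop("required fine labels absent: ", paste(absent, collapse = ", "))
  out <- rep("background", length(fine))
  for (sub in names(mapping)) out[fine %in% mapping[[sub]]] <- sub
  factor(out, levels = c("vAI", "dAI", "PI", "background"))
}

# Per-vertex one-ring areas (sum of incident triangle areas / 3); used for
# the optional area-weighted subdivision means.
vertex_areas <- function(mesh) {
  tri <- mesh$triangles
  p1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  p2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  p3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  cr <- cross_rows(p2 - p1, p3 - p1)
  area <- 0.5 * sqrt(rowSums(cr^2))
  acc <- numeric(nrow(mesh$vertices))
  for (k in 1:3) {
    t <- tapply(area, tri[, k], sum)
    acc[as.integer(names(t))] <- acc[as.integer(names(t))] + t
  }
  acc / 3
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
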