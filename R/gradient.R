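# Surface gradient fields and directional statistics.

#' Gradient of a scalar field on a triangle mesh
#'
#' Per triangle, the gradient of the piecewise-linear interpolant:
#' grad f = sum_i f_i (n x e_i) / (2A), where e_i is the edge opposite vertex
#' i and n the unit triangle normal. Per vertex, the area-weighted average of
#' incident triangle gradients re-projected onto the vertex tangent plane
#' (normal = area-weighted average of incident triangle normals). Boundary
#' vertices (incident to an edge used by a single triangle) are flagged
#' invalid; zero-area triangles are excluded with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_values finite numeric vector, one value per vertex.
#' @param area_weighted use triangle-area weights for the vertex average
#'   (default TRUE).
#' @return `gradient_field`: list with `gradients` (n x 3), `valid` (logical,
#'   interior vertices), `vertex_normals`.
#' @export
mesh_gradient <- function(mesh, vertex_values, area_weighted = TRUE) {
  assert_that(all(is.finite(vertex_values)), "vertex_values must be finite")
  assert_that(length(vertex_values) == nrow(mesh$vertices),
              "one value per vertex required")
  tri <- mesh$triangles
  p1 <- mesh$vertices[tri[, 1], , drop = FALSE]
  p2 <- mesh$vertices[tri[, 2], , drop = FALSE]
  p3 <- mesh$vertices[tri[, 3], , drop = FALSE]
  nrm <- cross_rows(p2 - p1, p3 - p1)       # 2A * unit normal
  area2 <- sqrt(rowSums(nrm^2))             # 2A
  degenerate <- area2 < 1e-12
  if (all(degenerate)) stop("all triangles are degenerate")
  if (any(degenerate))
    warning(sum(degenerate), " zero-area triangle(s) excluded")
  unit_n <- nrm / pmax(area2, 1e-300)

  f1 <- vertex_values[tri[, 1]]
  f2 <- vertex_values[tri[, 2]]
  f3 <- vertex_values[tri[, 3]]
  # grad = (f1 (p3-p2) + f2 (p1-p3) + f3 (p2-p1)) x n / (2A)  [n x e form]
  gsum <- (cross_rows(p3 - p2, unit_n) * f1 +
             cross_rows(p1 - p3, unit_n) * f2 +
             cross_rows(p2 - p1, unit_n) * f3)
  tri_grad <- -gsum / pmax(area2, 1e-300)   # n x e convention sign
  tri_grad[degenerate, ] <- 0

  nv <- nrow(mesh$vertices)
  w_tri <- if (area_weighted) area2 / 2 else rep(1, nrow(tri))
  w_tri[degenerate] <- 0
  acc_g <- rowsum(rbind(tri_grad * w_tri, tri_grad * w_tri,
                        tri_grad * w_tri),
                  group = c(tri[, 1], tri[, 2], tri[, 3]))
  acc_n <- rowsum(rbind(unit_n * w_tri, unit_n * w_tri, unit_n * w_tri),
                  group = c(tri[, 1], tri[, 2], tri[, 3]))
  acc_w <- rowsum(c(w_tri, w_tri, w_tri),
                  group = c(tri[, 1], tri[, 2], tri[, 3]))
  got <- as.integer(rownames(acc_g))
  grads <- matrix(0, nv, 3); normals <- matrix(0, nv, 3)
  grads[got, ] <- acc_g / pmax(as.numeric(acc_w), 1e-300)
  normals[got, ] <- acc_n
  nn <- sqrt(rowSums(normals^2))
  normals[nn > 0, ] <- normals[nn > 0, ] / nn[nn > 0]
  # re-project to the vertex tangent plane
  dot <- rowSums(grads * normals)
  grads <- grads - normals * dot

  # boundary detection: edges used once
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- names(table(key))[table(key) == 1]
  boundary_v <- unique(as.integer(unlist(strsplit(once, " "))))
  valid <- rep(TRUE, nv)
  valid[boundary_v] <- FALSE
  valid[!(seq_len(nv) %in% got)] <- FALSE

  structure(list(gradients = grads, valid = valid, vertex_normals = normals),
            class = "gradient_field")
}

#' Main gradient direction of a region
#'
#' Normalized resultant of the per-vertex gradient unit directions over the
#' region (optionally magnitude-weighted). Errors when the region is empty,
#' has fewer than `min_vertices` valid vertices, or when near-antipodal
#' cancellation leaves a resultant below `1e-8`.
#'
#' @param field a [mesh_gradient()] result.
#' @param region logical or integer vertex selector.
#' @param magnitude_weighted weight directions by gradient magnitude.
#' @param min_vertices minimum usable vertices (default 10).
#' @return unit 3-vector.
#' @export
main_direction <- function(field, region, magnitude_weighted = FALSE,
                           min_vertices = 10) {
  if (is.logical(region)) region <- which(region)
  if (!length(region)) stop("empty region")
  g <- field$gradients[region, , drop = FALSE]
  ok <- field$valid[region] & sqrt(rowSums(g^2)) > 1e-12
  g <- g[ok, , drop = FALSE]
  if (nrow(g) < min_vertices)
    stop("region has ", nrow(g), " valid vertices; need >= ", min_vertices)
  u <- unit_rows(g)
  r <- if (magnitude_weighted) colSums(g) else colSums(u)
  if (vec_norm(r) < 1e-8)
    stop("degenerate direction: resultant norm below 1e-8")
  r / vec_norm(r)
}

#' Directional statistics of per-subject unit vectors
#'
#' Spherical mean direction, dispersion (circular standard deviation
#' sqrt(-2 log Rbar) of the resultant length), SEM = dispersion / sqrt(N),
#' a seeded bootstrap 95% confidence half-width (angle between resampled and
#' full-sample means), and the Rayleigh uniformity test.
#'
#' @param directions N x 3 matrix of unit vectors (N >= 3).
#' @param n_boot bootstrap draws for the confidence interval.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return `directional_stats`: list with mean_direction, mean_angle
#'   (radians, atan2(y, x) in the first two coordinates), resultant_length,
#'   dispersion, sem, ci_halfwidth (radians), rayleigh (statistic, df, p), n.
#' @export
directional_stats <- function(directions, n_boot = 2000, conf = 0.95,
                              seed = 1L) {
  directions <- as.matrix(directions)
  assert_that(nrow(directions) >= 3, "need at least 3 directions")
  nn <- sqrt(rowSums(directions^2))
  assert_that(all(nn > 1e-12), "zero-length direction vector")
  u <- directions / nn
  n <- nrow(u)
  res <- colMeans(u)
  rbar <- vec_norm(res)
  mean_dir <- res / max(rbar, 1e-300)
  dispersion <- sqrt(max(0, -2 * log(max(rbar, 1e-300))))
  ray <- rayleigh_test(u)
  ci <- with_seed(seed, {
    angles <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      m <- colMeans(u[idx, , drop = FALSE])
      angle_between(m, mean_dir)
    })
    stats::quantile(angles, conf, names = FALSE)
  })
  structure(list(mean_direction = mean_dir,
                 mean_angle = atan2(mean_dir[2], mean_dir[1]),
                 resultant_length = rbar,
                 dispersion = dispersion,
                 sem = dispersion / sqrt(n),
                 ci_halfwidth = ci,
                 rayleigh = ray, n = n),
            class = "directional_stats")
}

#' Rayleigh test of directional uniformity on the sphere
#'
#' S = 3 N ||mean resultant||^2 referred to a chi-squared distribution with
#' 3 degrees of freedom (one per vector component); S is bounded by 3N and
#' attains it for identical directions.
#'
#' @param directions N x 3 unit vectors, N >= 10.
#' @return list with statistic, df = 3, p, n.
#' @export
rayleigh_test <- function(directions) {
  u <- as.matrix(directions)
  assert_that(nrow(u) >= 10, "need at least 10 directions")
  u <- unit_rows(u)
  n <- nrow(u)
  s <- 3 * n * sum(colMeans(u)^2)
  list(statistic = s, df = 3,
       p = stats::pchisq(s, df = 3, lower.tail = FALSE), n = n)
}

#' Isocontours of a scalar field on a triangle mesh
#'
#' Marching-triangles extraction: each triangle crossed by a level
#' contributes one segment joining the linear-interpolation crossing points
#' on its two crossed edges. Segments are chained into polylines (closed or
#' boundary-terminated). Levels outside the field range yield an empty set
#' with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_values finite numeric per-vertex field.
#' @param levels numeric contour levels.
#' @return data.frame (level, polyline, x1, y1, z1, x2, y2, z2), one row per
#'   segment.
#' @export
isocontours <- function(mesh, vertex_values, levels) {
  assert_that(all(is.finite(vertex_values)), "vertex_values must be finite")
  tri <- mesh$triangles
  v <- mesh$vertices
  out <- list()
  for (lev in levels) {
    if (lev < min(vertex_values) || lev > max(vertex_values)) {
      warning("level ", lev, " outside the field range; empty contour")
      next
    }
    segs <- list()
    for (t in seq_len(nrow(tri))) {
      id <- tri[t, ]
      f <- vertex_values[id]
      above <- f > lev
      if (all(above) || all(!above)) next
      pts <- list()
      for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
        fa <- f[e[1]]; fb <- f[e[2]]
        if ((fa > lev) != (fb > lev)) {
          s <- (lev - fa) / (fb - fa)
          pts[[length(pts) + 1]] <- v[id[e[1]], ] + s * (v[id[e[2]], ] - v[id[e[1]], ])
        }
      }
      if (length(pts) == 2)
        segs[[length(segs) + 1]] <- c(pts[[1]], pts[[2]])
    }
    if (!length(segs)) next
    sm <- do.call(rbind, segs)
    poly <- chain_segments(sm)
    out[[length(out) + 1]] <- data.frame(level = lev, polyline = poly,
                                         x1 = sm[, 1], y1 = sm[, 2], z1 = sm[, 3],
                                         x2 = sm[, 4], y2 = sm[, 5], z2 = sm[, 6])
  }
  if (!length(out))
    return(data.frame(level = numeric(0), polyline = integer(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0)))
  do.call(rbind, out)
}

# Assign a polyline id to each segment by chaining shared endpoints.
chain_segments <- function(sm, tol = 1e-9) {
  n <- nrow(sm)
  key <- function(p) paste(round(p / tol) * tol, collapse = "_")
  ends <- rbind(sm[, 1:3, drop = FALSE], sm[, 4:6, drop = FALSE])
  keys <- apply(ends, 1, key)
  comp <- seq_len(n)
  # union-find over segments sharing an endpoint key
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  bykey <- split(c(seq_len(n), seq_len(n)), keys)
  for (grp in bykey) {
    if (length(grp) > 1) {
      r <- find(grp[1])
      for (g in grp[-1]) { rg <- find(g); if (rg != r) comp[rg] <- r }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

#' Total length of contour polylines
#'
#' @param contours output of [isocontours()].
#' @return named numeric vector of total length per level.
#' @export
contour_lengths <- function(contours) {
  if (!nrow(contours)) return(numeric(0))
  len <- sqrt((contours$x2 - contours$x1)^2 + (contours$y2 - contours$y1)^2 +
                (contours$z2 - contours$z1)^2)
  tapply(len, contours$level, sum)
}
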