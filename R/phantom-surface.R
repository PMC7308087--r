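# Surface phantom: an open rectangular cortical sheet with a planted linear
# scalar field. Emulates an insula-like sheet with three contiguous
# functional subdivisions per hemisphere (vAI anterior, dAI middle, PI
# posterior) and a known anterior-posterior / ventral-dorsal gradient; the
# analytic surface gradient of the planted field is the tangential projection
# of the chosen gradient direction.

#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  assert_that(ncol(vertices) == 3, "vertices must be n x 3")
  assert_that(min(triangles) >= 1 && max(triangles) <= nrow(vertices),
              "triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

# Regular grid sheet (nx x ny vertices) spanning length_mm x width_mm,
# embedded at z = 0, triangulated with alternating diagonals.
grid_sheet <- function(nx, ny, length_mm, width_mm) {
  xs <- seq(0, length_mm, length.out = nx)
  ys <- seq(0, width_mm, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  tri <- matrix(0L, 2 * (nx - 1) * (ny - 1), 3)
  k <- 1L
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    a <- (j - 1L) * nx + i
    b <- a + 1L
    c <- a + nx
    d <- c + 1L
    tri[k, ] <- c(a, b, d); tri[k + 1L, ] <- c(a, d, c)
    k <- k + 2L
  }
  surface_mesh(v, tri)
}

#' Surface phantom with a planted scalar gradient
#'
#' Builds left and right hemisphere sheets (about `n_vertices` each), assigns
#' three contiguous subdivisions per hemisphere along the anterior-posterior
#' axis (vAI, dAI, PI; anterior = low x), and plants the scalar field
#' `offset + slope * (vertex . gradient_direction) + noise`. The planted
#' per-subdivision gradient direction is the tangential projection of
#' `gradient_direction` onto the (flat) sheet. The right-hemisphere sheet is
#' mirrored across y. Subdivision offsets emulate the empirical RTOP ordering
#' vAI < dAI < PI.
#'
#' @param n_vertices target vertex count per hemisphere (>= 100).
#' @param gradient_direction non-zero 3-vector of the planted gradient.
#' @param noise_sd per-vertex Gaussian noise standard deviation.
#' @param slope field change per mm along `gradient_direction`.
#' @param offset field value at the origin.
#' @param subdivision_shift additive offsets for (vAI, dAI, PI), emulating
#'   the subdivision contrast; zero by default so the field stays linear.
#' @param seed integer seed (noise only; geometry and labels deterministic).
#' @return `surface_phantom`: list with `left` and `right`, each holding
#'   `mesh`, `labels` (factor vAI/dAI/PI), `planted_field`,
#'   `planted_gradient_direction` (unit 3-vector, same for all subdivisions),
#'   and `hemisphere`.
#' @export
make_surface_phantom <- function(n_vertices = 400,
                                 gradient_direction = c(1, 0, 0),
                                 noise_sd = 0, slope = 0.02, offset = 2,
                                 subdivision_shift = c(vAI = 0, dAI = 0, PI = 0),
                                 seed = 1L) {
  assert_that(n_vertices >= 100, "n_vertices must be >= 100")
  assert_that(vec_norm(gradient_direction) > 1e-12,
              "gradient_direction must be non-zero")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  # insula-like elongated sheet, 60 x 30 mm, 2:1 vertex grid
  nx <- max(2L, as.integer(ceiling(sqrt(2 * n_vertices))))
  ny <- max(2L, as.integer(ceiling(nx / 2)))
  g <- as.numeric(gradient_direction)
  tangential <- c(g[1], g[2], 0)  # sheet lies in z = 0
  assert_that(vec_norm(tangential) > 1e-12,
              "gradient_direction must have a tangential component")

  build_hemi <- function(hemisphere, hemi_seed) {
    mesh <- grid_sheet(nx, ny, 60, 30)
    if (hemisphere == "right") mesh$vertices[, 2] <- -mesh$vertices[, 2]
    x <- mesh$vertices[, 1]
    labels <- cut(x, breaks = c(-Inf, 20, 40, Inf),
                  labels = c("vAI", "dAI", "PI"))
    field <- offset + slope * as.vector(mesh$vertices %*% g)
    shift <- subdivision_shift[as.character(labels)]
    shift[is.na(shift)] <- 0
    field <- field + as.numeric(shift)
    field <- field + with_seed(hemi_seed, stats::rnorm(length(field),
                                                       sd = noise_sd))
    list(mesh = mesh, labels = labels, planted_field = field,
         planted_gradient_direction = normalize_vec(tangential),
         hemisphere = hemisphere)
  }
  structure(list(left = build_hemi("left", seed),
                 right = build_hemi("right", seed + 10000L),
                 slope = slope, noise_sd = noise_sd),
            class = "surface_phantom")
}
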