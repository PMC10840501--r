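# Modified bead-chain geometry: each bead carries two endpoints, a centroid
# and an approximate radius; consecutive beads share an endpoint, so a chain
# of n beads has n+1 endpoints. Chains are stored column-compactly
# (centroids n x 3, endpoints (n+1) x 3) rather than as bead lists; the
# bead-list view is available through chain_bead()/new_chain().

## ---- quaternions -----------------------------------------------------------

#' Quaternion from rotation axis and angle
#'
#' @param axis_dir Non-zero 3-vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion as a numeric 4-vector `(w, x, y, z)`.
#' @export
quaternion_from_axis_angle <- function(axis_dir, angle) {
  nrm <- sqrt(sum(axis_dir^2))
  if (nrm < 1e-12) stop("zero axis direction")
  u <- axis_dir / nrm
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Quaternion product (Hamilton convention)
#'
#' @param q,p Numeric 4-vectors `(w, x, y, z)`.
#' @return The product quaternion `q * p`.
#' @export
quaternion_multiply <- function(q, p) {
  c(q[1] * p[1] - sum(q[2:4] * p[2:4]),
    q[1] * p[2:4] + p[1] * q[2:4] + cross3(q[2:4], p[2:4]))
}

quaternion_conjugate <- function(q) c(q[1], -q[2:4])

#' Rotate a 3D point by a unit quaternion (conjugation q v q*)
#'
#' @param point Numeric 3-vector.
#' @param q Unit quaternion `(w, x, y, z)`.
#' @return The rotated 3-vector.
#' @export
quaternion_rotate <- function(point, q) {
  v <- c(0, point)
  out <- quaternion_multiply(quaternion_multiply(q, v), quaternion_conjugate(q))
  out[2:4]
}

#' Rotate points about an arbitrary axis, via quaternion conjugation
#'
#' @param points A 3-vector or an `n x 3` matrix of points.
#' @param axis_point A point on the rotation axis.
#' @param axis_dir Axis direction (non-zero; normalized internally).
#' @param angle Angle in radians (right-handed about `axis_dir`).
#' @return Rotated points, same shape as `points`.
#' @export
rotate_about_axis <- function(points, axis_point, axis_dir, angle) {
  q <- quaternion_from_axis_angle(axis_dir, angle)
  one <- is.null(dim(points))
  pts <- if (one) matrix(points, 1, 3) else points
  out <- t(apply(pts, 1, function(p) quaternion_rotate(p - axis_point, q) + axis_point))
  if (one) out[1, ] else out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(NULL)
  v / nrm
}

# deterministic unit vector orthogonal to v (fallback normal for collinear sets)
fallback_normal <- function(v) {
  u <- unit3(v)
  if (is.null(u)) return(c(0, 0, 1))
  ref <- if (abs(u[1]) <= abs(u[2]) && abs(u[1]) <= abs(u[3])) c(1, 0, 0)
         else if (abs(u[2]) <= abs(u[3])) c(0, 1, 0) else c(0, 0, 1)
  unit3(cross3(u, ref))
}

# normal of the plane through three points, deterministic fallback if collinear
plane_normal <- function(p1, p2, p3, warn = FALSE) {
  n <- cross3(p2 - p1, p3 - p1)
  u <- unit3(n)
  if (is.null(u)) {
    if (warn) warning("collinear points: using deterministic fallback plane")
    u <- fallback_normal(p3 - p1)
  }
  u
}

# signed dihedral angle from plane normal n1 to n2 about unit axis t, in (-pi, pi]
signed_dihedral <- function(n1, n2, t) {
  ang <- atan2(sum(cross3(n1, n2) * t), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

## ---- beads and chains ------------------------------------------------------

#' Construct a modified bead
#'
#' @param centroid,endpoint_in,endpoint_out 3D points in nm.
#' @param radius Approximate bead radius in nm (> 0).
#' @param span Genomic span `(start, end)` in bp.
#' @param payload Optional finer-scale chain represented by this bead, as
#'   stored by [summarize_chain_as_bead()].
#' @return An object of class `modified_bead`.
#' @export
modified_bead <- function(centroid, endpoint_in, endpoint_out, radius,
                          span = c(0, 0), payload = NULL) {
  if (radius <= 0) stop("bead radius must be > 0")
  structure(list(centroid = as.numeric(centroid),
                 endpoint_in = as.numeric(endpoint_in),
                 endpoint_out = as.numeric(endpoint_out),
                 radius = as.numeric(radius), span = as.numeric(span),
                 payload = payload),
            class = "modified_bead")
}

#' Assemble a bead chain
#'
#' Either pass `beads` (a list of [modified_bead()]s whose consecutive
#' endpoints coincide within 1e-6 nm) or the compact arrays directly.
#'
#' @param beads List of `modified_bead`s (alternative to the arrays).
#' @param centroids `n x 3` matrix of bead centroids (nm).
#' @param endpoints `(n+1) x 3` matrix of shared endpoints; row `k` is the
#'   in-endpoint of bead `k` and the out-endpoint of bead `k-1`.
#' @param radii Numeric vector of bead radii.
#' @param spans `n x 2` matrix of genomic spans (bp).
#' @param payloads Optional list of per-bead payloads (`NULL` entries allowed).
#' @param scale_level Integer scale level, 0 = finest.
#' @return An object of class `bead_chain`.
#' @export
new_chain <- function(beads = NULL, centroids = NULL, endpoints = NULL,
                      radii = NULL, spans = NULL, payloads = NULL,
                      scale_level = 0L) {
  if (!is.null(beads)) {
    n <- length(beads)
    if (n == 0) stop("empty bead list")
    centroids <- t(vapply(beads, `[[`, numeric(3), "centroid"))
    endpoints <- rbind(t(vapply(beads, `[[`, numeric(3), "endpoint_in")),
                       matrix(beads[[n]]$endpoint_out, 1, 3))
    for (k in seq_len(n - 1)) {
      gap <- sqrt(sum((beads[[k]]$endpoint_out - beads[[k + 1]]$endpoint_in)^2))
      if (gap > 1e-6)
        stop(sprintf("beads %d and %d do not share an endpoint (gap %.3g nm)", k, k + 1, gap))
    }
    radii <- vapply(beads, `[[`, 0, "radius")
    spans <- t(vapply(beads, `[[`, numeric(2), "span"))
    payloads <- lapply(beads, `[[`, "payload")
  }
  n <- nrow(centroids)
  if (is.null(spans)) spans <- cbind(seq_len(n) - 1, seq_len(n))
  if (is.null(payloads)) payloads <- vector("list", max(n, 0))
  stopifnot(nrow(endpoints) == n + 1, length(radii) == n)
  structure(list(centroids = unname(centroids), endpoints = unname(endpoints),
                 radii = as.numeric(radii), spans = unname(spans),
                 payloads = payloads, scale_level = as.integer(scale_level)),
            class = "bead_chain")
}

#' Number of beads in a chain
#' @param chain A `bead_chain`.
#' @export
chain_length <- function(chain) nrow(chain$centroids)

#' Extract one bead of a chain as a [modified_bead()]
#'
#' @param chain A `bead_chain`.
#' @param k Bead index, 1-based.
#' @export
chain_bead <- function(chain, k) {
  modified_bead(chain$centroids[k, ], chain$endpoints[k, ], chain$endpoints[k + 1, ],
                chain$radii[k], chain$spans[k, ], chain$payloads[[k]])
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain> %d beads, scale level %d, %d with payload\n",
              chain_length(x), x$scale_level,
              sum(!vapply(x$payloads, is.null, TRUE))))
  invisible(x)
}

#' Centroid pairwise distance matrix of a chain (nm)
#'
#' @param chain A `bead_chain`.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(chain) {
  if (chain_length(chain) == 0) stop("empty chain")
  unname(as.matrix(dist(chain$centroids)))
}

# apply rigid transform x -> R x + t to a chain, recursing into payload
# reference frames so later refinement stays consistent
transform_chain <- function(chain, R, t) {
  chain$centroids <- sweep(chain$centroids %*% t(R), 2, t, `+`)
  chain$endpoints <- sweep(chain$endpoints %*% t(R), 2, t, `+`)
  chain$payloads <- lapply(chain$payloads, function(p) {
    if (is.null(p)) return(NULL)
    p$ref <- sweep(p$ref %*% t(R), 2, t, `+`)
    p$chain <- transform_chain(p$chain, R, t)
    p
  })
  chain
}

# orthonormal frame (3x3, columns x/y/z) anchored at a point triple
triple_frame <- function(p1, p2, p3) {
  x <- unit3(p2 - p1)
  if (is.null(x)) x <- c(1, 0, 0)
  z <- unit3(cross3(x, p3 - p1))
  if (is.null(z)) z <- fallback_normal(x)
  y <- cross3(z, x)
  cbind(x, y, z)
}

# rigid transform (R, t) mapping point triple `from` (3x3, rows) onto `to`
rigid_from_triples <- function(from, to) {
  Fa <- triple_frame(from[1, ], from[2, ], from[3, ])
  Fb <- triple_frame(to[1, ], to[2, ], to[3, ])
  R <- Fb %*% t(Fa)
  list(R = R, t = to[1, ] - as.numeric(R %*% from[1, ]))
}

## ---- multiscale bead operations -------------------------------------------

#' Summarize a chain as a single coarser-scale bead
#'
#' The coarse bead keeps the chain's outer endpoints, takes the mean of the
#' member centroids as its centroid, and estimates its physical size as the
#' standard deviation along the first principal axis of the member centroids
#' (square root of the leading eigenvalue of their covariance), floored at
#' the largest member radius. The chain itself is stored as the payload,
#' together with the bead's reference triple, so it can be re-expanded by
#' [refine_chain()] after the coarse bead has been moved.
#'
#' @param chain A non-empty `bead_chain`.
#' @return A [modified_bead()] whose `payload` holds the chain.
#' @export
summarize_chain_as_bead <- function(chain) {
  n <- chain_length(chain)
  if (n == 0) stop("cannot summarize an empty chain")
  centroid <- colMeans(chain$centroids)
  e_in <- chain$endpoints[1, ]
  e_out <- chain$endpoints[n + 1, ]
  centred <- sweep(chain$centroids, 2, centroid)
  covm <- crossprod(centred) / n  # population covariance
  lead <- max(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0)
  radius <- max(sqrt(lead), max(chain$radii))
  ref <- rbind(e_in, centroid, e_out)
  dimnames(ref) <- NULL
  modified_bead(centroid, e_in, e_out, radius,
                span = c(chain$spans[1, 1], chain$spans[n, 2]),
                payload = list(chain = chain, ref = ref))
}

#' Relative pose of a bead with respect to its predecessor
#'
#' `zeta` is the signed dihedral between the previous bead's plane P1
#' (endpoints + centroid) and the hinge plane P12 (the two centroids + the
#' shared endpoint), measured about their common line C1-E12; `xi` is the
#' signed dihedral between P12 and the bead's own plane P2, measured about
#' their common line E12-C2. When `zeta = 0` the hinge plane coincides with
#' P1 and `xi` is exactly the angle between P1 and P2.
#'
#' @param previous_bead,bead Two consecutive placed [modified_bead()]s.
#' @return List with `zeta`, `xi`, `bend` (angle C1-E12-C2), radians.
#' @export
measure_pose <- function(previous_bead, bead) {
  C1 <- previous_bead$centroid; E12 <- previous_bead$endpoint_out
  C2 <- bead$centroid; E2 <- bead$endpoint_out
  n1 <- plane_normal(previous_bead$endpoint_in, C1, E12)
  t_axis <- unit3(E12 - C1); if (is.null(t_axis)) t_axis <- c(1, 0, 0)
  u_axis <- unit3(C2 - E12); if (is.null(u_axis)) u_axis <- t_axis
  # hinge and bead-plane normals oriented as place_bead() constructs them
  n12 <- unit3(cross3(u_axis, t_axis))
  if (is.null(n12)) n12 <- fallback_normal(t_axis)
  n2 <- plane_normal(E12, C2, E2)
  v1 <- unit3(C1 - E12); v2 <- unit3(C2 - E12)
  bend <- if (is.null(v1) || is.null(v2)) pi else acos(max(-1, min(1, sum(v1 * v2))))
  list(zeta = signed_dihedral(n1, n12, t_axis),
       xi = signed_dihedral(n12, n2, u_axis),
       bend = bend)
}

#' Place a bead after a previously placed bead, at a requested pose
#'
#' Rigidly moves `bead` so that its in-endpoint lands on `target_in` and its
#' orientation realizes the pose angles (see [measure_pose()] for the
#' conventions). The bead's internal geometry is untouched.
#'
#' @param bead The [modified_bead()] to place (its internal shape is reused).
#' @param target_in 3D point where the bead's in-endpoint must land; must
#'   equal `previous_bead$endpoint_out` for a connected chain.
#' @param pose List or vector with `zeta` and `xi` (radians).
#' @param previous_bead The already placed predecessor, or `NULL` for the
#'   first bead of a chain (canonical orientation: chain along +x, planes
#'   normal to +z).
#' @param bend Bend angle C1-E12-C2 in radians; a degree of freedom the pose
#'   angles leave free. Default `2*pi/3`.
#' @return The placed `modified_bead`.
#' @export
place_bead <- function(bead, target_in, pose, previous_bead = NULL,
                       bend = 2 * pi / 3) {
  pose <- as.list(pose)
  zeta <- pose$zeta %||% pose[[1]]
  xi <- pose$xi %||% pose[[2]]
  # local shape: distances from in-endpoint, and the fixed angle alpha at E_in
  a_c <- sqrt(sum((bead$centroid - bead$endpoint_in)^2))
  a_e <- sqrt(sum((bead$endpoint_out - bead$endpoint_in)^2))
  v_c <- bead$centroid - bead$endpoint_in
  v_e <- bead$endpoint_out - bead$endpoint_in
  alpha <- if (a_c < 1e-12 || a_e < 1e-12) 0 else
    acos(max(-1, min(1, sum(v_c * v_e) / (a_c * a_e))))

  if (is.null(previous_bead)) {
    t_axis <- c(1, 0, 0); n1 <- c(0, 0, 1); C1 <- target_in - t_axis
  } else {
    C1 <- previous_bead$centroid
    t_axis <- unit3(target_in - C1)
    if (is.null(t_axis)) t_axis <- c(1, 0, 0)
    n1 <- plane_normal(previous_bead$endpoint_in, C1, previous_bead$endpoint_out,
                       warn = TRUE)
    # ensure the reference normal is orthogonal to the dihedral axis
    n1 <- unit3(n1 - sum(n1 * t_axis) * t_axis)
    if (is.null(n1)) n1 <- fallback_normal(t_axis)
  }
  n12 <- as.numeric(rotate_about_axis(n1, c(0, 0, 0), t_axis, zeta))
  # centroid direction: rotate the backward direction within the hinge plane
  # so that angle C1-E12-C2 equals `bend` (bend = pi means straight)
  dir_c <- as.numeric(rotate_about_axis(-t_axis, c(0, 0, 0), n12, bend))
  C2 <- target_in + a_c * dir_c
  u_axis <- unit3(C2 - target_in)
  n2 <- as.numeric(rotate_about_axis(n12, c(0, 0, 0), u_axis, xi))
  w <- cross3(n2, u_axis)
  E2 <- target_in + a_e * (cos(alpha) * u_axis + sin(alpha) * w)
  placed <- rigid_from_triples(rbind(bead$endpoint_in, bead$centroid, bead$endpoint_out),
                               rbind(target_in, C2, E2))
  out <- bead
  out$endpoint_in <- target_in
  out$centroid <- C2
  out$endpoint_out <- E2
  if (!is.null(bead$payload)) {
    out$payload <- list(
      ref = sweep(bead$payload$ref %*% t(placed$R), 2, placed$t, `+`),
      chain = transform_chain(bead$payload$chain, placed$R, placed$t))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a coarse chain into the chain at the next finer scale
#'
#' Every bead must carry a payload (stored by [summarize_chain_as_bead()]);
#' each payload chain is rigidly transported by the transform that maps the
#' bead's stored reference triple onto its current placement, and the
#' transported payloads are concatenated.
#'
#' @param coarse_chain A `bead_chain` whose beads all have payloads.
#' @return The finer-scale `bead_chain`.
#' @export
refine_chain <- function(coarse_chain) {
  n <- chain_length(coarse_chain)
  pieces <- vector("list", n)
  for (k in seq_len(n)) {
    p <- coarse_chain$payloads[[k]]
    if (is.null(p)) stop(sprintf("bead %d has no payload to refine", k))
    cur <- rbind(coarse_chain$endpoints[k, ], coarse_chain$centroids[k, ],
                 coarse_chain$endpoints[k + 1, ])
    tr <- rigid_from_triples(p$ref, cur)
    pieces[[k]] <- transform_chain(p$chain, tr$R, tr$t)
  }
  centroids <- do.call(rbind, lapply(pieces, `[[`, "centroids"))
  radii <- unlist(lapply(pieces, `[[`, "radii"))
  spans <- do.call(rbind, lapply(pieces, `[[`, "spans"))
  payloads <- do.call(c, lapply(pieces, `[[`, "payloads"))
  # drop the duplicated junction endpoints (out of piece k == in of piece k+1
  # within tolerance; keep piece k's copy)
  eps <- lapply(pieces, `[[`, "endpoints")
  endpoints <- eps[[1]]
  if (n > 1) for (k in 2:n) endpoints <- rbind(endpoints, eps[[k]][-1, , drop = FALSE])
  new_chain(centroids = centroids, endpoints = endpoints, radii = radii,
            spans = spans, payloads = payloads,
            scale_level = pieces[[1]]$scale_level)
}
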