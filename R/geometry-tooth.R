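# Parametric lower-second-premolar generator: implicit multi-tissue solid,
# structured voxel-to-tet meshing, occlusal surface + antagonist, wear operator.
#
# Coordinates: x lingual->buccal, y inferior->superior (tooth long axis),
# z mesial->distal; origin at the cervix centroid. Units mm.

# depth of the alveolar crest below the cervix (mm); biologic-width analog
ALVEOLAR_CREST_DEPTH <- 1.0

#' Parameters of the synthetic premolar
#'
#' A two-cusp lower second premolar: conical cusp lobes over a cylindrical
#' crown base, tapered root, pulp chamber + canal, periodontal ligament shell
#' and an alveolar bone block with planar mesial/distal cut faces. Occlusal
#' wear is modelled as a planar truncation of the crown a depth `wear_depth`
#' below the unworn buccal cusp tip.
#'
#' @param crown_height crown height above the cervix, mm (upper bound for
#'   wear_depth).
#' @param buccal_cusp_height buccal (protoconid) cusp tip height above the
#'   cervix, mm; the tallest point of the crown.
#' @param lingual_cusp_height lingual (metaconid) cusp tip height, mm.
#' @param buccal_cusp_slope cusp flank inclination, degrees from the occlusal
#'   plane, in (0, 85).
#' @param cervix_radius crown/cervix radius, mm.
#' @param root_length root length below the cervix, mm.
#' @param enamel_thickness occlusal enamel cap thickness, mm (lateral walls
#'   are 0.75 of this).
#' @param pulp_radius pulp chamber/canal radius, mm.
#' @param pdl_thickness periodontal ligament thickness, mm (0.2-0.3 typical).
#' @param bone_block (x, y, z) dimensions of the alveolar bone block, mm; its
#'   top face sits 1 mm below the cervix and the z faces are the mesial and
#'   distal cuts.
#' @param wear_depth occlusal truncation depth, mm, `0 <= wear_depth <
#'   crown_height`.
#' @param mesh_size target element edge length, mm.
#' @param seed integer; recorded for provenance (the generator itself is
#'   deterministic).
#' @return validated list of class `tooth_params`.
#' @export
tooth_params <- function(crown_height = 8,
                         buccal_cusp_height = 8,
                         lingual_cusp_height = 7.2,
                         buccal_cusp_slope = 55,
                         cervix_radius = 4,
                         root_length = 12,
                         enamel_thickness = 1.2,
                         pulp_radius = 1.0,
                         pdl_thickness = 0.25,
                         bone_block = c(12, 13, 10),
                         wear_depth = 0,
                         mesh_size = 0.8,
                         seed = 1L) {
  p <- list(crown_height = crown_height,
            buccal_cusp_height = buccal_cusp_height,
            lingual_cusp_height = lingual_cusp_height,
            buccal_cusp_slope = buccal_cusp_slope,
            cervix_radius = cervix_radius,
            root_length = root_length,
            enamel_thickness = enamel_thickness,
            pulp_radius = pulp_radius,
            pdl_thickness = pdl_thickness,
            bone_block = bone_block,
            wear_depth = wear_depth,
            mesh_size = mesh_size,
            seed = as.integer(seed))
  class(p) <- "tooth_params"
  validate_tooth_params(p)
  p
}

validate_tooth_params <- function(p) {
  lens <- c("crown_height", "buccal_cusp_height", "lingual_cusp_height",
            "cervix_radius", "root_length", "enamel_thickness", "pulp_radius",
            "pdl_thickness", "mesh_size")
  for (f in lens) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("tooth_params: field '", f, "' must be a positive scalar")
    }
  }
  if (!is.numeric(p$bone_block) || length(p$bone_block) != 3 ||
      any(p$bone_block <= 0)) {
    stop("tooth_params: field 'bone_block' must be three positive lengths")
  }
  if (!is.numeric(p$wear_depth) || length(p$wear_depth) != 1 ||
      p$wear_depth < 0) {
    stop("tooth_params: field 'wear_depth' must be >= 0")
  }
  if (p$wear_depth >= p$crown_height) {
    stop("tooth_params: field 'wear_depth' must be < crown_height")
  }
  if (p$buccal_cusp_slope <= 0 || p$buccal_cusp_slope >= 85) {
    stop("tooth_params: field 'buccal_cusp_slope' must lie in (0, 85) degrees")
  }
  if (p$enamel_thickness >= p$cervix_radius) {
    stop("tooth_params: field 'enamel_thickness' must be < cervix_radius")
  }
  if (p$buccal_cusp_height > p$crown_height + 1e-12) {
    stop("tooth_params: field 'buccal_cusp_height' must be <= crown_height")
  }
  invisible(TRUE)
}

#' Set the wear depth of a tooth
#'
#' The computational analog of grinding antagonist crowns in a dental
#' articulator: the crown is truncated `wear_depth` below the unworn buccal
#' cusp tip. The derived Smith wear stage (see [smith_stage()]) stays
#' consistent: dentine becomes exposed exactly when the truncation plane cuts
#' below the enamel cap at the cusp tip.
#'
#' @param params a [tooth_params()] object.
#' @param wear_depth new occlusal truncation depth, mm.
#' @return the updated `tooth_params`.
#' @export
apply_wear <- function(params, wear_depth) {
  stopifnot(inherits(params, "tooth_params"))
  if (!is.numeric(wear_depth) || length(wear_depth) != 1 || wear_depth < 0) {
    stop("apply_wear: wear_depth must be a scalar >= 0")
  }
  if (wear_depth >= params$crown_height) {
    stop("apply_wear: wear_depth must be < crown_height")
  }
  params$wear_depth <- wear_depth
  validate_tooth_params(params)
  params
}

#' Smith ordinal wear stage of a wear depth
#'
#' Stage bands relative to the occlusal enamel cap thickness `e`:
#' stage 1 for depth <= 0.25 e (slight facets), stage 2 for depth <= e
#' (coalescing facets, down to the enamel-dentine junction), stage 3 beyond
#' (dentine exposed at the protoconid tip).
#'
#' @param params a [tooth_params()] object (uses its wear_depth), or a numeric
#'   wear depth together with `enamel_thickness`.
#' @param enamel_thickness required when `params` is numeric.
#' @return list with `stage` (1, 2 or 3) and `dentine_exposed` (logical).
#' @export
smith_stage <- function(params, enamel_thickness = NULL) {
  if (inherits(params, "tooth_params")) {
    wd <- params$wear_depth; e <- params$enamel_thickness
  } else {
    wd <- params; e <- enamel_thickness
    if (is.null(e)) stop("smith_stage: enamel_thickness required")
  }
  stage <- if (wd <= 0.25 * e) 1L else if (wd <= e) 2L else 3L
  list(stage = stage, dentine_exposed = wd > e)
}

#' Representative wear depth for a Smith stage
#'
#' Maps the ordinal stage to a depth inside its band: 0.2, 0.75 and 1.4 times
#' the occlusal enamel thickness for stages 1, 2 and 3.
#'
#' @param stage integer in 1:3.
#' @param params a [tooth_params()] (for the enamel thickness).
#' @return wear depth in mm.
#' @export
stage_wear_depth <- function(stage, params) {
  stopifnot(stage %in% 1:3)
  c(0.2, 0.75, 1.4)[stage] * params$enamel_thickness
}

# --- implicit model -------------------------------------------------------

# unworn occlusal height field over the crown footprint: max of two cusp
# cones plus a fossa floor
occlusal_height_unworn <- function(x, z, p) {
  s <- tan(p$buccal_cusp_slope * pi / 180)
  xb <- cusp_offset(p)
  hb <- p$buccal_cusp_height - s * sqrt((x - xb)^2 + z^2)
  hl <- p$lingual_cusp_height - s * sqrt((x + xb)^2 + z^2)
  floor_h <- 0.35 * p$crown_height
  pmax(hb, hl, floor_h)
}

# cusp tip offset from the tooth axis. Kept small: the buccal cusp tip of a
# lower premolar rides nearly over the root axis (lingually tilted crown),
# so its buccal slope faces outward well beyond the tip.
cusp_offset <- function(p) 0.2 * p$cervix_radius

# worn occlusal surface: planar truncation below the unworn buccal cusp tip
occlusal_height <- function(x, z, p) {
  pmin(occlusal_height_unworn(x, z, p), p$buccal_cusp_height - p$wear_depth)
}

# root radius profile for y in [-root_length, 0]
root_radius <- function(y, p) {
  p$cervix_radius * (1 - 0.8 * pmin(pmax(-y / p$root_length, 0), 1))
}

# pulp radius profile (chamber into the crown, canal down the root)
pulp_profile <- function(y, p) {
  rl <- p$root_length; ch <- p$crown_height
  up <- 0.3 * ch      # pulp horn tip height
  lo <- -0.85 * rl    # canal end
  r <- rep(0, length(y))
  full <- y >= -0.6 * rl & y <= 0.15 * ch
  r[full] <- p$pulp_radius
  upper <- y > 0.15 * ch & y < up
  r[upper] <- p$pulp_radius * (up - y[upper]) / (up - 0.15 * ch)
  lower <- y < -0.6 * rl & y > lo
  r[lower] <- p$pulp_radius * (y[lower] - lo) / (-0.6 * rl - lo)
  r
}

#' Classify points into tissue regions
#'
#' Evaluates the implicit multi-tissue model at arbitrary points.
#'
#' @param pts q x 3 matrix of coordinates (mm).
#' @param params a [tooth_params()].
#' @return character vector: ENAMEL, DENTINE, PULP, PDL, BONE or NA (outside).
#' @export
classify_tissue <- function(pts, params) {
  p <- params
  pts <- matrix(pts, ncol = 3)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  r <- sqrt(x^2 + z^2)
  out <- rep(NA_character_, nrow(pts))

  crest <- -ALVEOLAR_CREST_DEPTH
  R <- p$cervix_radius
  occ <- occlusal_height(x, z, p)
  edj <- occlusal_height_unworn(x, z, p) - p$enamel_thickness
  e_lat <- 0.75 * p$enamel_thickness
  pulp_r <- pulp_profile(y, p)

  in_crown <- y >= 0 & y <= occ & r <= R
  in_root <- y < 0 & y >= -p$root_length & r <= root_radius(y, p)

  # crown: enamel shell above the EDJ or along the lateral wall; dentine core
  is_enamel <- in_crown & (y > edj | r > R - e_lat)
  is_pulp <- (in_crown | in_root) & r <= pulp_r & !is_enamel
  is_dentine <- (in_crown | in_root) & !is_enamel & !is_pulp

  # periodontal ligament shell around (and under) the root, below the crest
  rr_pdl <- root_radius(pmax(y, -p$root_length), p) + p$pdl_thickness
  in_pdl <- !in_root & y <= crest & y >= -p$root_length - p$pdl_thickness &
    r <= rr_pdl

  bb <- p$bone_block
  in_bone <- !in_root & !in_pdl &
    abs(x) <= bb[1] / 2 & abs(z) <= bb[3] / 2 &
    y <= crest & y >= crest - bb[2]

  out[in_bone] <- "BONE"
  out[in_pdl] <- "PDL"
  out[is_dentine] <- "DENTINE"
  out[is_pulp] <- "PULP"
  out[is_enamel] <- "ENAMEL"
  out
}

# --- structured voxel-to-tet meshing --------------------------------------

# Kuhn 6-tet subdivision of the unit cube along the (0,0,0)-(1,1,1) diagonal.
# Corners indexed 1..8 as (i,j,k) bits: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0)
# 4=(1,1,0) 5=(0,0,1) 6=(1,0,1) 7=(0,1,1) 8=(1,1,1). All tets positively
# oriented and conforming across neighbouring cells.
KUHN_TETS <- matrix(c(
  1L, 2L, 4L, 8L,
  1L, 4L, 3L, 8L,
  1L, 3L, 7L, 8L,
  1L, 7L, 5L, 8L,
  1L, 5L, 6L, 8L,
  1L, 6L, 2L, 8L), ncol = 4, byrow = TRUE)

# structured tet4 grid over a box; returns nodes, elements and grid info
box_tet4_grid <- function(lo, hi, h) {
  n <- pmax(1L, as.integer(ceiling((hi - lo) / h - 1e-9)))
  xs <- seq(lo[1], hi[1], length.out = n[1] + 1)
  ys <- seq(lo[2], hi[2], length.out = n[2] + 1)
  zs <- seq(lo[3], hi[3], length.out = n[3] + 1)
  nid <- function(i, j, k) {  # 1-based grid indices -> node id
    (k - 1L) * (n[1] + 1L) * (n[2] + 1L) + (j - 1L) * (n[1] + 1L) + i
  }
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  # corner ids for every cell, vectorized
  cells <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]), k = seq_len(n[3]))
  i <- cells$i; j <- cells$j; k <- cells$k
  corn <- cbind(nid(i, j, k), nid(i + 1L, j, k), nid(i, j + 1L, k),
                nid(i + 1L, j + 1L, k), nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                nid(i, j + 1L, k + 1L), nid(i + 1L, j + 1L, k + 1L))
  nc <- nrow(corn)
  elements <- matrix(0L, 6L * nc, 4)
  for (t in seq_len(6)) {
    elements[seq(t, by = 6L, length.out = nc), ] <- corn[, KUHN_TETS[t, ], drop = FALSE]
  }
  list(nodes = nodes, elements = elements)
}

#' Generate the multi-tissue premolar model
#'
#' Builds the 10-node tetrahedral volume mesh (tooth, periodontal ligament and
#' alveolar bone block), the analytic crown surface, and the antagonist
#' occlusal surface positioned above the crown at a 0.5 mm standoff.
#'
#' The voxel grid spans the full unworn model for every wear depth, so meshes
#' of different wear states of the same tooth share their node lattice below
#' the truncation plane (parametric homology for cervical sampling).
#'
#' Node sets: MESIAL_CUT and DISTAL_CUT (bone faces at z = -/+ bone_block/2),
#' OCCLUSAL_SURFACE (upward-facing tooth boundary nodes), BUCCAL_CERVIX
#' (tooth boundary nodes in the +/-0.5 mm band around the cervix on the buccal
#' half). Occlusal boundary faces are kept on the mesh (`occlusal_faces`) for
#' load mapping.
#'
#' @param params a [tooth_params()].
#' @return list of class `tooth_model`: `volume` (volume_mesh), `crown`
#'   (surface_mesh), `antagonist` (surface_mesh), `params`, `wear`
#'   (Smith stage info).
#' @export
generate_tooth <- function(params) {
  stopifnot(inherits(params, "tooth_params"))
  p <- params
  bb <- p$bone_block
  crest <- -ALVEOLAR_CREST_DEPTH
  lo <- c(-bb[1] / 2, crest - bb[2], -bb[3] / 2)
  hi <- c(bb[1] / 2, p$buccal_cusp_height, bb[3] / 2)  # unworn top: fixed grid

  grid <- box_tet4_grid(lo, hi, p$mesh_size)
  cen <- tet4_centroids(grid$nodes, grid$elements)
  reg <- classify_tissue(cen, p)
  keep <- !is.na(reg)
  el <- grid$elements[keep, , drop = FALSE]
  reg <- reg[keep]

  # ensure a contiguous PDL shell: bone tets sharing a face with root dentine
  reg <- pdl_adjacency_pass(el, reg, grid$nodes)

  # drop orphan nodes, renumber
  used <- sort(unique(as.vector(el)))
  remap <- integer(nrow(grid$nodes)); remap[used] <- seq_along(used)
  el <- matrix(remap[el], nrow(el), 4)
  nodes <- grid$nodes[used, , drop = FALSE]

  mesh <- linear_to_quadratic(nodes, el, region = reg)
  mesh$h <- p$mesh_size
  mesh <- add_tooth_node_sets(mesh, p)

  crown <- crown_surface(p)
  antag <- antagonist_surface(p)
  structure(list(volume = mesh, crown = crown, antagonist = antag,
                 params = p, wear = smith_stage(p)),
            class = "tooth_model")
}

tet4_centroids <- function(nodes, elements) {
  (nodes[elements[, 1], , drop = FALSE] + nodes[elements[, 2], , drop = FALSE] +
     nodes[elements[, 3], , drop = FALSE] + nodes[elements[, 4], , drop = FALSE]) / 4
}

# retag BONE tets that share a face with a root DENTINE tet as PDL, so the
# ligament is at least one element thick even when thinner than the grid
pdl_adjacency_pass <- function(el, reg, nodes) {
  ne <- nrow(el)
  faces <- matrix(0L, 4L * ne, 3)
  fo <- rep(seq_len(ne), each = 4L)
  pat <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  for (f in 1:4) {
    faces[seq(f, by = 4L, length.out = ne), ] <- el[, pat[f, ], drop = FALSE]
  }
  key <- face_sort_key(faces, max(el))
  ord <- order(key)
  k <- key[ord]; own <- fo[ord]
  same <- which(k[-1] == k[-length(k)])
  a <- own[same]; b <- own[same + 1L]
  crest <- -ALVEOLAR_CREST_DEPTH
  cen_y <- tet4_centroids(nodes, el)[, 2]
  is_root_dent <- reg == "DENTINE" & cen_y < crest
  retag <- c(a[reg[a] == "BONE" & is_root_dent[b]],
             b[reg[b] == "BONE" & is_root_dent[a]])
  reg[unique(retag)] <- "PDL"
  reg
}

add_tooth_node_sets <- function(mesh, p) {
  bf <- boundary_faces(mesh)
  tol <- 1e-6
  z_lo <- -p$bone_block[3] / 2; z_hi <- p$bone_block[3] / 2
  nd <- mesh$nodes
  mesial <- which(abs(nd[, 3] - z_lo) < tol)
  distal <- which(abs(nd[, 3] - z_hi) < tol)

  tooth_face <- mesh$region[bf$element] %in% c("ENAMEL", "DENTINE")
  occl <- tooth_face & bf$normal[, 2] > 0.3 & bf$centroid[, 2] > 0.5
  occ_nodes <- sort(unique(as.vector(bf$faces[occl, , drop = FALSE])))

  lat_nodes <- unique(as.vector(bf$faces[tooth_face & !occl, , drop = FALSE]))
  yy <- nd[lat_nodes, 2]; xx <- nd[lat_nodes, 1]
  cerv <- sort(lat_nodes[abs(yy) <= 0.5 & xx > 0.1])

  mesh$node_sets <- list(MESIAL_CUT = mesial, DISTAL_CUT = distal,
                         OCCLUSAL_SURFACE = occ_nodes, BUCCAL_CERVIX = cerv)
  mesh$occlusal_faces <- lapply(
    list(faces = bf$faces, element = bf$element, centroid = bf$centroid,
         normal = bf$normal, area = bf$area),
    function(v) if (is.matrix(v)) v[occl, , drop = FALSE] else v[occl])
  validate_volume_mesh(mesh)
  mesh
}

# --- analytic crown and antagonist surfaces -------------------------------

# wear-facet windows on the cusp flanks, in the (x, z) plane: fixed disks on
# the buccal cusp outer slope and the distal/mesial marginal ridges (the
# mesial facet appears once facets start to coalesce, Smith stage >= 2)
facet_windows <- function(p) {
  R <- p$cervix_radius
  xb <- cusp_offset(p)
  # buccal facet on the outer (buccal-facing) slope of the buccal cusp, just
  # below the tip, where the antagonist overlaps the lower crown buccally;
  # its perpendicular load points linguo-apically -- the non-axial component
  # that bends the crown lingually and tenses the buccal cervical margin
  w <- data.frame(
    cx = c(xb + 0.18 * R, 0.35, 0.35),
    cz = c(0, 0.62 * R, -0.62 * R),
    radius = c(0.9, 0.25, 0.22),
    label = c("buccal_facet", "distal_facet", "mesial_facet"),
    stringsAsFactors = FALSE)
  if (smith_stage(p)$stage < 2) w <- w[1:2, ]
  w
}

# gap field of the antagonist above the worn occlusal surface: ~0 over the
# slope facet windows AND over the worn plateau (attrition grinds antagonist
# pairs flat against each other, so the whole truncated table is a facet);
# g0 elsewhere. Cosine-squared falloffs keep the field smooth.
antagonist_gap <- function(x, z, p, g0 = 0.35, blend = 0.6, blend_h = 0.3) {
  w <- facet_windows(p)
  wmax <- rep(0, length(x))
  for (k in seq_len(nrow(w))) {
    d <- sqrt((x - w$cx[k])^2 + (z - w$cz[k])^2)
    s <- pmax(d - w$radius[k], 0)
    wk <- ifelse(s >= blend, 0, cos(pi * s / (2 * blend))^2)
    wmax <- pmax(wmax, wk)
  }
  # plateau window: closed wherever the unworn relief rises above the
  # truncation plane (the ground-flat area), fading over blend_h of height
  s <- pmax((p$buccal_cusp_height - p$wear_depth) - occlusal_height_unworn(x, z, p), 0)
  wp <- ifelse(s >= blend_h, 0, cos(pi * s / (2 * blend_h))^2)
  wmax <- pmax(wmax, wp)
  g0 * (1 - wmax)
}

# polar triangulated grid over the crown footprint; f(x, z) gives the height
polar_heightfield <- function(p, f, n_theta = 64, n_r = 24, flip = FALSE) {
  R <- p$cervix_radius
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  rr <- seq(0, R, length.out = n_r + 1)[-1]
  ctr <- c(0, f(0, 0), 0)
  ring <- as.matrix(expand.grid(r = rr, t = th))
  xs <- ring[, 1] * cos(ring[, 2]); zs <- ring[, 1] * sin(ring[, 2])
  verts <- rbind(ctr, cbind(xs, f(xs, zs), zs))
  dimnames(verts) <- NULL
  vid <- function(ir, it) 1L + (((it - 1L) %% n_theta)) * n_r + ir
  tris <- list()
  # centre fan
  it <- seq_len(n_theta)
  tris[[1]] <- cbind(1L, vid(1L, it), vid(1L, it + 1L))
  for (ir in seq_len(n_r - 1)) {
    a <- vid(ir, it); b <- vid(ir + 1L, it)
    a2 <- vid(ir, it + 1L); b2 <- vid(ir + 1L, it + 1L)
    tris[[ir + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  tri <- do.call(rbind, tris)
  # as built, normals point downward (-y); flip = FALSE means upward normals
  if (!flip) tri <- tri[, c(1, 3, 2)]
  list(vertices = verts, triangles = tri, n_theta = n_theta, n_r = n_r)
}

#' Analytic crown surface of the (possibly worn) lower premolar
#'
#' Polar-grid triangulation of the occlusal height field plus a lateral skirt
#' down to the cervix plane. Facet labels distinguish OCCLUSAL from WALL
#' triangles. Normals point out of the tooth (upward on the occlusal table).
#'
#' @param params a [tooth_params()].
#' @param n_theta,n_r angular and radial resolution of the polar grid.
#' @return a `surface_mesh`.
#' @export
crown_surface <- function(params, n_theta = 64, n_r = 24) {
  p <- params
  hf <- polar_heightfield(p, function(x, z) occlusal_height(x, z, p),
                          n_theta, n_r)
  nv <- nrow(hf$vertices)
  # skirt: rim ring duplicated at y = 0
  rim_id <- 1L + ((seq_len(hf$n_theta) - 1L)) * hf$n_r + hf$n_r
  rim <- hf$vertices[rim_id, , drop = FALSE]
  base <- cbind(rim[, 1], 0, rim[, 3])
  verts <- rbind(hf$vertices, base)
  it <- seq_len(hf$n_theta); itn <- c(seq_len(hf$n_theta)[-1], 1L)
  a <- rim_id[it]; b <- rim_id[itn]
  a0 <- nv + it; b0 <- nv + itn
  skirt <- rbind(cbind(a, b0, a0), cbind(a, b, b0))  # outward radial normals
  tri <- rbind(hf$triangles, skirt)
  labels <- c(rep("OCCLUSAL", nrow(hf$triangles)), rep("WALL", nrow(skirt)))
  surface_mesh(verts, tri, facet_labels = labels)
}

#' Antagonist occlusal surface
#'
#' The upper-tooth occlusal surface is modelled as the complement of the worn
#' lower crown: the lower height field raised by a gap field that closes to
#' zero over the wear-facet windows (buccal cusp flank, distal margin, and a
#' mesial facet from Smith stage 2 on), plus a 0.5 mm approach standoff.
#' Triangles wind so normals face downward (out of the upper tooth).
#'
#' @param params a [tooth_params()].
#' @param standoff initial separation above maximum intercuspation, mm.
#' @param n_theta,n_r grid resolution.
#' @return a `surface_mesh`.
#' @export
antagonist_surface <- function(params, standoff = 0.5, n_theta = 64, n_r = 24) {
  p <- params
  f <- function(x, z) {
    occlusal_height(x, z, p) + antagonist_gap(x, z, p) + standoff
  }
  hf <- polar_heightfield(p, f, n_theta, n_r, flip = TRUE)
  surface_mesh(hf$vertices, hf$triangles,
               facet_labels = rep("ANTAGONIST", nrow(hf$triangles)))
}

#' @export
print.tooth_model <- function(x, ...) {
  s <- x$wear
  cat(sprintf("synthetic premolar: wear depth %.2f mm (Smith stage %d%s)\n",
              x$params$wear_depth, s$stage,
              if (s$dentine_exposed) ", dentine exposed" else ""))
  print(x$volume)
  invisible(x)
}
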