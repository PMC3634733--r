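# Comparison stage: homologous buccal-cervical sampling, wear-state
# comparison, anatomical-zone stress summaries.

#' Sample homologous nodes along the buccal cervical margin
#'
#' Picks the nodes of the BUCCAL_CERVIX set nearest to `n` equally spaced
#' parametric positions along the buccal cervix arc (azimuth about the tooth
#' axis, mapped to [0, 1] across the buccal half). Deterministic: distance
#' ties break to the lowest node id. Because the positions are parametric,
#' samples from different wear states of the same tooth are homologous.
#'
#' @param mesh a `volume_mesh` with a BUCCAL_CERVIX node set.
#' @param n number of sample nodes (10 by convention for cervical profiles).
#' @return object of class `cervical_sample`: data.frame with `node`,
#'   `arc_position` (strictly increasing), `x`, `y`, `z`.
#' @export
sample_cervical_nodes <- function(mesh, n = 10) {
  set <- mesh$node_sets$BUCCAL_CERVIX
  if (is.null(set) || !length(set)) {
    stop("sample_cervical_nodes: BUCCAL_CERVIX node set is empty")
  }
  if (length(set) < n) {
    stop("sample_cervical_nodes: only ", length(set),
         " cervix nodes available for ", n, " samples")
  }
  nd <- mesh$nodes[set, , drop = FALSE]
  theta <- atan2(nd[, 3], nd[, 1])          # buccal = +x => theta ~ 0
  arc <- (theta + pi / 2) / pi              # mesial end 0, distal end 1
  targets <- (seq_len(n) - 0.5) / n
  chosen <- integer(n)
  avail <- rep(TRUE, length(set))
  for (i in seq_len(n)) {
    d <- abs(arc - targets[i])
    d[!avail] <- Inf
    # nearest available; ties to lowest node id
    best <- which(d < min(d) + 1e-12)
    best <- best[which.min(set[best])]
    chosen[i] <- best
    avail[best] <- FALSE
  }
  df <- data.frame(node = set[chosen], arc_position = arc[chosen],
                   x = nd[chosen, 1], y = nd[chosen, 2], z = nd[chosen, 3])
  df <- df[order(df$arc_position, df$node), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cervical_sample", "data.frame")
  df
}

#' Maximum principal stress at cervical sample nodes
#'
#' Reads sigma1 at the sampled nodes from the ENAMEL region average when the
#' node touches enamel (the cervical margin is the enamel edge), falling back
#' to the node's dominant region otherwise. When `mesh` is supplied, each
#' sampled value is the mean over the cervix-band nodes within `radius` of
#' the sample point: single-node values at the bimaterial cervical edge are
#' recovery-noise prone on coarse voxel boundaries, and the small-band mean
#' is the mesh-stable reading.
#'
#' @param sample a `cervical_sample`.
#' @param stress a `stress_field`.
#' @param mesh optional `volume_mesh` (enables band averaging over its
#'   BUCCAL_CERVIX node set).
#' @param radius band-averaging radius, mm; defaults to the mesh edge length.
#' @return the sample with a `sigma1` column (MPa).
#' @export
cervical_sigma1 <- function(sample, stress, mesh = NULL, radius = NULL) {
  node_s1 <- function(nodes) {
    s1 <- stress$principal[nodes, 1]
    en <- stress$by_region$ENAMEL
    if (!is.null(en)) {
      ix <- match(nodes, en$nodes)
      hit <- !is.na(ix)
      s1[hit] <- en$principal[ix[hit], 1]
    }
    as.numeric(s1)
  }
  if (is.null(mesh)) {
    sample$sigma1 <- node_s1(sample$node)
    return(sample)
  }
  if (is.null(radius)) radius <- if (!is.null(mesh$h)) mesh$h else 1
  pool <- mesh$node_sets$BUCCAL_CERVIX
  pool_xyz <- mesh$nodes[pool, , drop = FALSE]
  pool_s1 <- node_s1(pool)
  sample$sigma1 <- vapply(seq_len(nrow(sample)), function(i) {
    d2 <- (pool_xyz[, 1] - sample$x[i])^2 + (pool_xyz[, 2] - sample$y[i])^2 +
      (pool_xyz[, 3] - sample$z[i])^2
    mean(pool_s1[d2 <= radius^2])
  }, numeric(1))
  sample
}

#' Compare two wear states at homologous cervical nodes
#'
#' @param state_a,state_b lists with elements `sample` (a `cervical_sample`
#'   carrying `sigma1`) and `load_case`; conventionally a = less worn,
#'   b = more worn.
#' @return object of class `wear_comparison`: per-position sigma1 pairs and
#'   deltas (a minus b), their mean and max, and the load obliquity (degrees
#'   between each state's resultant and the tooth long axis).
#' @export
compare_wear_states <- function(state_a, state_b) {
  sa <- state_a$sample; sb <- state_b$sample
  if (nrow(sa) != nrow(sb)) {
    stop("compare_wear_states: sample sizes differ")
  }
  if (max(abs(sa$arc_position - sb$arc_position)) > 1e-9) {
    stop("compare_wear_states: arc positions do not match (samples are not homologous)")
  }
  if (is.null(sa$sigma1) || is.null(sb$sigma1)) {
    stop("compare_wear_states: samples lack sigma1 (run cervical_sigma1 first)")
  }
  delta <- sa$sigma1 - sb$sigma1
  structure(list(
    table = data.frame(arc_position = sa$arc_position,
                       sigma1_a = sa$sigma1, sigma1_b = sb$sigma1,
                       delta = delta),
    mean_delta = mean(delta),
    max_delta = max(delta),
    mean_sigma1 = c(a = mean(sa$sigma1), b = mean(sb$sigma1)),
    load_obliquity = c(a = load_obliquity(state_a$load_case),
                       b = load_obliquity(state_b$load_case))),
    class = "wear_comparison")
}

#' Obliquity of a load case
#'
#' Angle between the resultant force and the tooth long axis (y), in degrees;
#' 0 means a purely axial (apically directed) load.
#'
#' @param load_case a `load_case`.
#' @return angle in degrees.
#' @export
load_obliquity <- function(load_case) {
  r <- load_case$resultant
  nr <- sqrt(sum(r^2))
  if (nr == 0) return(0)
  acos(min(abs(r[2]) / nr, 1)) * 180 / pi
}

# anatomical zone membership for tooth-surface nodes
ZONE_NAMES <- c("buccal_cervix", "lingual_cervix", "mesial_side",
                "distal_side", "root_apex")

# nodes on the outer tooth surface (crown boundary + root/PDL interface),
# excluding the pulp chamber walls
tooth_surface_nodes <- function(mesh) {
  tooth_el <- which(mesh$region %in% c("ENAMEL", "DENTINE"))
  bf <- boundary_faces(mesh, tooth_el)
  keep <- rep(TRUE, nrow(bf$faces))
  pulp_el <- which(mesh$region == "PULP")
  if (length(pulp_el)) {
    pf <- boundary_faces(mesh, pulp_el)
    pulp_keys <- face_sort_key(pf$faces[, 1:3, drop = FALSE], nrow(mesh$nodes))
    keys <- face_sort_key(bf$faces[, 1:3, drop = FALSE], nrow(mesh$nodes))
    keep <- !(keys %in% pulp_keys)
  }
  sort(unique(as.vector(bf$faces[keep, , drop = FALSE])))
}

#' Per-zone stress summary (stress pattern report)
#'
#' Summarizes the nodal stress field over five anatomical zones of the tooth
#' surface: buccal and lingual cervical bands (|y| <= 0.5 mm around the
#' cervix, +/-45 degrees of azimuth about the respective direction), mesial
#' and distal flanks (azimuth bands over crown base and upper root), and the
#' root apex (deepest quarter of the root). Zones contain boundary nodes of
#' enamel/dentine elements only.
#'
#' @param stress a `stress_field`.
#' @param mesh the `volume_mesh` it was computed on.
#' @param root_length root length (mm) used for the apex band; taken from the
#'   mesh extent if omitted.
#' @return data.frame with per-zone node counts, mean/max sigma1, mean/min
#'   sigma3 and mean trace (MPa); the zone holding the global maximum sigma1
#'   is attached as attribute `max_sigma1_zone` and flagged in the table.
#' @export
pattern_report <- function(stress, mesh, root_length = NULL) {
  surf_nodes <- tooth_surface_nodes(mesh)
  nd <- mesh$nodes[surf_nodes, , drop = FALSE]
  if (is.null(root_length)) root_length <- -min(nd[, 2])
  theta <- atan2(nd[, 3], nd[, 1])
  y <- nd[, 2]
  deg <- theta * 180 / pi
  crown_top <- max(y)
  zones <- list(
    buccal_cervix = abs(y) <= 0.5 & abs(deg) <= 45,
    lingual_cervix = abs(y) <= 0.5 & abs(deg) >= 135,
    mesial_side = deg > -135 & deg < -45 & y > -0.5 * root_length & y < 0.4 * crown_top,
    distal_side = deg > 45 & deg < 135 & y > -0.5 * root_length & y < 0.4 * crown_top,
    root_apex = y <= -0.75 * root_length)
  s1 <- stress$principal[surf_nodes, 1]
  s3 <- stress$principal[surf_nodes, 3]
  tr <- rowSums(stress$sigma[surf_nodes, 1:3, drop = FALSE])
  rows <- lapply(names(zones), function(zn) {
    sel <- zones[[zn]]
    if (!any(sel)) {
      return(data.frame(zone = zn, n_nodes = 0L, mean_sigma1 = NA_real_,
                        max_sigma1 = NA_real_, mean_sigma3 = NA_real_,
                        min_sigma3 = NA_real_, mean_trace = NA_real_))
    }
    data.frame(zone = zn, n_nodes = sum(sel),
               mean_sigma1 = mean(s1[sel]), max_sigma1 = max(s1[sel]),
               mean_sigma3 = mean(s3[sel]), min_sigma3 = min(s3[sel]),
               mean_trace = mean(tr[sel]))
  })
  df <- do.call(rbind, rows)
  # the dominant-tension zone is flagged on the zone MEAN: raw nodal maxima
  # sit at bimaterial edges and load application points, where the linear
  # elastic solution is singular and the peak grows without bound under mesh
  # refinement; the mean is the mesh-stable pattern statistic (the color-map
  # reading of a stress plot)
  mx <- df$zone[which.max(df$mean_sigma1)]
  df$global_max_sigma1 <- df$zone == mx
  attr(df, "max_sigma1_zone") <- mx
  df
}

#' @export
print.wear_comparison <- function(x, ...) {
  cat("wear comparison (a = less worn, b = more worn)\n")
  cat(sprintf("  mean sigma1 buccal cervix: a %.4f MPa, b %.4f MPa (mean delta %.4f)\n",
              x$mean_sigma1["a"], x$mean_sigma1["b"], x$mean_delta))
  cat(sprintf("  load obliquity: a %.2f deg, b %.2f deg\n",
              x$load_obliquity["a"], x$load_obliquity["b"]))
  invisible(x)
}

#' Plot a wear comparison (tensile stress along the cervical arc)
#'
#' @param x a `wear_comparison`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.wear_comparison <- function(x, ...) {
  graphics::matplot(x$table$arc_position,
                    cbind(x$table$sigma1_a, x$table$sigma1_b),
                    type = "b", pch = c(19, 1), lty = 1,
                    xlab = "arc position along buccal cervix",
                    ylab = expression(sigma[1] ~ "(MPa)"), ...)
  graphics::legend("topright", c("less worn", "more worn"),
                   pch = c(19, 1), lty = 1, col = 1:2, bty = "n")
  invisible(x)
}

#' Prevalence of cervical lesions in a sample
#'
#' Utility for reporting epidemiological counts as a percentage at one
#' decimal, e.g. 10 affected individuals out of 225 gives 4.4.
#'
#' @param cases affected individuals.
#' @param total sample size.
#' @return percentage, rounded to one decimal.
#' @export
nccl_prevalence <- function(cases, total) {
  stopifnot(cases >= 0, total > 0, cases <= total)
  round(100 * cases / total, 1)
}
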