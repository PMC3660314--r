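## Ground-truth specimens live on a voxel grid but are defined in continuous
## physical coordinates (nm). Convention: the center of voxel (i, j, k)
## (1-based indices) sits at ((i-1)*dx, (j-1)*dy, (k-1)*dz).

#' Empty phantom
#'
#' A phantom holds per-label emitter-density arrays (emitters per voxel) plus
#' an exact record of the continuous-coordinate geometry that generated them.
#'
#' @param dim Integer voxel dimensions `c(nx, ny, nz)`.
#' @param voxel Voxel sizes `c(dx, dy, dz)` in nm.
#' @param labels Character vector of label (channel) names.
#' @return Object of class `phantom` with elements `dim`, `voxel`, `density`
#'   (named list of 3D arrays) and `geometry` (list of primitive records).
#' @export
phantom <- function(dim = c(128, 128, 32), voxel = c(50, 50, 150),
                    labels = "QD655") {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L),
            length(voxel) == 3L, all(voxel > 0))
  dens <- stats::setNames(
    lapply(labels, function(l) array(0, dim = dim)), labels)
  structure(list(dim = dim, voxel = as.numeric(voxel),
                 density = dens, geometry = list()),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d x %d voxels @ %g x %g x %g nm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  labels: %s; %d geometry primitives\n",
              paste(names(x$density), collapse = ", "), length(x$geometry)))
  invisible(x)
}

## ---- sub-voxel rendering kernels -------------------------------------------

## Gaussian splat sigmas: physical cross-section (FWHM = structure diameter)
## combined in quadrature with a half-voxel anti-aliasing width, so the
## deposited total is insensitive to sub-voxel position and orientation
## (residual grid aliasing < 1%) while adding as little spurious width to
## thin structures as possible.
splat_sigma <- function(diameter, voxel) {
  sqrt((diameter / (2 * sqrt(2 * log(2))))^2 + (0.5 * voxel)^2)
}

## Add a Gaussian splat of given total weight at continuous point p (nm).
deposit_point <- function(arr, dim, voxel, p, sigma, weight) {
  ctr <- p / voxel + 1           # fractional 1-based index
  half <- ceiling(3 * sigma / voxel)
  i0 <- pmax(1L, floor(ctr - half)); i1 <- pmin(dim, ceiling(ctr + half))
  if (any(i0 > i1)) return(arr)
  xs <- (seq.int(i0[1], i1[1]) - 1) * voxel[1]
  ys <- (seq.int(i0[2], i1[2]) - 1) * voxel[2]
  zs <- (seq.int(i0[3], i1[3]) - 1) * voxel[3]
  gx <- exp(-(xs - p[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(ys - p[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-(zs - p[3])^2 / (2 * sigma[3]^2))
  splat <- outer(outer(gx, gy), gz)
  s <- sum(splat)
  if (s > 0)
    arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + splat * (weight / s)
  arr
}

## Render a polyline of given diameter into an array; the deposited total is
## scaled to exactly `total` emitters (label conservation by construction).
deposit_curve <- function(arr, dim, voxel, pts, diameter, total) {
  sigma <- splat_sigma(diameter, voxel)
  step <- min(voxel) / 2
  tmp <- array(0, dim = dim)
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    nseg <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = nseg)
    w <- rep(len / (nseg - 1L), nseg); w[c(1L, nseg)] <- w[1L] / 2
    for (q in seq_len(nseg))
      tmp <- deposit_point(tmp, dim, voxel, a + t[q] * (b - a), sigma, w[q])
  }
  s <- sum(tmp)
  if (s > 0) arr <- arr + tmp * (total / s)
  arr
}

## Render a solid sphere or spherical shell; smoothed radial indicator,
## total scaled to `total` emitters.
deposit_sphere <- function(arr, dim, voxel, center, radius, total,
                           shell_thickness = NULL) {
  h <- max(voxel)
  half <- ceiling((radius + 2 * h) / voxel)
  ctr <- center / voxel + 1
  i0 <- pmax(1L, floor(ctr - half)); i1 <- pmin(dim, ceiling(ctr + half))
  xs <- (seq.int(i0[1], i1[1]) - 1) * voxel[1] - center[1]
  ys <- (seq.int(i0[2], i1[2]) - 1) * voxel[2] - center[2]
  zs <- (seq.int(i0[3], i1[3]) - 1) * voxel[3] - center[3]
  r <- sqrt(outer(outer(xs^2, ys^2, `+`), zs^2, `+`))
  solid <- function(R) pmin(pmax((R - r) / h + 0.5, 0), 1)
  w <- if (is.null(shell_thickness)) solid(radius)
       else solid(radius) - solid(radius - shell_thickness)
  s <- sum(w)
  if (s > 0)
    arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      arr[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] + w * (total / s)
  arr
}

## ---- filaments --------------------------------------------------------------

#' Seeded filament phantom
#'
#' Generates filaments (microtubule-like linear structures) with stated
#' diameter, rendered with sub-voxel accuracy. Layouts: `"parallel"`
#' (straight filaments along y at random x positions, all in the mid
#' z-plane - the layout used for resolution measurements), `"pairs"`
#' (parallel filament pairs with controlled center-to-center spacing) and
#' `"random"` (randomly oriented, gently curved polylines at random depths).
#'
#' @param n Number of filaments (or pairs for `layout = "pairs"`).
#' @param diameter Filament diameter in nm (default 25, a microtubule).
#' @param min_separation Minimum center-to-center distance between filaments
#'   (pair centers for `"pairs"`), nm.
#' @param dim,voxel Grid dimensions (voxels) and voxel sizes (nm).
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @param layout One of `"parallel"`, `"pairs"`, `"random"`.
#' @param pair_spacing Center-to-center spacing within a pair, nm.
#' @param emitters_per_um Labeling density along the filament.
#' @param wiggle Amplitude (nm) of sinusoidal bending for `"random"` layout.
#' @param fragmented Break each filament into short segments with gaps
#'   (depolymerizing-filament look).
#' @param z_offset For `"parallel"`: half-distance (nm) of the two z-planes
#'   the filaments alternate between, so that cross profiles of one filament
#'   are not contaminated by its lateral neighbors (which then sit two
#'   x-gaps away in the same plane). `0` places all filaments in the mid
#'   plane.
#' @param label Channel name carrying the filaments.
#' @return A [phantom()].
#' @export
make_filaments <- function(n = 10, diameter = 25, min_separation = 400,
                           dim = c(128, 128, 32), voxel = c(50, 50, 150),
                           seed = 1, layout = c("parallel", "pairs", "random"),
                           pair_spacing = 150, emitters_per_um = 200,
                           wiggle = 200, fragmented = FALSE, z_offset = 750,
                           label = "QD655") {
  layout <- match.arg(layout)
  ph <- phantom(dim, voxel, label)
  set.seed(seed)
  ext <- (ph$dim - 1) * ph$voxel          # physical extent, nm
  zmid <- (ph$dim[3] %/% 2L) * ph$voxel[3]
  margin <- pmax(0.06 * ext, c(450, 150, 0))  # leave room for cross profiles
  ## evenly spaced slots with random jitter: guarantees the separation while
  ## keeping continuous (sub-voxel) positions
  place_x <- function(k, sep) {
    usable <- ext[1] - 2 * margin[1]
    gap <- usable / k
    if (gap < sep)
      stop(sprintf(
        "could not place %d filaments at min separation %g nm in a %g nm field",
        k, sep, ext[1]), call. = FALSE)
    jit <- stats::runif(k, -(gap - sep) / 2, (gap - sep) / 2)
    margin[1] + (seq_len(k) - 0.5) * gap + jit
  }
  add_straight <- function(x, z = zmid, pair = NA_integer_,
                           spacing = NA_real_) {
    pts <- rbind(c(x, margin[2], z), c(x, ext[2] - margin[2], z))
    segs <- if (fragmented) fragment_polyline(pts) else list(pts)
    for (p in segs) {
      len <- sum(sqrt(rowSums(diff(p)^2)))
      ph$density[[label]] <<- deposit_curve(
        ph$density[[label]], ph$dim, ph$voxel, p, diameter,
        emitters_per_um * len / 1000)
    }
    ph$geometry[[length(ph$geometry) + 1L]] <<- list(
      type = "filament", label = label, diameter = diameter,
      length = sum(sqrt(rowSums(diff(pts)^2))), points = pts,
      pair = pair, spacing = spacing)
  }
  if (layout == "parallel") {
    ## alternate sorted x positions between two z planes: same-plane
    ## neighbors are then >= min_separation apart even though the x grid is
    ## packed at min_separation / 2
    xs <- place_x(n, if (z_offset > 0) min_separation / 2 else min_separation)
    zoff <- pmin(z_offset, (ph$dim[3] %/% 2L - 1L) * ph$voxel[3])
    zs <- zmid + (if (zoff > 0) rep_len(c(-zoff, zoff), n) else rep(0, n))
    for (i in seq_along(xs)) add_straight(xs[i], z = zs[i])
  } else if (layout == "pairs") {
    for (i in seq_along(cx <- place_x(n, min_separation + pair_spacing))) {
      add_straight(cx[i] - pair_spacing / 2, pair = i, spacing = pair_spacing)
      add_straight(cx[i] + pair_spacing / 2, pair = i, spacing = pair_spacing)
    }
  } else {
    for (i in seq_len(n)) {
      p0 <- c(stats::runif(1, margin[1], ext[1] - margin[1]),
              stats::runif(1, margin[2], ext[2] - margin[2]),
              stats::runif(1, margin[3], ext[3] - margin[3]))
      th <- stats::runif(1, 0, pi)
      u <- c(cos(th), sin(th), 0)
      perp <- c(-u[2], u[1], 0)
      tt <- seq(-0.5, 0.5, length.out = 33)
      L <- 0.6 * min(ext[1:2])
      ph_off <- stats::runif(1, 0, 2 * pi)
      pts <- t(vapply(tt, function(s)
        p0 + s * L * u + wiggle * sin(2 * pi * s + ph_off) * perp,
        numeric(3)))
      pts[, 1] <- pmin(pmax(pts[, 1], margin[1]), ext[1] - margin[1])
      pts[, 2] <- pmin(pmax(pts[, 2], margin[2]), ext[2] - margin[2])
      segs <- if (fragmented) fragment_polyline(pts) else list(pts)
      for (p in segs) {
        len <- sum(sqrt(rowSums(diff(p)^2)))
        ph$density[[label]] <- deposit_curve(
          ph$density[[label]], ph$dim, ph$voxel, p, diameter,
          emitters_per_um * len / 1000)
      }
      ph$geometry[[length(ph$geometry) + 1L]] <- list(
        type = "filament", label = label, diameter = diameter,
        length = sum(sqrt(rowSums(diff(pts)^2))), points = pts,
        pair = NA_integer_, spacing = NA_real_)
    }
  }
  ph
}

## break a polyline into short kept segments separated by gaps
fragment_polyline <- function(pts, keep = 0.6, pieces = 5L) {
  nr <- nrow(pts)
  if (nr < 2L) return(list(pts))
  ## resample finely, then drop gap stretches
  t <- seq(0, 1, length.out = 64)
  fine <- apply(pts, 2, function(col)
    stats::approx(seq(0, 1, length.out = nr), col, xout = t)$y)
  cuts <- sort(stats::runif(pieces, 0, 1))
  segs <- list()
  lo <- 0
  for (cc in c(cuts, 1)) {
    hi <- cc
    mid0 <- lo + (1 - keep) / 2 * (hi - lo)
    mid1 <- hi - (1 - keep) / 2 * (hi - lo)
    idx <- which(t >= mid0 & t <= mid1)
    if (length(idx) >= 2L) segs[[length(segs) + 1L]] <- fine[idx, , drop = FALSE]
    lo <- cc
  }
  if (length(segs) == 0L) list(pts) else segs
}

## ---- vesicles ---------------------------------------------------------------

#' Seeded vesicle phantom
#'
#' Small microvesicles are uniformly labeled solid spheres with diameters
#' drawn from `small_range` (lentiviral microvesicles are roughly
#' 50-250 nm); hollow vesicles are spherical shells (label only at the
#' periphery) with diameters from `hollow_range` (0.7-0.9 um).
#'
#' @param n_small,n_hollow Numbers of solid and hollow vesicles.
#' @param small_range,hollow_range Diameter ranges in nm.
#' @param shell_thickness Shell thickness of hollow vesicles, nm.
#' @param dim,voxel Grid dimensions and voxel sizes.
#' @param seed RNG seed.
#' @param emitters_per_um3 Label density of solid vesicles (per um^3).
#' @param emitters_per_um2 Label density of shells (per um^2).
#' @param label Channel name.
#' @param max_retries Placement retries before a packing error.
#' @return A [phantom()].
#' @export
make_vesicles <- function(n_small = 15, small_range = c(50, 250),
                          n_hollow = 3, hollow_range = c(700, 900),
                          shell_thickness = 50,
                          dim = c(128, 128, 32), voxel = c(50, 50, 150),
                          seed = 1, emitters_per_um3 = 2e5,
                          emitters_per_um2 = 2000,
                          label = "QD655", max_retries = 2000L) {
  stopifnot(all(small_range > 0), all(hollow_range > 0))
  if (shell_thickness >= hollow_range[1] / 2)
    stop("`shell_thickness` must be below the hollow radius", call. = FALSE)
  ph <- phantom(dim, voxel, label)
  set.seed(seed)
  ext <- (ph$dim - 1) * ph$voxel
  placed <- matrix(numeric(0), ncol = 4)   # x, y, z, radius
  place <- function(radius) {
    for (i in seq_len(max_retries)) {
      c0 <- stats::runif(3, radius, ext - radius)
      if (nrow(placed) == 0 ||
          all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - c0)^2)) >
              placed[, 4] + radius + 25))
        return(c0)
    }
    stop("vesicle packing failed: volume too crowded", call. = FALSE)
  }
  ## hollow first (largest), then small
  for (i in seq_len(n_hollow)) {
    d <- stats::runif(1, hollow_range[1], hollow_range[2])
    c0 <- place(d / 2)
    placed <- rbind(placed, c(c0, d / 2))
    rmid <- (d / 2 - shell_thickness / 2) / 1000   # um
    total <- 4 * pi * rmid^2 * emitters_per_um2
    ph$density[[label]] <- deposit_sphere(ph$density[[label]], ph$dim,
                                          ph$voxel, c0, d / 2, total,
                                          shell_thickness)
    ph$geometry[[length(ph$geometry) + 1L]] <- list(
      type = "vesicle", label = label, diameter = d, hollow = TRUE,
      shell_thickness = shell_thickness, center = c0, emitters = total)
  }
  for (i in seq_len(n_small)) {
    d <- stats::runif(1, small_range[1], small_range[2])
    c0 <- place(d / 2)
    placed <- rbind(placed, c(c0, d / 2))
    total <- 4 / 3 * pi * (d / 2000)^3 * emitters_per_um3
    ph$density[[label]] <- deposit_sphere(ph$density[[label]], ph$dim,
                                          ph$voxel, c0, d / 2, total)
    ph$geometry[[length(ph$geometry) + 1L]] <- list(
      type = "vesicle", label = label, diameter = d, hollow = FALSE,
      shell_thickness = NA_real_, center = c0, emitters = total)
  }
  ph
}

## ---- deterministic test pattern --------------------------------------------

#' Deterministic blob test pattern
#'
#' A fixed arrangement of blobs for qualitative PSF demonstrations: a row of
#' single blobs of decreasing size, close pairs at configurable spacings
#' (separation probes), and a large blob containing two bright sub-blobs
#' (substructure probe). Calling it twice returns bit-identical phantoms.
#'
#' @param dim,voxel Grid dimensions and voxel sizes.
#' @param pair_spacings Center-to-center spacings (nm) of the pair probes.
#' @param sizes Diameters (nm) of the single-blob row.
#' @param probe_diameter Diameter (nm) of each pair-probe blob.
#' @param label Channel name.
#' @return A [phantom()].
#' @export
make_test_pattern <- function(dim = c(128, 128, 17), voxel = c(50, 50, 150),
                              pair_spacings = c(100, 150, 200, 300),
                              sizes = c(600, 400, 200),
                              probe_diameter = 150, label = "QD655") {
  ph <- phantom(dim, voxel, label)
  ext <- (ph$dim - 1) * ph$voxel
  zmid <- (ph$dim[3] %/% 2L) * ph$voxel[3]
  dens <- 2e5   # emitters per um^3, uniform for all blobs
  blob <- function(c0, d) {
    total <- 4 / 3 * pi * (d / 2000)^3 * dens
    ph$density[[label]] <<- deposit_sphere(ph$density[[label]], ph$dim,
                                           ph$voxel, c0, d / 2, total)
    total
  }
  ## row 1: single blobs
  y1 <- 0.2 * ext[2]
  xs <- seq(0.15, 0.85, length.out = length(sizes)) * ext[1]
  for (i in seq_along(sizes)) {
    blob(c(xs[i], y1, zmid), sizes[i])
    ph$geometry[[length(ph$geometry) + 1L]] <- list(
      type = "blob", label = label, diameter = sizes[i],
      center = c(xs[i], y1, zmid), spacing = NA_real_)
  }
  ## row 2: pair probes
  y2 <- 0.5 * ext[2]
  xs <- seq(0.12, 0.88, length.out = length(pair_spacings)) * ext[1]
  for (i in seq_along(pair_spacings)) {
    s <- pair_spacings[i]
    blob(c(xs[i] - s / 2, y2, zmid), probe_diameter)
    blob(c(xs[i] + s / 2, y2, zmid), probe_diameter)
    ph$geometry[[length(ph$geometry) + 1L]] <- list(
      type = "pair", label = label, diameter = probe_diameter,
      center = c(xs[i], y2, zmid), spacing = s)
  }
  ## row 3: substructure probe - large blob with two bright cores
  y3 <- 0.8 * ext[2]
  c0 <- c(0.5 * ext[1], y3, zmid)
  blob(c0, 800)
  blob(c0 + c(-150, 0, 0), 150)
  blob(c0 + c(150, 0, 0), 150)
  ph$geometry[[length(ph$geometry) + 1L]] <- list(
    type = "substructure", label = label, diameter = 800,
    center = c0, spacing = 300)
  ph
}

## ---- geometry serialization -------------------------------------------------

#' Serialize / restore phantom geometry
#'
#' Ground-truth geometry round-trips through JSON exactly (full-precision
#' numbers).
#'
#' @param ph A [phantom()].
#' @return `geometry_to_json()`: a JSON string; `geometry_from_json()`: the
#'   geometry list.
#' @export
geometry_to_json <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  as.character(jsonlite::toJSON(ph$geometry, digits = I(17),
                                auto_unbox = TRUE, na = "null"))
}

#' @param json JSON string produced by [geometry_to_json()].
#' @rdname geometry_to_json
#' @export
geometry_from_json <- function(json) {
  g <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                          simplifyMatrix = TRUE)
  lapply(g, function(rec) {
    if (!is.null(rec$points)) rec$points <- matrix(unlist(rec$points),
                                                   ncol = 3, byrow = FALSE)
    for (f in c("center", "spacing", "pair"))
      if (!is.null(rec[[f]])) rec[[f]] <- unlist(rec[[f]])
    rec
  })
}

#' Geometry records as a data frame
#'
#' One row per primitive with its recorded ground-truth dimensions.
#'
#' @param ph A [phantom()].
#' @return `data.frame` with columns `type`, `label`, `diameter`, `spacing`.
#' @export
phantom_geometry <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  do.call(rbind, lapply(ph$geometry, function(g)
    data.frame(type = g$type, label = g$label,
               diameter = g$diameter %||% NA_real_,
               spacing = g$spacing %||% NA_real_)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a phantom's emitter density
#'
#' Convenience for adjusting overall brightness (e.g. to hit a target peak
#' count) without regenerating geometry.
#'
#' @param ph A [phantom()].
#' @param factor Multiplicative factor.
#' @param label Label to scale; default all labels.
#' @return The scaled [phantom()].
#' @export
scale_phantom <- function(ph, factor, label = NULL) {
  stopifnot(inherits(ph, "phantom"), factor >= 0)
  labs <- label %||% names(ph$density)
  for (l in labs) ph$density[[l]] <- ph$density[[l]] * factor
  ph
}
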