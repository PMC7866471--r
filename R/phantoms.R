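# Synthetic IVUS phantoms: nested elliptical lumen-in-EEM geometry, catheter
# ring artifact, multiplicative gamma speckle and an optional deterministic
# position-dependent intensity bias (so coordinate channels carry signal).

#' Configuration for the synthetic IVUS phantom generator
#'
#' All radii and thicknesses are fractions of the image side. The phantom is
#' a nested pair of ellipses (lumen inside the EEM contour) on a textured
#' adventitia background, with a bright catheter ring artifact at the image
#' centre. Intensities get multiplicative gamma speckle; labels never do.
#'
#' @param image_size pixels per side (512 for the clinical geometry; tests
#'   use 128).
#' @param lumen_radius_range range of the lumen semi-major axis, as a
#'   fraction of image size.
#' @param wall_thickness_range range of the EEM-to-lumen wall thickness
#'   (EEM semi-axes = lumen semi-axes + thickness), fraction of image size.
#' @param eccentricity_max maximum offset of the lumen centre inside the EEM,
#'   as a fraction of the mean EEM radius (0 gives concentric contours).
#' @param axis_ratio_range range of the minor/major axis ratio; \code{c(1, 1)}
#'   forces circles.
#' @param catheter_radius catheter artifact radius, fraction of image size;
#'   must be smaller than the smallest possible lumen semi-minor axis.
#' @param speckle_scale dispersion of the multiplicative gamma speckle
#'   (standard deviation of a unit-mean multiplier); 0 disables noise.
#' @param gradient_strength amplitude in \code{[0, 1]} of a fixed
#'   vertical-plus-radial intensity bias added to the image, emulating
#'   depth-dependent gain; gives positional information exploitable by
#'   coordinate channels.
#' @param seed RNG seed used when one is not passed explicitly to the
#'   generator functions.
#' @return A validated list of class \code{phantom_config}.
#' @export
phantom_config <- function(image_size = 512L,
                           lumen_radius_range = c(0.10, 0.18),
                           wall_thickness_range = c(0.05, 0.10),
                           eccentricity_max = 0.25,
                           axis_ratio_range = c(0.7, 1.0),
                           catheter_radius = 0.035,
                           speckle_scale = 0.3,
                           gradient_strength = 0.2,
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size),
              lumen_radius_range = as.numeric(lumen_radius_range),
              wall_thickness_range = as.numeric(wall_thickness_range),
              eccentricity_max = as.numeric(eccentricity_max),
              axis_ratio_range = as.numeric(axis_ratio_range),
              catheter_radius = as.numeric(catheter_radius),
              speckle_scale = as.numeric(speckle_scale),
              gradient_strength = as.numeric(gradient_strength),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  in_unit_half <- function(x) all(x > 0 & x < 0.5)
  if (cfg$image_size < 16) stop_config("image_size", "must be >= 16")
  if (!in_unit_half(cfg$lumen_radius_range) ||
      cfg$lumen_radius_range[1] > cfg$lumen_radius_range[2])
    stop_config("lumen_radius_range", "must be an increasing range in (0, 0.5)")
  if (!in_unit_half(cfg$wall_thickness_range) ||
      cfg$wall_thickness_range[1] > cfg$wall_thickness_range[2])
    stop_config("wall_thickness_range", "must be an increasing range in (0, 0.5)")
  if (cfg$eccentricity_max < 0 || cfg$eccentricity_max > 1)
    stop_config("eccentricity_max", "must lie in [0, 1]")
  if (any(cfg$axis_ratio_range <= 0) || any(cfg$axis_ratio_range > 1) ||
      cfg$axis_ratio_range[1] > cfg$axis_ratio_range[2])
    stop_config("axis_ratio_range", "must be an increasing range in (0, 1]")
  if (cfg$lumen_radius_range[2] + cfg$wall_thickness_range[2] >= 0.5)
    stop_config("wall_thickness_range",
                "EEM radius (lumen + thickness) must stay below 0.5")
  min_lumen_minor <- cfg$lumen_radius_range[1] * cfg$axis_ratio_range[1]
  if (cfg$catheter_radius <= 0 || cfg$catheter_radius >= min_lumen_minor)
    stop_config("catheter_radius",
                "must be positive and smaller than the minimum lumen semi-minor axis")
  if (cfg$speckle_scale < 0) stop_config("speckle_scale", "must be >= 0")
  if (cfg$gradient_strength < 0 || cfg$gradient_strength > 1)
    stop_config("gradient_strength", "must lie in [0, 1]")
  invisible(cfg)
}

# Sample the per-phantom geometry (uses the current RNG stream).
sample_geometry <- function(cfg) {
  S <- cfg$image_size
  a_l <- runif(1, cfg$lumen_radius_range[1], cfg$lumen_radius_range[2]) * S
  q <- runif(1, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
  b_l <- a_l * q
  theta <- runif(1, 0, pi)
  thick <- runif(1, cfg$wall_thickness_range[1], cfg$wall_thickness_range[2]) * S
  # Lumen centre jitter around the catheter (image centre), bounded so the
  # catheter disc stays strictly inside the lumen.
  jmax <- min(0.3 * cfg$eccentricity_max * (a_l + thick),
              0.8 * (b_l - cfg$catheter_radius * S))
  jmax <- max(jmax, 0)
  phi_j <- runif(1, 0, 2 * pi)
  rj <- runif(1, 0, jmax)
  # EEM centre offset relative to the lumen centre. Containment of two
  # same-orientation ellipses whose axes differ by `thick` holds whenever the
  # offset is below thick * (b+t)/(a+t); with axis ratios >= 0.7 a clamp at
  # half the wall thickness keeps the lumen strictly inside the EEM contour.
  emax <- min(cfg$eccentricity_max * (a_l + thick), 0.5 * thick)
  phi_e <- runif(1, 0, 2 * pi)
  re <- runif(1, 0, emax)
  list(a_l = a_l, b_l = b_l, theta = theta, thick = thick,
       lumen_center = c(S / 2 + rj * cos(phi_j), S / 2 + rj * sin(phi_j)),
       eem_offset = c(re * cos(phi_e), re * sin(phi_e)))
}

# Small per-frame perturbation of a patient-level geometry (pullback drift).
jitter_geometry <- function(geom, cfg) {
  S <- cfg$image_size
  g <- geom
  g$a_l <- geom$a_l * runif(1, 0.95, 1.05)
  g$b_l <- geom$b_l * runif(1, 0.95, 1.05)
  g$theta <- geom$theta + runif(1, -0.1, 0.1)
  g$thick <- geom$thick * runif(1, 0.95, 1.05)
  g$lumen_center <- geom$lumen_center + runif(2, -0.005, 0.005) * S
  # Re-clamp the invariants after jitter.
  rc <- cfg$catheter_radius * S
  ctr <- c(S / 2, S / 2)
  d <- sqrt(sum((g$lumen_center - ctr)^2))
  dmax <- 0.8 * (min(g$a_l, g$b_l) - rc)
  if (dmax < 0) dmax <- 0
  if (d > dmax) g$lumen_center <- ctr + (g$lumen_center - ctr) * (dmax / max(d, 1e-12))
  de <- sqrt(sum(g$eem_offset^2))
  if (de > 0.5 * g$thick) g$eem_offset <- g$eem_offset * (0.5 * g$thick / de)
  g
}

# Quadratic form of a rotated ellipse, evaluated at pixel centres; <= 1 inside.
ellipse_q <- function(rows, cols, center, a, b, theta) {
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2
}

render_phantom <- function(cfg, geom) {
  S <- cfg$image_size
  rows <- seq_len(S) - 1  # pixel centres at integer coordinates, origin top-left
  cols <- rows
  q_l <- ellipse_q(rows, cols, geom$lumen_center, geom$a_l, geom$b_l, geom$theta)
  eem_center <- geom$lumen_center + geom$eem_offset
  q_e <- ellipse_q(rows, cols, eem_center,
                   geom$a_l + geom$thick, geom$b_l + geom$thick, geom$theta)
  in_lumen <- q_l < 1        # half-open, centre-sampling rasterization
  in_eem <- q_e < 1

  labels <- matrix(0L, S, S)
  labels[in_eem] <- 2L
  labels[in_lumen] <- 1L

  # Tissue template: dark blood pool, bright media/plaque ring, mid-gray
  # textured adventitia outside the EEM.
  tmpl <- matrix(0.45, S, S)
  tmpl[in_eem & !in_lumen] <- 0.72
  tmpl[in_lumen] <- 0.18

  # Catheter ring artifact around the transducer at the image centre.
  ctr <- c(S / 2, S / 2)
  dr <- outer(rows - ctr[1], rep(1, S))
  dc <- outer(rep(1, S), cols - ctr[2])
  dist_ctr <- sqrt(dr^2 + dc^2)
  rc <- cfg$catheter_radius * S
  tmpl[dist_ctr < rc] <- 0.08
  tmpl[dist_ctr >= rc - 1.5 & dist_ctr < rc + 0.5] <- 0.9

  img <- tmpl
  if (cfg$speckle_scale > 0) {
    shp <- 1 / cfg$speckle_scale^2
    mult <- matrix(rgamma(S * S, shape = shp, scale = 1 / shp), S, S)
    img <- img * mult
  }
  if (cfg$gradient_strength > 0) {
    vert <- outer((rows / (S - 1)) - 0.5, rep(1, S))
    radial <- 0.5 - pmin(dist_ctr / (S / 2), 1)
    img <- img + cfg$gradient_strength * (0.5 * vert + 0.5 * radial)
  }
  img <- pmin(pmax(img, 0), 1)

  list(pixels = img, labels = labels)
}

#' Generate one synthetic IVUS phantom
#'
#' Draws the geometry from \code{config}, rasterizes the labels (0 =
#' background, 1 = lumen, 2 = EEM ring) with the pixel-centre-inside
#' convention, and renders an intensity image with catheter artifact,
#' speckle and optional positional gradient. Speckle perturbs intensities
#' only, never the labels.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed; defaults to \code{config$seed}. Identical
#'   (config, seed) pairs reproduce the phantom bit for bit.
#' @return A list with elements \code{frame} ([new_frame()]) and
#'   \code{mask} ([new_label_mask()]).
#' @export
make_phantom <- function(config, seed = config$seed) {
  validate_phantom_config(config)
  with_seed(seed, {
    geom <- sample_geometry(config)
    r <- render_phantom(config, geom)
    list(frame = new_frame(r$pixels, patient_id = "phantom", frame_index = 0L),
         mask = new_label_mask(r$labels))
  })
}

#' Generate a multi-patient phantom corpus with a patient-wise split
#'
#' Geometry parameters are drawn once per synthetic patient and jittered per
#' frame, so frames of one patient are correlated as in a pullback. Patients
#' are assigned to train/test as whole patients, never frame-wise.
#'
#' @param config a [phantom_config()].
#' @param n_patients number of synthetic patients (>= 2).
#' @param frames_per_patient frames per patient.
#' @param seed corpus RNG seed; defaults to \code{config$seed}.
#' @param n_train_patients patients assigned to the training split
#'   (default: 80 percent, at least 1, leaving at least 1 test patient).
#' @return An [new_dataset()] with patient ids \code{"P001"}, ...
#' @export
make_corpus <- function(config, n_patients, frames_per_patient,
                        seed = config$seed,
                        n_train_patients = max(1L, floor(0.8 * n_patients))) {
  validate_phantom_config(config)
  if (n_patients < 2)
    stop("n_patients must be >= 2: a patient-wise split is impossible otherwise",
         call. = FALSE)
  if (n_train_patients < 1 || n_train_patients >= n_patients)
    stop("n_train_patients must leave at least one test patient", call. = FALSE)
  with_seed(seed, {
    frames <- list(); masks <- list(); k <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%03d", p)
      base_geom <- sample_geometry(config)
      for (f in seq_len(frames_per_patient)) {
        g <- jitter_geometry(base_geom, config)
        r <- render_phantom(config, g)
        k <- k + 1L
        frames[[k]] <- new_frame(r$pixels, patient_id = pid,
                                 frame_index = f - 1L)
        masks[[k]] <- new_label_mask(r$labels)
      }
    }
    pids <- sprintf("P%03d", seq_len(n_patients))
    split <- stats::setNames(
      c(rep("train", n_train_patients), rep("test", n_patients - n_train_patients)),
      pids)
    new_dataset(frames, masks, split)
  })
}

#' Write a phantom corpus to disk as PNG pairs plus a manifest
#'
#' Images are 8-bit grayscale PNG; masks are 8-bit PNG with raw label values
#' 0/1/2 (bit-exact round trip). The manifest is a CSV with columns
#' \code{path_image, path_mask, patient_id, frame_index, split}.
#'
#' @param dataset an [new_dataset()].
#' @param dir output directory, created if missing.
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$frames)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- dataset$frames[[i]]
    stem <- sprintf("%s_f%03d", fr$patient_id, fr$frame_index)
    pimg <- file.path(dir, paste0(stem, ".png"))
    pmsk <- file.path(dir, paste0(stem, "_mask.png"))
    write_image_png(fr, pimg)
    write_mask_png(dataset$masks[[i]], pmsk)
    rows[[i]] <- data.frame(path_image = pimg, path_mask = pmsk,
                            patient_id = fr$patient_id,
                            frame_index = fr$frame_index,
                            split = unname(dataset$split[[fr$patient_id]]),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
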