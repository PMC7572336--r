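#' Specify a synthetic brain phantom
#'
#' Builds the parameter object for [make_phantom()]. The phantom is a set of
#' concentric ellipsoids on an isotropic grid: a ventricular CSF core, a
#' basal-ganglia shell around it, a white-matter shell, and a cortical
#' grey-matter sheet. Eight angular sectors (frontal/temporal/parietal/
#' occipital crossed with left/right) plus the basal ganglia give the nine
#' lobar segments of the bullseye scheme. Spherical hyperintense lesions are
#' planted in white matter and basal ganglia with a configurable bias towards
#' periventricular placement.
#'
#' Default intensities are arbitrary scanner-free units chosen so that the
#' FLAIR-like channel shows the canonical contrast: CSF dark, lesions
#' markedly hyperintense relative to white matter, grey matter slightly
#' brighter than white matter.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Numeric length-3, mm per axis (default isotropic 1 mm).
#' @param brain_axes,ventricle_axes Ellipsoid semi-axes in mm.
#' @param cortex_thickness Cortical sheet thickness in mm.
#' @param bg_offset,bg_axes The basal ganglia are two ellipsoidal blobs
#'   (internal capsule / thalamus analogue) centred `bg_offset` mm left and
#'   right of the midline with semi-axes `bg_axes`, touching the ventricle
#'   medially and reaching towards the cortex laterally so that all four
#'   depth layers are populated.
#' @param lesion_count Number of spherical lesions to plant.
#' @param lesion_radius_range Length-2 mm range for lesion radii.
#' @param lesion_depth_bias Non-negative weight; placement probability is
#'   proportional to `exp(-bias * depth)` so larger values favour
#'   periventricular lesions. 0 is uniform.
#' @param class_intensity_means 5 x 3 matrix of class means, rows
#'   `csf, wm, gm, bg, lesion`, columns `t1, flair, fse`.
#' @param noise_sd Length-3 additive Gaussian noise SD per channel.
#' @param seed Integer seed; the phantom is a pure function of this spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size = c(1, 1, 1),
                         brain_axes = c(20, 17, 17),
                         ventricle_axes = c(8, 5, 5),
                         cortex_thickness = 2.5,
                         bg_offset = 12,
                         bg_axes = c(4.5, 4, 4),
                         lesion_count = 6L,
                         lesion_radius_range = c(2, 4),
                         lesion_depth_bias = 2,
                         class_intensity_means = NULL,
                         noise_sd = c(6, 6, 6),
                         seed = 1L) {
  if (is.null(class_intensity_means)) {
    class_intensity_means <- matrix(
      c( 30, 25, 140,   # csf
        120, 100, 90,   # wm
         90, 112, 100,  # gm
        100, 106, 95,   # bg
         95, 150, 130), # lesion
      nrow = 5, byrow = TRUE,
      dimnames = list(c("csf", "wm", "gm", "bg", "lesion"),
                      c("t1", "flair", "fse"))
    )
  }
  spec <- list(
    grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
    brain_axes = brain_axes, ventricle_axes = ventricle_axes,
    cortex_thickness = cortex_thickness,
    bg_offset = bg_offset, bg_axes = as.numeric(bg_axes),
    lobe_count = 9L,
    lesion_count = as.integer(lesion_count),
    lesion_radius_range = lesion_radius_range,
    lesion_depth_bias = lesion_depth_bias,
    class_intensity_means = class_intensity_means,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$noise_sd <= 0)) {
    rlang::abort("all noise SDs must be > 0", class = "bullseye_parameter_error")
  }
  if (any(spec$lesion_radius_range <= 0) || spec$lesion_depth_bias < 0) {
    rlang::abort("lesion radii must be positive and depth bias non-negative",
                 class = "bullseye_parameter_error")
  }
  inner <- spec$brain_axes - spec$cortex_thickness
  half_extent <- spec$grid_shape * spec$voxel_size / 2
  # shells must nest strictly, with >=1 voxel of margin; the BG blobs must
  # fit inside the WM shell and touch the ventricle medially
  margin <- max(spec$voxel_size)
  bg_lateral <- spec$bg_offset + spec$bg_axes[1]
  bg_medial <- spec$bg_offset - spec$bg_axes[1]
  if (any(spec$ventricle_axes + margin >= inner) ||
      any(spec$brain_axes + margin >= half_extent) ||
      bg_lateral >= inner[1] || bg_medial >= spec$ventricle_axes[1]) {
    rlang::abort(
      "grid too small to nest ventricle, basal ganglia, white matter and cortex shells",
      class = "bullseye_sizing_error"
    )
  }
  invisible(spec)
}

# tissue codes used throughout
.tissue_codes <- c(background = 0L, csf = 1L, wm = 2L, gm = 3L, bg = 4L)

#' Generate a synthetic multimodal brain phantom
#'
#' Deterministically renders the phantom described by a [phantom_spec()]:
#' three co-registered intensity channels (T1-like, FLAIR-like, FSE-like),
#' tissue labels (CSF ventricle, white matter, cortical grey matter, basal
#' ganglia), nine lobar labels, and the ground-truth lesion mask.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `brain_phantom`: a list with `channels`
#'   (named list of 3D arrays), `tissue` (integer 3D array, codes 0 =
#'   background, 1 = CSF, 2 = WM, 3 = cortical GM, 4 = basal ganglia),
#'   `lobes` (integer 3D array, 0 outside brain, 1..9 in the order
#'   FR, FL, TR, TL, PR, PL, OR, OL, BG), `lesion` (logical 3D array),
#'   `voxel_size` and the `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(lesion_count = 2, seed = 7))
#' table(ph$tissue[ph$tissue > 0])
#' @export
make_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  co <- grid_coords_mm(d, spec$voxel_size)
  X <- array(co[[1]], d)
  Y <- array(rep(co[[2]], each = d[1]), d)
  Z <- array(rep(co[[3]], each = d[1] * d[2]), d)

  inside <- function(axes) (X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2 <= 1
  brain <- inside(spec$brain_axes)
  inner <- inside(spec$brain_axes - spec$cortex_thickness)
  vent <- inside(spec$ventricle_axes)
  blob <- function(sgn) {
    ((X - sgn * spec$bg_offset) / spec$bg_axes[1])^2 +
      (Y / spec$bg_axes[2])^2 + (Z / spec$bg_axes[3])^2 <= 1
  }
  bg_shell <- (blob(1) | blob(-1)) & inner & !vent

  tissue <- array(.tissue_codes[["background"]], d)
  tissue[brain & !inner] <- .tissue_codes[["gm"]]
  tissue[inner] <- .tissue_codes[["wm"]]
  tissue[bg_shell] <- .tissue_codes[["bg"]]
  tissue[vent] <- .tissue_codes[["csf"]]

  # lobar sectors: hemisphere by sign of x, lobe by angle in the (y, z) plane
  theta <- atan2(Z, Y)
  lobe4 <- ifelse(theta >= 0 & theta < pi / 2, "F",
           ifelse(theta >= pi / 2, "P",
           ifelse(theta < -pi / 2, "O", "T")))
  side <- ifelse(X >= 0, "R", "L")
  lobes <- array(0L, d)
  in_brain <- tissue > 0L
  lobes[in_brain] <- match(paste0(lobe4, side)[in_brain], .lobe_levels)
  lobes[tissue == .tissue_codes[["bg"]]] <- match("BG", .lobe_levels)
  lobes[tissue == .tissue_codes[["csf"]]] <- 0L

  lesion <- array(FALSE, d)
  wm_bg <- tissue == .tissue_codes[["wm"]] | tissue == .tissue_codes[["bg"]]
  if (spec$lesion_count > 0L) {
    depth <- normalized_depth(
      ventricle_mask = tissue == .tissue_codes[["csf"]],
      cortex_mask = tissue == .tissue_codes[["gm"]],
      wm_mask = wm_bg, voxel_size = spec$voxel_size
    )
    dom_ijk <- mask_ijk(wm_bg)
    dom_mm <- mask_coords_mm(wm_bg, spec$voxel_size)
    # clearance: distance to the boundary of WM+BG (lesions must fit inside)
    boundary <- touching_voxels(!wm_bg, wm_bg)
    clearance <- nearest_surface_distance(dom_mm, mask_coords_mm(boundary, spec$voxel_size))
    dvals <- depth[wm_bg]
    centres <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    with_seed(spec$seed + 1L, {
      for (l in seq_len(spec$lesion_count)) {
        r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        ok <- clearance >= r
        if (nrow(centres) > 0) {
          sep <- nearest_surface_distance(dom_mm, centres)
          ok <- ok & sep >= (r + max(radii))
        }
        if (!any(ok)) {
          if (l == 1L) {
            rlang::abort("no white-matter voxel can host a lesion of the requested radius",
                         class = "bullseye_sizing_error")
          }
          next
        }
        w <- exp(-spec$lesion_depth_bias * dvals) * ok
        pick <- sample.int(length(w), 1L, prob = w)
        centres <- rbind(centres, dom_mm[pick, ])
        radii <- c(radii, r)
      }
    })
    for (l in seq_along(radii)) {
      dist2 <- (X - centres[l, 1])^2 + (Y - centres[l, 2])^2 + (Z - centres[l, 3])^2
      lesion <- lesion | (dist2 <= radii[l]^2)
    }
    lesion <- lesion & wm_bg
  }

  mean_of <- function(channel) {
    m <- array(0, d)
    for (cls in c("csf", "wm", "gm", "bg")) {
      m[tissue == .tissue_codes[[cls]]] <- spec$class_intensity_means[cls, channel]
    }
    m[lesion] <- spec$class_intensity_means["lesion", channel]
    m
  }
  channels <- with_seed(spec$seed, {
    setNames(lapply(seq_along(c("t1", "flair", "fse")), function(i) {
      ch <- c("t1", "flair", "fse")[i]
      mean_of(ch) + array(rnorm(prod(d), 0, spec$noise_sd[i]), d)
    }), c("t1", "flair", "fse"))
  })

  structure(
    list(channels = channels, tissue = tissue, lobes = lobes,
         lesion = lesion, voxel_size = spec$voxel_size, spec = spec),
    class = "brain_phantom"
  )
}

#' @export
print.brain_phantom <- function(x, ...) {
  d <- dim(x$tissue)
  cat("<brain_phantom> grid", paste(d, collapse = "x"),
      "| voxel", paste(x$voxel_size, collapse = "x"), "mm\n")
  cat("  tissue voxels:",
      paste(names(.tissue_codes)[-1],
            vapply(.tissue_codes[-1], function(k) sum(x$tissue == k), 0L),
            collapse = ", "), "\n")
  cat("  lesion voxels:", sum(x$lesion),
      sprintf("(%.0f mm3)", sum(x$lesion) * prod(x$voxel_size)), "\n")
  invisible(x)
}

#' Spatial tissue priors from label maps
#'
#' Converts the phantom's hard tissue labels into per-class spatial
#' probability maps (CSF, cortical GM, WM — basal ganglia counts as WM) that
#' constrain the mixture segmentation, optionally softened by Gaussian
#' smoothing. This stands in for atlas-propagated priors in clinical
#' pipelines.
#'
#' @param phantom A `brain_phantom`.
#' @param smoothing_mm Gaussian smoothing FWHM-free sigma in mm; 0 reproduces
#'   the hard labels.
#' @return A list with 3D probability arrays `csf`, `gm`, `wm` (summing to 1
#'   on every brain voxel) and the logical `mask` of brain voxels.
#' @export
tissue_priors <- function(phantom, smoothing_mm = 1) {
  stopifnot(inherits(phantom, "brain_phantom"), smoothing_mm >= 0)
  tis <- phantom$tissue
  mask <- tis > 0L
  hard <- list(
    csf = (tis == .tissue_codes[["csf"]]) * 1,
    gm = (tis == .tissue_codes[["gm"]]) * 1,
    wm = (tis == .tissue_codes[["wm"]] | tis == .tissue_codes[["bg"]]) * 1
  )
  if (smoothing_mm > 0) {
    hard <- lapply(hard, gaussian_blur3d, sigma_mm = smoothing_mm,
                   voxel_size = phantom$voxel_size)
  }
  tot <- hard$csf + hard$gm + hard$wm
  tot[tot == 0] <- 1
  out <- lapply(hard, function(p) {
    p <- p / tot
    p[!mask] <- 0
    p
  })
  out$mask <- mask
  out
}
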