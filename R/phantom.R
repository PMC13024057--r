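#' Region template for the phantom skull layout
#'
#' Describes one of the six craniofacial regions as a parametric shape in the
#' unit square (x rightwards = anterior, y downwards), together with its
#' planted growth and sexual-dimorphism signal. Region size follows
#' \code{s(age) = s0 * (1 + growth_coeff * g(age) + is_male * dimorphism_coeff
#' * d(age))} where \code{g} is a logistic schedule
#' \code{1/(1 + exp(-growth_rate * (age - growth_midpoint)))} and
#' \code{d(age) = (age - 4)/15} rises monotonically towards adulthood.
#'
#' @param name region name; one of orbit, zygoma, maxilla, sphenoid,
#'   temporal, mandible.
#' @param shape one of "circle", "ellipse", "polygon", "arc".
#' @param params shape parameters in unit coordinates: circle needs
#'   \code{center, r}; ellipse \code{center, a, b, angle} (degrees);
#'   polygon \code{xs, ys}; arc (annulus sector) \code{center, r_in, r_out,
#'   theta} (degrees, measured with y pointing down).
#' @param growth_coeff non-negative planted growth amplitude (unitless).
#' @param growth_midpoint,growth_rate logistic schedule parameters (years,
#'   1/years).
#' @param dimorphism_coeff additive male size offset amplitude.
#' @param base_intensity gray level of the region body in [0, 1].
#' @param texture_wavelengths trabecular texture wavelengths (pixels at a
#'   128-px canvas) at the young and old ends of the region's growth
#'   schedule; regions differ, as trabecular patterns do across bones.
#' @param texture_amplitude_scale region-specific multiplier on the global
#'   texture amplitude.
#' @return an object of class \code{region_template}.
#' @export
region_template <- function(name, shape, params, growth_coeff = 0,
                            growth_midpoint = 10, growth_rate = 0.8,
                            dimorphism_coeff = 0, base_intensity = 0.7,
                            texture_wavelengths = c(9, 3),
                            texture_amplitude_scale = 1) {
  stopifnot(name %in% c("orbit", "zygoma", "maxilla", "sphenoid",
                        "temporal", "mandible"),
            shape %in% c("circle", "ellipse", "polygon", "arc"),
            growth_coeff >= 0,
            is.finite(c(growth_coeff, growth_midpoint, growth_rate,
                        dimorphism_coeff, base_intensity)))
  structure(list(name = name, shape = shape, params = params,
                 growth_coeff = growth_coeff,
                 growth_midpoint = growth_midpoint,
                 growth_rate = growth_rate,
                 dimorphism_coeff = dimorphism_coeff,
                 base_intensity = base_intensity,
                 texture_wavelengths = texture_wavelengths,
                 texture_amplitude_scale = texture_amplitude_scale),
            class = "region_template")
}

logistic_schedule <- function(age, midpoint, rate) {
  1 / (1 + exp(-rate * (age - midpoint)))
}

dimorphism_schedule <- function(age) (age - 4) / 15

region_scale <- function(region, age, sex) {
  g <- logistic_schedule(age, region$growth_midpoint, region$growth_rate)
  d <- if (identical(sex, "male")) region$dimorphism_coeff *
         dimorphism_schedule(age) else 0
  1 + region$growth_coeff * g + d
}

region_center <- function(region) {
  p <- region$params
  switch(region$shape,
         circle = , ellipse = , arc = p$center,
         polygon = c(mean(p$xs), mean(p$ys)))
}

#' Canonical six-region lateral skull layout
#'
#' The default arrangement plants early logistic growth midpoints in the
#' temporal and sphenoid regions (cranial base matures first), late midpoints
#' in the maxilla and zygoma (midface remodels through puberty), and the
#' sexual-dimorphism signal in the mandible, growing towards age 18.
#'
#' @return list of six \code{region_template}s.
#' @export
default_regions <- function() {
  list(
    region_template("orbit", "circle",
                    list(center = c(0.72, 0.26), r = 0.050),
                    growth_coeff = 0.08, growth_midpoint = 9,
                    growth_rate = 0.7, base_intensity = 0.35,
                    texture_wavelengths = c(8, 4),
                    texture_amplitude_scale = 0.5),
    region_template("zygoma", "ellipse",
                    list(center = c(0.64, 0.40), a = 0.055, b = 0.028,
                         angle = -15),
                    growth_coeff = 0.30, growth_midpoint = 11,
                    growth_rate = 0.8, base_intensity = 0.75,
                    texture_wavelengths = c(6, 2.5)),
    region_template("maxilla", "polygon",
                    list(xs = c(0.61, 0.79, 0.81, 0.59),
                         ys = c(0.50, 0.50, 0.62, 0.62)),
                    growth_coeff = 0.30, growth_midpoint = 10.5,
                    growth_rate = 0.8, base_intensity = 0.65,
                    texture_wavelengths = c(8, 3)),
    region_template("sphenoid", "ellipse",
                    list(center = c(0.47, 0.36), a = 0.065, b = 0.042,
                         angle = 0),
                    growth_coeff = 0.30, growth_midpoint = 6,
                    growth_rate = 0.9, base_intensity = 0.60,
                    texture_wavelengths = c(10, 4)),
    region_template("temporal", "arc",
                    list(center = c(0.30, 0.34), r_in = 0.10, r_out = 0.135,
                         theta = c(95, 265)),
                    growth_coeff = 0.35, growth_midpoint = 5.5,
                    growth_rate = 0.9, base_intensity = 0.70,
                    texture_wavelengths = c(12, 5)),
    region_template("mandible", "arc",
                    list(center = c(0.56, 0.60), r_in = 0.13, r_out = 0.175,
                         theta = c(20, 160)),
                    growth_coeff = 0.10, growth_midpoint = 8,
                    growth_rate = 0.7, dimorphism_coeff = 0.12,
                    base_intensity = 0.80,
                    texture_wavelengths = c(7, 3))
  )
}

#' Phantom cohort specification
#'
#' Bundles the canvas size, region layout, acquisition-noise model and
#' subject-level variability of a synthetic lateral-cephalogram cohort.
#' Validation renders the region footprints at the oldest age for both sexes
#' (zero jitter) and rejects layouts whose footprints overlap.
#'
#' @param canvas_side square canvas side in pixels (>= 32).
#' @param regions list of \code{region_template}s; defaults to
#'   \code{default_regions()}.
#' @param noise_sd additive Gaussian acquisition noise (intensity units).
#' @param jitter_sd subject-level global translation jitter (pixels).
#' @param region_scale_sd relative SD of per-subject, per-region size
#'   variation (truncated at 3 SD), modeling individual differences in
#'   regional proportions that are unrelated to age; this is what makes a
#'   mature region uninformative rather than merely static.
#' @param flip_prob probability that a subject is stored mirrored.
#' @param texture trabecular texture: list with \code{amplitude} (0
#'   disables). Wavelengths come from each region template (young/old ends,
#'   pixels at a 128-px canvas) and shorten with age along the region's
#'   growth schedule, so bone texture is an age cue independent of shape.
#' @param intensity_gain_range multiplicative per-subject exposure gain range.
#' @param validate render and check footprint disjointness (skip for speed).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(canvas_side = 128, regions = default_regions(),
                         noise_sd = 0.02, jitter_sd = 1.5,
                         region_scale_sd = 0.025, flip_prob = 0.5,
                         texture = list(amplitude = 0.06),
                         intensity_gain_range = c(0.9, 1.1),
                         validate = TRUE) {
  stopifnot(canvas_side >= 32, flip_prob >= 0, flip_prob <= 1,
            noise_sd >= 0, jitter_sd >= 0, region_scale_sd >= 0,
            region_scale_sd < 0.2,
            length(intensity_gain_range) == 2)
  nm <- vapply(regions, function(r) r$name, "")
  if (!setequal(nm, c("orbit", "zygoma", "maxilla", "sphenoid", "temporal",
                      "mandible")) || anyDuplicated(nm))
    stop("regions must be exactly the six canonical craniofacial regions")
  spec <- structure(list(canvas_side = as.integer(canvas_side),
                         regions = regions, noise_sd = noise_sd,
                         jitter_sd = jitter_sd,
                         region_scale_sd = region_scale_sd,
                         flip_prob = flip_prob,
                         texture = texture,
                         intensity_gain_range = intensity_gain_range),
                    class = "phantom_spec")
  if (validate) {
    for (sex in c("male", "female")) {
      masks <- region_masks(spec, age = 18.99, sex = sex,
                            jitter = c(0, 0), mirrored = FALSE,
                            scale_extra = rep(1 + 3 * region_scale_sd,
                                              length(regions)))
      tot <- Reduce(`+`, masks)
      if (any(tot > 1))
        stop("region footprints overlap at maximal growth (", sex,
             "); adjust the layout")
    }
  }
  spec
}

# Vectorized shape membership at points (x, y) in unit coordinates.
shape_member <- function(shape, p, x, y) {
  switch(shape,
         circle = (x - p$center[1])^2 + (y - p$center[2])^2 <= p$r^2,
         ellipse = {
           th <- p$angle * pi / 180
           dx <- x - p$center[1]; dy <- y - p$center[2]
           xr <- dx * cos(th) + dy * sin(th)
           yr <- -dx * sin(th) + dy * cos(th)
           (xr / p$a)^2 + (yr / p$b)^2 <= 1
         },
         polygon = point_in_polygon(x, y, p$xs, p$ys),
         arc = {
           dx <- x - p$center[1]; dy <- y - p$center[2]
           r <- sqrt(dx^2 + dy^2)
           th <- (atan2(dy, dx) * 180 / pi) %% 360
           r >= p$r_in & r <= p$r_out & th >= p$theta[1] & th <= p$theta[2]
         })
}

# Even-odd crossing test, vectorized over query points.
point_in_polygon <- function(x, y, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > y) != (ys[j] > y)) &
      (x < (xs[j] - xs[i]) * (y - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# All six post-transform region footprints for one subject configuration.
# scale_extra: per-region multiplicative size factors (individual variation).
region_masks <- function(spec, age, sex, jitter = c(0, 0), mirrored = FALSE,
                         scale_extra = NULL) {
  S <- spec$canvas_side
  u <- (seq_len(S) - 0.5) / S
  px <- matrix(u, S, S, byrow = TRUE)   # x = column position
  py <- matrix(u, S, S)                 # y = row position
  if (mirrored) px <- 1 - px
  qx <- px - jitter[1] / S
  qy <- py - jitter[2] / S
  masks <- lapply(seq_along(spec$regions), function(ri) {
    rg <- spec$regions[[ri]]
    s <- region_scale(rg, age, sex)
    if (!is.null(scale_extra)) s <- s * scale_extra[ri]
    ct <- region_center(rg)
    cx <- ct[1] + (qx - ct[1]) / s
    cy <- ct[2] + (qy - ct[2]) / s
    matrix(shape_member(rg$shape, rg$params, as.vector(cx), as.vector(cy)),
           S, S)
  })
  names(masks) <- vapply(spec$regions, function(r) r$name, "")
  masks
}

# Band-limited noise: coarse white-noise grid, bilinearly upsampled so the
# dominant wavelength is ~`wavelength` pixels.
texture_field <- function(side, wavelength) {
  g <- max(2L, as.integer(ceiling(side / max(wavelength, 1)) + 1L))
  coarse <- matrix(rnorm(g * g), g, g)
  bilinear_resize(coarse, side, side)
}

#' Render one phantom cephalogram
#'
#' Draws the six regions at the subject's age- and sex-dependent sizes, adds
#' age-scheduled trabecular texture, subject-level jitter and exposure gain,
#' acquisition noise, and the subject's stored orientation. Deterministic
#' given (spec, subject, seed).
#'
#' @param spec a \code{phantom_spec}.
#' @param subject list or one-row data frame with \code{age} (years in
#'   [4, 19)), \code{sex} ("male"/"female") and \code{orientation}
#'   ("standard"/"mirrored").
#' @param seed integer seed for the subject's noise and jitter draws.
#' @return list with \code{image} (canvas_side x canvas_side matrix in
#'   [0, 1]), \code{masks} (named list of six logical matrices, the
#'   post-transform truth footprints) and \code{meta}.
#' @export
render_phantom <- function(spec, subject, seed = 1) {
  age <- as.numeric(subject$age)
  if (is.na(age) || age < 4 || age >= 19)
    stop("subject age must lie in [4, 19); got ", age)
  sex <- match.arg(as.character(subject$sex), c("male", "female"))
  orientation <- match.arg(as.character(subject$orientation %||% "standard"),
                           c("standard", "mirrored"))
  S <- spec$canvas_side
  with_seed(seed, {
    jitter <- rnorm(2, 0, spec$jitter_sd)
    gain <- runif(1, spec$intensity_gain_range[1],
                  spec$intensity_gain_range[2])
    ssd <- spec$region_scale_sd %||% 0
    scale_extra <- 1 + pmin(pmax(rnorm(length(spec$regions), 0, ssd),
                                 -3 * ssd), 3 * ssd)
    masks <- region_masks(spec, age, sex, jitter,
                          mirrored = orientation == "mirrored",
                          scale_extra = scale_extra)
    img <- matrix(0.05, S, S)
    amp <- spec$texture$amplitude %||% 0
    for (i in seq_along(spec$regions)) {
      rg <- spec$regions[[i]]
      m <- masks[[i]]
      img[m] <- rg$base_intensity
      if (amp > 0 && rg$texture_amplitude_scale > 0) {
        g <- logistic_schedule(age, rg$growth_midpoint, rg$growth_rate)
        wls <- rg$texture_wavelengths
        wl <- (wls[1] + (wls[2] - wls[1]) * g) * S / 128
        tex <- texture_field(S, wl)
        img[m] <- img[m] + amp * rg$texture_amplitude_scale * tex[m]
      }
    }
    img <- img * gain
    if (spec$noise_sd > 0) img <- img + rnorm(S * S, 0, spec$noise_sd)
    list(image = clamp01(img), masks = masks,
         meta = list(age = age, sex = sex, orientation = orientation,
                     jitter = jitter, gain = gain,
                     region_scale = scale_extra, seed = seed))
  })
}

#' Sample a phantom cohort
#'
#' Draws n subjects (ages from \code{age_law}, sexes Bernoulli, orientations
#' Bernoulli(flip_prob)) and renders their images and truth masks. Ages are
#' recorded to two decimals. Masks are stored compactly as a per-subject
#' region-label map (0 = background, 1..6 in spec region order).
#'
#' @param spec a \code{phantom_spec}.
#' @param n number of subjects (>= 1).
#' @param age_law function(n) returning ages in [4, 19); default uniform.
#' @param sex_ratio probability of male.
#' @param seed master seed; per-subject render seeds are derived from it and
#'   recorded in the metadata.
#' @param render if FALSE, return metadata only.
#' @return list with \code{metadata} (data.frame: subject_id, age, sex,
#'   orientation, seed), \code{images} (side x side x n array) and
#'   \code{labels} (side x side x n integer array of region labels).
#' @export
sample_cohort <- function(spec, n, age_law = function(n) runif(n, 4, 19),
                          sex_ratio = 0.5, seed = 1, render = TRUE) {
  if (n < 1) stop("n must be >= 1")
  meta <- with_seed(seed, {
    ages <- round(pmin(age_law(n), 18.99), 2)
    if (any(ages < 4 | ages >= 19)) stop("age_law produced ages outside [4, 19)")
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               age = ages,
               sex = ifelse(rbinom(n, 1, sex_ratio) == 1, "male", "female"),
               orientation = ifelse(rbinom(n, 1, spec$flip_prob) == 1,
                                    "mirrored", "standard"),
               seed = derive_seeds(sample.int(.Machine$integer.max - 1L, 1), n),
               stringsAsFactors = FALSE)
  })
  if (!render) return(list(metadata = meta, images = NULL, labels = NULL))
  S <- spec$canvas_side
  images <- array(0, c(S, S, n))
  labels <- array(0L, c(S, S, n))
  for (i in seq_len(n)) {
    ph <- render_phantom(spec, meta[i, ], seed = meta$seed[i])
    images[, , i] <- ph$image
    lab <- matrix(0L, S, S)
    for (k in seq_along(ph$masks)) lab[ph$masks[[k]]] <- k
    labels[, , i] <- lab
  }
  list(metadata = meta, images = images, labels = labels)
}

#' Planted regional importance at a given age
#'
#' The ground-truth importance of region r at age a is proportional to the
#' magnitude of the age-derivative of its planted size signal,
#' \code{|growth_coeff * g'(age)|}; for the logistic schedule
#' \code{g'(a) = rate * g(a) * (1 - g(a))}. Scores are normalized to sum 1
#' when any is positive.
#'
#' @param spec a \code{phantom_spec}.
#' @param age age in [4, 19).
#' @return named numeric vector over the six regions.
#' @export
planted_importance <- function(spec, age) {
  if (age < 4 || age >= 19) stop("age must lie in [4, 19)")
  sc <- vapply(spec$regions, function(rg) {
    g <- logistic_schedule(age, rg$growth_midpoint, rg$growth_rate)
    abs(rg$growth_coeff * rg$growth_rate * g * (1 - g))
  }, 0)
  names(sc) <- vapply(spec$regions, function(r) r$name, "")
  if (any(sc > 0)) sc <- sc / sum(sc)
  sc
}
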