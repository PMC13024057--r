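#' Consensus mask by pixelwise majority vote
#'
#' A pixel is included when its mean coverage over the annotator masks is at
#' least the rule threshold (ties included).
#'
#' @param masks list of k binary masks with equal dimensions.
#' @param rule coverage fraction required (default majority, 0.5).
#' @return logical matrix.
#' @export
consensus_mask <- function(masks, rule = 0.5) {
  if (!length(masks)) stop("no masks supplied")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), TRUE)))
    stop("mask dimensions differ")
  cov <- Reduce(`+`, lapply(masks, function(m) (m > 0) * 1)) / length(masks)
  cov >= rule
}

#' Simulate annotator segmentations of the region masks
#'
#' Produces k perturbed replicas of each truth mask: a small random integer
#' translation plus a random morphological dilation or erosion (disc brush),
#' emulating inter-annotator variability in manual ROI delineation. A
#' replica that comes out empty is regenerated up to a retry cap.
#'
#' @param truth_masks named list of binary region masks.
#' @param k number of annotators (default 20).
#' @param jitter list with \code{shift_sd} (pixels) and \code{morph_max}
#'   (max dilation/erosion radius, pixels); all zeros reproduce the truth.
#' @param seed integer seed.
#' @param retry_cap regenerations allowed before erroring.
#' @return list of k lists of region masks (same names as truth_masks).
#' @export
simulate_annotations <- function(truth_masks, k = 20,
                                 jitter = list(shift_sd = 1.5, morph_max = 2),
                                 seed = 1, retry_cap = 5) {
  if (k < 1) stop("k must be >= 1")
  with_seed(seed, {
    lapply(seq_len(k), function(a) {
      out <- lapply(truth_masks, function(m) {
        for (try in seq_len(retry_cap + 1)) {
          r <- perturb_mask(m, jitter)
          if (sum(r) > 0) return(r)
          warning("annotation replica emptied the mask; regenerating")
        }
        stop("annotation jitter too large: mask emptied repeatedly")
      })
      names(out) <- names(truth_masks)
      out
    })
  })
}

perturb_mask <- function(mask, jitter) {
  m <- mask > 0
  shift_sd <- jitter$shift_sd %||% 0
  morph_max <- jitter$morph_max %||% 0
  if (shift_sd > 0) {
    sh <- round(rnorm(2, 0, shift_sd))
    m <- shift_mask(m, sh[1], sh[2])
  }
  if (morph_max > 0) {
    r <- sample.int(morph_max + 1, 1) - 1L
    if (r > 0) {
      brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
      img <- EBImage::Image(m * 1)
      m <- (if (runif(1) < 0.5) EBImage::dilate(img, brush)
            else EBImage::erode(img, brush)) > 0
      m <- matrix(m, nrow(mask), ncol(mask))
    }
  }
  m
}

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Region mask set for one age-sex group
#'
#' The phantom analog of the per-group ROI templates: truth masks rendered
#' at the bin-center age in canonical pose (zero jitter, standard
#' orientation), k simulated annotator replicas, and their majority-vote
#' consensus.
#'
#' @param spec a \code{phantom_spec}.
#' @param bin integer age bin (4..18).
#' @param sex "male" or "female".
#' @param k number of simulated annotators.
#' @param jitter annotation jitter parameters (see
#'   \code{\link{simulate_annotations}}).
#' @param seed integer seed.
#' @return object of class \code{region_mask_set} with \code{truth},
#'   \code{annotators}, \code{consensus} and \code{group_key}.
#' @export
group_mask_set <- function(spec, bin, sex, k = 20,
                           jitter = list(shift_sd = 1.5, morph_max = 2),
                           seed = 1) {
  truth <- region_masks(spec, age = bin + 0.5, sex = sex,
                        jitter = c(0, 0), mirrored = FALSE)
  ann <- simulate_annotations(truth, k = k, jitter = jitter, seed = seed)
  cons <- lapply(names(truth), function(nm)
    consensus_mask(lapply(ann, `[[`, nm)))
  names(cons) <- names(truth)
  structure(list(truth = truth, annotators = ann, consensus = cons,
                 group_key = list(age_bin = bin, sex = sex), k = k),
            class = "region_mask_set")
}

#' Group saliency threshold
#'
#' The q-th percentile (linear interpolation between closest ranks) of all
#' pixel values pooled over a group's image-resolution rectified saliency
#' maps.
#'
#' @param maps list of upsampled \code{saliency_map}s or numeric matrices.
#' @param q percentile in (0, 100); default 75.
#' @return numeric threshold with attributes \code{q} and \code{n_maps}.
#' @export
group_threshold <- function(maps, q = 75) {
  if (!length(maps)) stop("empty group")
  stopifnot(q > 0, q < 100)
  pool <- unlist(lapply(maps, function(m)
    if (inherits(m, "saliency_map")) m$image else m), use.names = FALSE)
  t <- unname(quantile(pool, q / 100, type = 7))
  attr(t, "q") <- q
  attr(t, "n_maps") <- length(maps)
  t
}

#' Mean supra-threshold saliency within a region
#'
#' The regional saliency statistic shared by the ASI and SSI: with
#' \code{N_s} the number of region pixels whose saliency is >= t, the value
#' is the mean saliency over those pixels; by convention 0 when
#' \code{N_s = 0}. With \code{normalize = "area"} the sum is divided by the
#' region area instead (sensitivity variant).
#'
#' @param map numeric saliency matrix (image resolution, raw values).
#' @param mask binary region mask of the same dimensions.
#' @param t threshold in saliency units.
#' @param normalize "supra" (divide by N_s) or "area" (divide by region
#'   area).
#' @return list(value, n_supra).
#' @export
region_mean_index <- function(map, mask, t, normalize = c("supra", "area")) {
  normalize <- match.arg(normalize)
  if (inherits(map, "saliency_map")) map <- map$image
  stopifnot(all(dim(map) == dim(mask)), is.finite(t))
  inside <- mask > 0
  if (!any(inside)) stop("empty region mask")
  supra <- inside & (map >= t)
  ns <- sum(supra)
  val <- if (normalize == "supra") {
    if (ns == 0) 0 else sum(map[supra]) / ns
  } else sum(map[supra]) / sum(inside)
  list(value = val, n_supra = ns)
}

#' Ensemble regional index over annotator masks
#'
#' The arithmetic mean of \code{region_mean_index} over the k annotator
#' replicas of one region (default k = 20), each applying the N_s = 0 -> 0
#' convention.
#'
#' @param map saliency matrix or upsampled \code{saliency_map}.
#' @param masks list of k binary masks for one region.
#' @param t threshold.
#' @param normalize passed to \code{region_mean_index}.
#' @return list(value, n_supra) with n_supra the mean supra-threshold count.
#' @export
ensemble_index <- function(map, masks, t, normalize = "supra") {
  if (!length(masks)) stop("no masks")
  vals <- lapply(masks, function(m) region_mean_index(map, m, t, normalize))
  list(value = mean(vapply(vals, `[[`, 0, "value")),
       n_supra = mean(vapply(vals, `[[`, 0, "n_supra")))
}

#' Regional saliency index table
#'
#' The full quantification: per (age bin, sex) group, the pooled
#' 75th-percentile threshold is computed from the group's maps, every
#' subject's map is scored against the k annotator masks of each region
#' (ensemble mean), and the group entry is the unweighted mean over the
#' group's subjects. Maps from the age task yield the ASI; maps from the
#' sex task yield the SSI.
#'
#' @param maps list of upsampled, aligned \code{saliency_map}s (raw values).
#' @param groups data.frame with one row per map: \code{age_bin},
#'   \code{sex}.
#' @param mask_sets named list of \code{region_mask_set}s, keyed
#'   "bin.sex" (see \code{\link{group_mask_set}}); groups without a mask set
#'   are skipped with a warning.
#' @param kind "ASI" or "SSI".
#' @param q threshold percentile.
#' @param scope "group" pools pixels over all of the group's maps (default);
#'   "map" thresholds each map by its own distribution.
#' @param normalize passed through to the regional statistic.
#' @return data.frame with columns kind, sex, age, region, value, n_supra,
#'   n_subjects, t (class \code{saliency_index_table}).
#' @export
index_table <- function(maps, groups, mask_sets, kind = c("ASI", "SSI"),
                        q = 75, scope = c("group", "map"),
                        normalize = "supra") {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  stopifnot(length(maps) == nrow(groups))
  key <- paste(groups$age_bin, groups$sex, sep = ".")
  rows <- list()
  for (gk in unique(key)) {
    idx <- which(key == gk)
    ms <- mask_sets[[gk]]
    if (is.null(ms)) {
      warning("no mask set for group ", gk, "; skipped")
      next
    }
    gmaps <- maps[idx]
    t_group <- if (scope == "group") group_threshold(gmaps, q) else NA_real_
    for (region in names(ms$truth)) {
      region_masks_k <- lapply(ms$annotators, `[[`, region)
      per_subject <- lapply(gmaps, function(m) {
        t_use <- if (scope == "group") t_group else group_threshold(list(m), q)
        ensemble_index(m, region_masks_k, t_use, normalize)
      })
      rows[[length(rows) + 1]] <- data.frame(
        kind = kind,
        sex = groups$sex[idx[1]],
        age = groups$age_bin[idx[1]],
        region = region,
        value = mean(vapply(per_subject, `[[`, 0, "value")),
        n_supra = mean(vapply(per_subject, `[[`, 0, "n_supra")),
        n_subjects = length(idx),
        t = if (scope == "group") as.numeric(t_group) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sex, out$age), ]
  rownames(out) <- NULL
  class(out) <- c("saliency_index_table", "data.frame")
  out
}
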