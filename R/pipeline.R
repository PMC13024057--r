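#' Aligned image-resolution saliency maps for a set of subjects
#'
#' Computes per-subject Grad-CAM maps (age head: the scalar prediction; sex
#' head: the true-class logit), bilinearly upsamples them to the image frame
#' and aligns mirrored subjects to the standard orientation.
#'
#' @param model fitted \code{ceph_cnn}.
#' @param images side x side x n array (same frame the model saw).
#' @param metadata data.frame with \code{age}, \code{sex},
#'   \code{orientation} rows matching the images.
#' @param map_norm "mean" divides each subject's upsampled map by its mean,
#'   putting maps in units of the subject's mean saliency so that groups of
#'   different prediction magnitude are comparable; "none" keeps raw units.
#' @return list(maps, groups): upsampled \code{saliency_map}s and a
#'   data.frame with age_bin and sex per map.
#' @export
subject_saliency_maps <- function(model, images, metadata,
                                  map_norm = c("mean", "none")) {
  map_norm <- match.arg(map_norm)
  n <- dim(images)[3]
  stopifnot(nrow(metadata) == n)
  targets <- if (model$config$head == "sex_classification")
    as.character(metadata$sex) else NULL
  maps <- gradcam_maps(model, images, targets)
  side <- dim(images)[1]
  maps <- lapply(seq_len(n), function(i) {
    m <- upsample_align(maps[[i]], side, metadata$orientation[i])
    if (map_norm == "mean") {
      mu <- mean(m$image)
      if (mu > 0) m$image <- m$image / mu
    }
    m
  })
  list(maps = maps,
       groups = data.frame(age_bin = age_bin(metadata$age),
                           sex = as.character(metadata$sex),
                           stringsAsFactors = FALSE))
}

#' Build consensus/annotator mask sets for a set of groups
#'
#' One \code{region_mask_set} per (age bin, sex) pair, keyed "bin.sex".
#'
#' @param spec a \code{phantom_spec}.
#' @param bins integer age bins.
#' @param sexes character vector of sexes.
#' @param k annotators per group.
#' @param jitter annotation jitter (see \code{simulate_annotations}).
#' @param seed master seed; one child seed per group.
#' @return named list of \code{region_mask_set}s.
#' @export
build_mask_sets <- function(spec, bins, sexes = c("male", "female"), k = 20,
                            jitter = list(shift_sd = 1.5, morph_max = 2),
                            seed = 1) {
  grid <- expand.grid(bin = bins, sex = sexes, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(i)
    group_mask_set(spec, grid$bin[i], grid$sex[i], k = k, jitter = jitter,
                   seed = seeds[i]))
  names(out) <- paste(grid$bin, grid$sex, sep = ".")
  out
}

#' Regional saliency index table straight from a fitted model
#'
#' Convenience wrapper: subject saliency maps, per-group mask sets and the
#' full \code{index_table} in one call. Age-head models yield the ASI,
#' sex-head models the SSI.
#'
#' @param model fitted \code{ceph_cnn}.
#' @param images,metadata evaluation subjects (typically the test split).
#' @param spec the \code{phantom_spec} that generated the cohort.
#' @param q threshold percentile.
#' @param k annotators per group.
#' @param annotation_jitter jitter for the simulated annotators.
#' @param seed seed for the mask-set simulation.
#' @param map_norm per-map normalization (see
#'   \code{\link{subject_saliency_maps}}).
#' @param ... passed to \code{index_table} (scope, normalize).
#' @return a \code{saliency_index_table}.
#' @export
saliency_index_table <- function(model, images, metadata, spec, q = 75,
                                 k = 20,
                                 annotation_jitter = list(shift_sd = 1.5,
                                                          morph_max = 2),
                                 seed = 1, map_norm = "mean", ...) {
  sm <- subject_saliency_maps(model, images, metadata, map_norm = map_norm)
  bins <- sort(unique(sm$groups$age_bin))
  sexes <- unique(sm$groups$sex)
  ms <- build_mask_sets(spec, bins, sexes, k = k, jitter = annotation_jitter,
                        seed = seed)
  kind <- if (model$task == "age") "ASI" else "SSI"
  index_table(sm$maps, sm$groups, ms, kind = kind, q = q, ...)
}

#' Spearman agreement between recovered and planted regional importance
#'
#' For each age bin in the table, ranks the six regional index values
#' (averaged over sexes) against the planted importance at the bin center
#' and reports the per-bin Spearman correlations and their mean.
#'
#' @param tab a \code{saliency_index_table} (ASI).
#' @param spec the generating \code{phantom_spec}.
#' @return list(per_bin, mean).
#' @export
planted_recovery <- function(tab, spec) {
  bins <- sort(unique(tab$age))
  rho <- vapply(bins, function(b) {
    sub <- tab[tab$age == b, ]
    v <- tapply(sub$value, sub$region, mean)
    p <- planted_importance(spec, b + 0.5)[names(v)]
    suppressWarnings(cor(v, p, method = "spearman"))
  }, 0)
  names(rho) <- bins
  list(per_bin = rho, mean = mean(rho, na.rm = TRUE))
}

default_run_config <- function() {
  list(
    seed = 1,
    phantom = list(canvas_side = 64, n = 600, sex_ratio = 0.5),
    pretreat = list(clahe = TRUE, clip_limit = 2, tile_grid = 8,
                    align = TRUE),
    split = list(ratios = c(train = 0.7, val = 0.15, test = 0.15)),
    age_task = list(lr0 = 3e-3, max_epochs = 25, batch_size = 32,
                    per_sex = TRUE),
    sex_task = list(ages = c(18), n_per_age = 300, lr0 = 3e-3,
                    max_epochs = 25, batch_size = 32),
    saliency = list(q = 75, k = 20,
                    annotation_jitter = list(shift_sd = 1.5, morph_max = 2)),
    write_images = FALSE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults.
#'
#' @param path YAML/JSON file, or a list of overrides, or NULL for defaults.
#' @return full configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- if (is.list(path)) path
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                      simplifyVector = TRUE)
          else yaml::read_yaml(path)
  merge_config(cfg, user)
}

manifest_write <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_done <- function(manifest, stage) {
  isTRUE(manifest[[stage]]$status == "complete")
}

#' Run the full phantom-to-index pipeline
#'
#' Executes phantom generation, stratified splits, per-sex age-model
#' training, age-subset sex-model training, test-set metrics, saliency maps,
#' population averages, thresholds and the ASI/SSI tables, writing CSV/TIFF/
#' PNG artifacts plus a JSON manifest into \code{out_dir}. Stages record
#' their seeds; re-runs skip completed stages (tracked in the manifest)
#' unless \code{force = TRUE}. Fully deterministic given the configuration.
#'
#' @param config path to a YAML config, a list of overrides, or NULL.
#' @param out_dir output directory (created if absent).
#' @param force re-run stages even if the manifest marks them complete.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir, force = FALSE) {
  cfg <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path) && !force)
    jsonlite::read_json(man_path, simplifyVector = TRUE) else list()
  manifest$config <- cfg
  seeds <- derive_seeds(cfg$seed, 6)
  state_path <- function(stage) file.path(out_dir, paste0(stage, "_state.rds"))
  finish <- function(stage, state, files = character()) {
    saveRDS(state, state_path(stage))
    manifest[[stage]] <<- list(status = "complete", seed = cfg$seed,
                               files = files, time = format(Sys.time()))
    manifest_write(out_dir, manifest)
    state
  }
  run_stage <- function(stage, fn) {
    if (!force && stage_done(manifest, stage) &&
        file.exists(state_path(stage))) {
      message("[", stage, "] cached")
      return(readRDS(state_path(stage)))
    }
    message("[", stage, "] running")
    fn()
  }

  spec <- do.call(phantom_spec,
                  cfg$phantom[intersect(names(cfg$phantom),
                                        names(formals(phantom_spec)))])

  ph <- run_stage("phantom", function() {
    co <- sample_cohort(spec, cfg$phantom$n,
                        sex_ratio = cfg$phantom$sex_ratio %||% 0.5,
                        seed = seeds[1])
    files <- "metadata.csv"
    write.csv(co$metadata, file.path(out_dir, "metadata.csv"),
              row.names = FALSE)
    if (isTRUE(cfg$write_images)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      for (i in seq_len(cfg$phantom$n))
        tiff::writeTIFF(co$images[, , i],
                        file.path(img_dir,
                                  paste0(co$metadata$subject_id[i], ".tif")),
                        bits.per.sample = 16)
      files <- c(files, "images/")
    }
    finish("phantom", co, files)
  })

  pp <- run_stage("pretreat", function() {
    imgs <- ph$images
    md <- ph$metadata
    if (isTRUE(cfg$pretreat$clahe))
      imgs <- preprocess_images(imgs, cfg$pretreat$clip_limit,
                                cfg$pretreat$tile_grid)
    if (isTRUE(cfg$pretreat$align)) {
      for (i in seq_len(nrow(md)))
        imgs[, , i] <- align_orientation(imgs[, , i], md$orientation[i])
      md$orientation <- "standard"
    }
    finish("pretreat", list(images = imgs, metadata = md))
  })

  sp <- run_stage("split", function() {
    s <- stratified_split(pp$metadata, ratios = cfg$split$ratios,
                          seed = seeds[2])
    write.csv(s, file.path(out_dir, "splits.csv"), row.names = FALSE)
    finish("split", s, "splits.csv")
  })

  age_models <- run_stage("train_age", function() {
    ctl <- train_control(lr0 = cfg$age_task$lr0,
                         max_epochs = cfg$age_task$max_epochs,
                         batch_size = cfg$age_task$batch_size)
    md <- pp$metadata
    groups <- if (isTRUE(cfg$age_task$per_sex)) c("male", "female") else "all"
    models <- lapply(groups, function(sx) {
      sel <- if (sx == "all") rep(TRUE, nrow(md)) else md$sex == sx
      spl <- sp$split[sel]
      imgs <- pp$images[, , sel, drop = FALSE]
      ages <- md$age[sel]
      ceph_cnn(imgs[, , spl == "train", drop = FALSE], ages[spl == "train"],
               "age",
               imgs[, , spl == "val", drop = FALSE], ages[spl == "val"],
               config = model_config("small_cnn", input_side = spec$canvas_side),
               control = ctl, seed = seeds[3])
    })
    names(models) <- groups
    for (g in groups)
      jsonlite::write_json(models[[g]]$history,
                           file.path(out_dir,
                                     paste0("history_age_", g, ".json")),
                           dataframe = "columns", digits = NA)
    finish("train_age", models,
           paste0("history_age_", groups, ".json"))
  })

  sex_models <- run_stage("train_sex", function() {
    ctl <- train_control(lr0 = cfg$sex_task$lr0,
                         max_epochs = cfg$sex_task$max_epochs,
                         batch_size = cfg$sex_task$batch_size)
    md <- pp$metadata
    subsets <- select_age_subsets(md, cfg$sex_task$ages)
    models <- lapply(names(subsets), function(a) {
      sub <- subsets[[a]]
      if (nrow(sub) < 10) {
        warning("age subset ", a, " too small to train; skipped")
        return(NULL)
      }
      sel <- match(sub$subject_id, md$subject_id)
      spl <- stratified_split(sub, ratios = cfg$split$ratios,
                              strata = "sex", seed = seeds[4])
      imgs <- pp$images[, , sel, drop = FALSE]
      ceph_cnn(imgs[, , spl$split == "train", drop = FALSE],
               sub$sex[spl$split == "train"], "sex",
               imgs[, , spl$split == "val", drop = FALSE],
               sub$sex[spl$split == "val"],
               config = model_config("small_cnn",
                                     input_side = spec$canvas_side,
                                     head = "sex_classification"),
               control = ctl, seed = seeds[4])
    })
    names(models) <- names(subsets)
    finish("train_sex", models)
  })

  metrics <- run_stage("evaluate", function() {
    md <- pp$metadata
    rows_reg <- list(); preds <- list()
    for (g in names(age_models)) {
      sel <- if (g == "all") rep(TRUE, nrow(md)) else md$sex == g
      test <- sel & sp$split == "test"
      pr <- predict(age_models[[g]], pp$images[, , test, drop = FALSE])
      rep_ <- regression_metrics(md$age[test], pr)
      rows_reg[[g]] <- data.frame(group = g, n = rep_$n, mae = rep_$mae,
                                  rmse = rep_$rmse, r2 = rep_$r2)
      preds[[g]] <- data.frame(subject_id = md$subject_id[test],
                               age = md$age[test], predicted = pr)
    }
    if (length(age_models) > 1) {
      all_p <- do.call(rbind, preds)
      rep_ <- regression_metrics(all_p$age, all_p$predicted)
      rows_reg$all <- data.frame(group = "all", n = rep_$n, mae = rep_$mae,
                                 rmse = rep_$rmse, r2 = rep_$r2)
    }
    reg <- do.call(rbind, rows_reg)
    rows_cls <- list()
    for (a in names(sex_models)) {
      if (is.null(sex_models[[a]])) next
      sub <- select_age_subsets(md, as.integer(a))[[1]]
      spl <- stratified_split(sub, ratios = cfg$split$ratios, strata = "sex",
                              seed = seeds[4])
      sel <- match(sub$subject_id[spl$split == "test"], md$subject_id)
      scores <- predict(sex_models[[a]], pp$images[, , sel, drop = FALSE])
      cm <- classification_metrics(sub$sex[spl$split == "test"], scores)
      rows_cls[[a]] <- data.frame(age = as.integer(a), n = cm$n,
                                  accuracy = cm$accuracy,
                                  precision = cm$precision,
                                  recall = cm$recall, f1 = cm$f1)
    }
    cls <- if (length(rows_cls)) do.call(rbind, rows_cls) else NULL
    write.csv(reg, file.path(out_dir, "regression_metrics.csv"),
              row.names = FALSE)
    if (!is.null(cls))
      write.csv(cls, file.path(out_dir, "classification_metrics.csv"),
                row.names = FALSE)
    preds_df <- do.call(rbind, preds)
    write.csv(preds_df, file.path(out_dir, "age_predictions.csv"),
              row.names = FALSE)
    finish("evaluate", list(regression = reg, classification = cls),
           c("regression_metrics.csv", "classification_metrics.csv",
             "age_predictions.csv"))
  })

  indices <- run_stage("saliency_index", function() {
    md <- pp$metadata
    test <- sp$split == "test"
    asi <- NULL
    tabs <- list()
    for (g in names(age_models)) {
      sel <- test & (if (g == "all") TRUE else md$sex == g)
      tabs[[g]] <- saliency_index_table(age_models[[g]],
                                        pp$images[, , sel, drop = FALSE],
                                        md[sel, ], spec,
                                        q = cfg$saliency$q,
                                        k = cfg$saliency$k,
                                        annotation_jitter =
                                          cfg$saliency$annotation_jitter,
                                        seed = seeds[5])
    }
    asi <- do.call(rbind, tabs)
    asi <- asi[order(asi$sex, asi$age), ]
    write.csv(asi, file.path(out_dir, "asi_table.csv"), row.names = FALSE)
    ssi <- NULL
    ssi_rows <- list()
    for (a in names(sex_models)) {
      if (is.null(sex_models[[a]])) next
      sub <- select_age_subsets(md, as.integer(a))[[1]]
      spl <- stratified_split(sub, ratios = cfg$split$ratios, strata = "sex",
                              seed = seeds[4])
      sel <- match(sub$subject_id[spl$split == "test"], md$subject_id)
      ssi_rows[[a]] <- saliency_index_table(sex_models[[a]],
                                            pp$images[, , sel, drop = FALSE],
                                            md[sel, ], spec,
                                            q = cfg$saliency$q,
                                            k = cfg$saliency$k,
                                            annotation_jitter =
                                              cfg$saliency$annotation_jitter,
                                            seed = seeds[6])
    }
    if (length(ssi_rows)) {
      ssi <- do.call(rbind, ssi_rows)
      write.csv(ssi, file.path(out_dir, "ssi_table.csv"), row.names = FALSE)
    }
    finish("saliency_index", list(asi = asi, ssi = ssi),
           c("asi_table.csv", if (!is.null(ssi)) "ssi_table.csv"))
  })

  invisible(manifest)
}

#' Export figures and summary reports from a completed pipeline run
#'
#' Writes per-group average-saliency overlays and a planted-vs-recovered
#' importance chart from the artifacts in \code{out_dir}.
#'
#' @param out_dir directory of a completed \code{run_pipeline} run.
#' @return invisibly, paths of the files written.
#' @export
export_reports <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest in ", out_dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  missing <- setdiff(c("phantom", "pretreat", "split", "train_age",
                       "evaluate", "saliency_index"), names(manifest))
  missing <- missing[!vapply(missing, function(s) stage_done(manifest, s),
                             TRUE)]
  if (length(missing))
    stop("pipeline incomplete; missing stages: ",
         paste(missing, collapse = ", "))
  cfg <- manifest$config
  spec <- do.call(phantom_spec,
                  cfg$phantom[intersect(names(cfg$phantom),
                                        names(formals(phantom_spec)))])
  pp <- readRDS(file.path(out_dir, "pretreat_state.rds"))
  sp <- readRDS(file.path(out_dir, "split_state.rds"))
  models <- readRDS(file.path(out_dir, "train_age_state.rds"))
  idx <- readRDS(file.path(out_dir, "saliency_index_state.rds"))
  files <- character()
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  md <- pp$metadata
  test <- sp$split == "test"
  for (g in names(models)) {
    sel <- test & (if (g == "all") TRUE else md$sex == g)
    sm <- subject_saliency_maps(models[[g]], pp$images[, , sel, drop = FALSE],
                                md[sel, ])
    for (b in sort(unique(sm$groups$age_bin))) {
      in_bin <- sm$groups$age_bin == b
      avg <- group_average(sm$maps[in_bin], group_key = list(bin = b, sex = g))
      ref <- apply(pp$images[, , sel, drop = FALSE][, , in_bin, drop = FALSE],
                   c(1, 2), mean)
      ov <- colorize_overlay(avg$mean, ref)
      f <- file.path(fig_dir, sprintf("avg_saliency_%s_bin%02d.png", g, b))
      png::writePNG(aperm(ov, c(1, 2, 3)), f)
      files <- c(files, f)
    }
  }
  if (!is.null(idx$asi)) {
    rec <- planted_recovery(idx$asi, spec)
    f <- file.path(fig_dir, "planted_vs_recovered.png")
    grDevices::png(f, 900, 450)
    graphics::par(mfrow = c(1, 2))
    bins <- sort(unique(idx$asi$age))
    regions <- unique(idx$asi$region)
    rec_m <- matrix(NA_real_, length(bins), length(regions),
                    dimnames = list(bins, regions))
    for (r in regions) for (bi in seq_along(bins))
      rec_m[bi, r] <- mean(idx$asi$value[idx$asi$age == bins[bi] &
                                           idx$asi$region == r])
    graphics::matplot(bins, rec_m, type = "l", lty = 1, lwd = 2,
                      xlab = "age bin", ylab = "ASI",
                      main = "recovered regional saliency")
    graphics::legend("topright", regions, lty = 1, lwd = 2,
                     col = seq_along(regions), bty = "n", cex = 0.8)
    pl <- matrix(NA_real_, length(bins), length(regions),
                 dimnames = list(bins, regions))
    for (r in regions) for (bi in seq_along(bins))
      pl[bi, r] <- planted_importance(spec, bins[bi] + 0.5)[[r]]
    graphics::matplot(bins, pl, type = "l", lty = 1, lwd = 2,
                      xlab = "age bin", ylab = "planted importance",
                      main = sprintf("planted signal (mean Spearman %.2f)",
                                     rec$mean))
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
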