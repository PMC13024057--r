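# Small, fast phantom configurations shared across tests.
quiet_spec <- function(...) phantom_spec(...)

# deterministic rendering config: no acquisition noise or subject jitter
clean_spec <- function(canvas = 64) {
  phantom_spec(canvas_side = canvas, noise_sd = 0, jitter_sd = 0,
               region_scale_sd = 0, texture = list(amplitude = 0),
               intensity_gain_range = c(1, 1))
}

subj <- function(age, sex = "male", orientation = "standard") {
  list(age = age, sex = sex, orientation = orientation)
}

# independent softmax cross-entropy written out elementwise
ref_xent <- function(z, g) {
  p1 <- exp(z[, 1]) / (exp(z[, 1]) + exp(z[, 2]))
  -mean(g * log(p1) + (1 - g) * log(1 - p1))
}

# a structurally valid fitted model without training (for plumbing tests)
toy_fitted <- function(side, head = "age_regression") {
  m <- build_model(model_config("small_cnn", side, head,
                                channels = c(3, 4), hidden = 4), seed = 1)
  m$fitted <- TRUE
  m$task <- if (head == "age_regression") "age" else "sex"
  m
}

# render, equalize and orientation-align a cohort (the standard pipeline)
prepared_cohort <- function(spec, n, seed, age_law = function(n)
                              runif(n, 4, 19)) {
  co <- sample_cohort(spec, n, age_law = age_law, seed = seed)
  co$images <- preprocess_images(co$images)
  for (i in seq_len(nrow(co$metadata)))
    co$images[, , i] <- align_orientation(co$images[, , i],
                                          co$metadata$orientation[i])
  co$metadata$orientation <- "standard"
  co
}
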